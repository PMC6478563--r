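#' Run the analysis pipeline
#'
#' Orchestrates the stages over a configuration list or YAML file:
#' `simulate-data` writes a synthetic input bundle; `fsir` computes the
#' familial-risk table; `qc` filters genotypes; `sgs-scan`, `gene-drop` and
#' `thresholds` run inside the `sgs()` fit; `combine` overlaps regions
#' across families; `followup` screens and tests variants; `all` chains
#' everything in study order.  Every output directory receives a
#' `run_metadata.json` with the seed, a config hash and package version, so
#' identical config + seed reproduce identical artifacts.
#'
#' @param config configuration list or path to a YAML file.  Recognised
#'   keys (all optional): `seed`, `out_dir`, `n_sims`, `sim` (arguments to
#'   [sim_config()]), `scan` (arguments to [scan_config()]),
#'   `fsir_alpha` (0.05), `hwe_alpha` (0.001), `max_marker_missing`,
#'   `max_sample_missing` (0.05), `maf_familial` (0.10), `maf_assoc`
#'   (0.20), `assoc_alpha` (0.05), `fp_targets` (c(0.5, 1)).
#' @param stage one of `"simulate-data"`, `"fsir"`, `"qc"`, `"sgs"`,
#'   `"combine"`, `"followup"`, `"all"`.
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(config = list(), stage = "all") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop(validation_error("config must be a list or YAML path"))
  known <- c("seed", "out_dir", "n_sims", "sim", "scan", "fsir_alpha",
             "hwe_alpha", "max_marker_missing", "max_sample_missing",
             "maf_familial", "maf_assoc", "assoc_alpha", "fp_targets")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    stop(validation_error("unknown config keys: ",
                          paste(bad, collapse = ", ")))
  stage <- match.arg(stage, c("simulate-data", "fsir", "qc", "sgs",
                              "combine", "followup", "all"))
  cf <- function(key, default) if (is.null(config[[key]])) default
                               else config[[key]]
  seed <- cf("seed", 1)
  out_dir <- cf("out_dir", tempfile("sgsfam_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                cf("sim", list())))
  sccfg <- do.call(scan_config,
                   utils::modifyList(list(min_markers_per_run = 10),
                                     cf("scan", list())))

  res <- list()
  bundle <- simulate_study(scfg,
                           dir = if (stage %in% c("simulate-data", "all"))
                             file.path(out_dir, "inputs") else NULL)
  res$bundle <- bundle
  if (stage == "simulate-data") {
    write_metadata(out_dir, seed, config)
    return(invisible(res))
  }

  if (stage %in% c("fsir", "all")) {
    res$fsir <- fsir_table(bundle$membership, bundle$rates)
    utils::write.table(res$fsir, file.path(out_dir, "fsir.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage %in% c("qc", "all")) {
    res$qc <- qc_filter(bundle$genotypes, bundle$map,
                        max_marker_missing = cf("max_marker_missing", 0.05),
                        hwe_alpha = cf("hwe_alpha", 0.001),
                        max_sample_missing = cf("max_sample_missing", 0.05))
    write_qc_report(res$qc$report, file.path(out_dir, "qc_report.tsv"))
  }
  gm <- if (!is.null(res$qc)) res$qc$genotypes else bundle$genotypes
  panel <- if (!is.null(res$qc))
    subset_panel(bundle$panel, colnames(gm)) else bundle$panel
  if (stage %in% c("sgs", "combine", "followup", "all")) {
    fit <- sgs(bundle$ped, gm, panel, cfg = sccfg,
               n_sims = cf("n_sims", 2000), seed = seed,
               targets = cf("fp_targets", c(0.5, 1)))
    res$sgs <- fit
    write_segments(fit$segments, fit$family_id,
                   bed_path = file.path(out_dir, "segments.bed"),
                   tsv_path = file.path(out_dir, "segments.tsv"))
    write_thresholds(stats::setNames(list(fit$thresholds),
                                     fit$family_id),
                     file.path(out_dir, "thresholds.tsv"),
                     file.path(out_dir, "threshold_diagnostics.json"))
  }
  if (stage %in% c("combine", "followup", "all")) {
    segs <- stats::setNames(list(res$sgs$segments), res$sgs$family_id)
    thrs <- stats::setNames(list(res$sgs$thresholds), res$sgs$family_id)
    res$regions <- overlap_regions(segs, thrs)
    utils::write.table(res$regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage %in% c("followup", "all")) {
    targets <- target_genes(res$regions, bundle$genes)
    res$targets <- targets
    res$enrichment <- if (length(targets) > 0)
      enrichment_test(length(targets),
                      sum(targets %in% bundle$literature),
                      length(unique(bundle$genes$gene)),
                      length(bundle$literature)) else NULL
    res$familial <- familial_variant_screen(
      res$regions, bundle$annotations, gm,
      maf_cutoff = cf("maf_familial", 0.10))
    sel <- select_assoc_variants(bundle$annotations, targets,
                                 maf_cutoff = cf("maf_assoc", 0.20))
    res$assoc <- if (nrow(sel) > 0)
      assoc_screen(sel, alpha = cf("assoc_alpha", 0.05)) else NULL
    if (!is.null(res$assoc))
      utils::write.table(res$assoc, file.path(out_dir, "assoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_metadata(out_dir, seed, config)
  invisible(res)
}

validation_error <- function(...) {
  structure(class = c("sgsfam_validation_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

write_metadata <- function(out_dir, seed, config) {
  tmp <- tempfile()
  yaml::write_yaml(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(seed = seed, config_md5 = hash,
         package = as.character(utils::packageVersion("sgsfam"))),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(hash)
}
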