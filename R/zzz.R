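#' @keywords internal
#' @useDynLib sgsfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
"_PACKAGE"

.datatable.aware <- TRUE

# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c("len_bp", "start_bp", "end_bp", "expected",
                         "cutoff"))
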