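#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haldane meiosis: crossover count ~ Poisson(L/100) on the cM scale,
// crossover positions uniform, no interference.  Writes the transmitted
// haplotype into `out`.  Uses R's RNG so results follow set.seed().
static void transmit(const int *hapA, const int *hapB, const double *cm,
                     const int m, int *out) {
  if (m == 0) return;
  const double lo = cm[0], L = cm[m - 1] - cm[0];
  int ncross = (L > 0) ? (int)::Rf_rpois(L / 100.0) : 0;
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (ncross == 0) {  // common case: whole chromosome from one parent copy
    std::copy(cur == 0 ? hapA : hapB, (cur == 0 ? hapA : hapB) + m, out);
    return;
  }
  std::vector<double> cuts((size_t)ncross);
  for (int i = 0; i < ncross; ++i) cuts[(size_t)i] = lo + unif_rand() * L;
  std::sort(cuts.begin(), cuts.end());
  int from = 0;
  for (int i = 0; i <= ncross; ++i) {
    // segment of markers strictly right of the previous cut, up to this cut
    int to = (i == ncross)
                 ? m
                 : (int)(std::upper_bound(cm, cm + m, cuts[(size_t)i]) - cm);
    if (to > from) {
      const int *src = (cur == 0) ? hapA : hapB;
      std::copy(src + from, src + to, out + from);
      from = to;
    }
    cur ^= 1;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_meiosis(IntegerVector hapA, IntegerVector hapB,
                          NumericVector cm) {
  const int m = hapA.size();
  if (hapB.size() != m || cm.size() != m)
    stop("haplotypes and genetic map must have equal length");
  IntegerVector out(m);
  if (m > 0) transmit(&hapA[0], &hapB[0], &cm[0], m, &out[0]);
  return out;
}

// Shared run detection.  geno: k x m matrix of {0,1,2}, NA/-1 = missing.
// subsets: list of 1-based row index vectors.  policy 0 = missing-compatible,
// 1 = missing breaks the run.  Returns matrix with columns
// (subset, chrom, start, end) of maximal sharing runs (1-based marker
// indices, global) with at least min_markers markers.
// [[Rcpp::export]]
IntegerMatrix cpp_run_scan(IntegerMatrix geno, List subsets,
                           IntegerVector chrom, int policy, int min_markers) {
  const int m = geno.ncol();
  if (chrom.size() != m) stop("chrom vector does not match marker count");
  std::vector<int> o_sub, o_chr, o_sta, o_end;
  const int ns = subsets.size();
  for (int s = 0; s < ns; ++s) {
    IntegerVector rows = subsets[s];
    const int k = rows.size();
    int run_start = -1;
    for (int j = 0; j <= m; ++j) {
      bool share = false;
      bool new_chrom = (j < m) && (j > 0) && (chrom[j] != chrom[j - 1]);
      if (j < m && !new_chrom) {
        bool any0 = false, any2 = false, anymiss = false;
        for (int i = 0; i < k; ++i) {
          int g = geno(rows[i] - 1, j);
          if (g == NA_INTEGER || g < 0) anymiss = true;
          else if (g == 0) any0 = true;
          else if (g == 2) any2 = true;
        }
        share = !(any0 && any2);
        if (policy == 1 && anymiss) share = false;
      }
      // close the current run on a break or chromosome change or at the end
      if (run_start >= 0 && (j == m || new_chrom || !share)) {
        int end = j - 1;
        if (end - run_start + 1 >= min_markers) {
          o_sub.push_back(s + 1);
          o_chr.push_back(chrom[run_start]);
          o_sta.push_back(run_start + 1);
          o_end.push_back(end + 1);
        }
        run_start = -1;
      }
      if (j < m) {
        if (new_chrom) {
          // re-evaluate marker j as a fresh run start on the new chromosome
          bool any0 = false, any2 = false, anymiss = false;
          for (int i = 0; i < k; ++i) {
            int g = geno(rows[i] - 1, j);
            if (g == NA_INTEGER || g < 0) anymiss = true;
            else if (g == 0) any0 = true;
            else if (g == 2) any2 = true;
          }
          share = !(any0 && any2);
          if (policy == 1 && anymiss) share = false;
        }
        if (share && run_start < 0) run_start = j;
      }
    }
  }
  const int n = (int)o_sub.size();
  IntegerMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = o_sub[(size_t)i];
    out(i, 1) = o_chr[(size_t)i];
    out(i, 2) = o_sta[(size_t)i];
    out(i, 3) = o_end[(size_t)i];
  }
  colnames(out) = CharacterVector::create("subset", "chrom", "start", "end");
  return out;
}

// Gene-drop null simulation.  Pedigree arrives in topological order
// (parents before children); father/mother are 0-based indices, -1 for
// founders.  Founders receive two whole-chromosome haplotypes drawn
// uniformly with replacement from the panel (LD preserved exactly);
// each meiosis transmits a Haldane recombinant.  For every simulation the
// sharing runs of every case subset are recorded (deduplicated within
// subset size).  Returns list(sim, size, chrom, start, end) with 1-based
// per-chromosome marker indices.
// [[Rcpp::export]]
List cpp_simulate_null(int n_sims, IntegerVector father, IntegerVector mother,
                       IntegerVector case_rows, List subsets,
                       IntegerVector subset_sizes, List panel, List cmlist,
                       int min_markers) {
  const int n_ind = father.size();
  const int n_chr = panel.size();
  const int n_cases = case_rows.size();
  const int n_sub = subsets.size();

  // copy panel into row-major buffers (sequential founder copies) and cm
  std::vector<std::vector<int> > pan(n_chr);
  std::vector<int> nhap(n_chr);
  std::vector<NumericVector> cms(n_chr);
  std::vector<int> nmark(n_chr);
  for (int c = 0; c < n_chr; ++c) {
    IntegerMatrix P = as<IntegerMatrix>(panel[c]);
    cms[(size_t)c] = as<NumericVector>(cmlist[c]);
    nmark[(size_t)c] = P.ncol();
    nhap[(size_t)c] = P.nrow();
    if (cms[(size_t)c].size() != nmark[(size_t)c])
      stop("genetic map does not match panel markers");
    pan[(size_t)c].resize((size_t)P.nrow() * (size_t)P.ncol());
    for (int r = 0; r < P.nrow(); ++r)
      for (int j = 0; j < P.ncol(); ++j)
        pan[(size_t)c][(size_t)r * (size_t)P.ncol() + (size_t)j] = P(r, j);
  }

  if (n_cases > 31) stop("null simulation supports at most 31 cases");
  std::vector<unsigned int> submask((size_t)n_sub, 0u);
  for (int s = 0; s < n_sub; ++s) {
    IntegerVector v = subsets[s];  // 1-based into case_rows
    for (int i = 0; i < v.size(); ++i)
      submask[(size_t)s] |= 1u << (v[i] - 1);
  }

  std::vector<int> o_sim, o_size, o_chr, o_sta, o_end;

  // fast path: break-bitmap cache keyed by the (hom0, hom2) case patterns
  // of a stretch; subsets tracked bit-parallel in two 64-bit words
  const bool fast = (n_cases <= 9) && (n_sub <= 128);
  std::vector<unsigned long long> cacheB0, cacheB1;
  std::vector<char> cachedF;
  if (fast) {
    const size_t tab = (size_t)1 << (2 * n_cases);
    cacheB0.assign(tab, 0ull);
    cacheB1.assign(tab, 0ull);
    cachedF.assign(tab, 0);
  }

  for (int c = 0; c < n_chr; ++c) {
    const int m = nmark[(size_t)c];
    const int *P = pan[(size_t)c].data();
    const int n_hap = nhap[(size_t)c];
    const double *cm = (m > 0) ? &cms[(size_t)c][0] : (double *)0;
    // haplotype storage: two alleles per individual per marker
    std::vector<int> h0((size_t)n_ind * (size_t)m),
        h1((size_t)n_ind * (size_t)m);

    for (int sim = 0; sim < n_sims; ++sim) {
      for (int i = 0; i < n_ind; ++i) {
        int *hi0 = &h0[(size_t)i * (size_t)m];
        int *hi1 = &h1[(size_t)i * (size_t)m];
        if (father[i] < 0) {  // founder: draw two panel haplotypes
          for (int cp = 0; cp < 2; ++cp) {
            int r = (int)(unif_rand() * n_hap);
            if (r >= n_hap) r = n_hap - 1;
            int *dst = (cp == 0) ? hi0 : hi1;
            std::copy(P + (size_t)r * (size_t)m,
                      P + (size_t)(r + 1) * (size_t)m, dst);
          }
        } else {
          transmit(&h0[(size_t)father[i] * (size_t)m],
                   &h1[(size_t)father[i] * (size_t)m], cm, m, hi0);
          transmit(&h0[(size_t)mother[i] * (size_t)m],
                   &h1[(size_t)mother[i] * (size_t)m], cm, m, hi1);
        }
      }
      // per-marker bitmasks over cases: which cases are hom-0 / hom-2
      std::vector<unsigned int> m0((size_t)m, 0u), m2((size_t)m, 0u);
      for (int i = 0; i < n_cases; ++i) {
        const size_t off = (size_t)(case_rows[i] - 1) * (size_t)m;
        const unsigned int bit = 1u << i;
        for (int j = 0; j < m; ++j) {
          const int g = h0[off + (size_t)j] + h1[off + (size_t)j];
          if (g == 0) m0[(size_t)j] |= bit;
          else if (g == 2) m2[(size_t)j] |= bit;
        }
      }
      // run-length compress constant (m0, m2) stretches: with LD blocks
      // most consecutive markers carry identical homozygote patterns
      std::vector<unsigned int> cu0, cu2;
      std::vector<int> cpos;
      for (int j = 0; j < m; ++j)
        if (j == 0 || m0[(size_t)j] != m0[(size_t)j - 1] ||
            m2[(size_t)j] != m2[(size_t)j - 1]) {
          cu0.push_back(m0[(size_t)j]);
          cu2.push_back(m2[(size_t)j]);
          cpos.push_back(j);
        }
      const int K = (int)cpos.size();
      cpos.push_back(m);  // sentinel
      // per-size dedup of identical runs from different same-size subsets
      std::vector<std::vector<std::pair<int, int> > > bysize;
      std::vector<int> sizes_seen;
      int starts[128];
#define SGSFAM_RECORD(sidx, a, b)                                        \
  do {                                                                   \
    int sz = subset_sizes[(sidx)];                                       \
    int slot = -1;                                                       \
    for (size_t q = 0; q < sizes_seen.size(); ++q)                       \
      if (sizes_seen[q] == sz) { slot = (int)q; break; }                 \
    if (slot < 0) {                                                      \
      sizes_seen.push_back(sz);                                          \
      bysize.push_back(std::vector<std::pair<int, int> >());             \
      slot = (int)sizes_seen.size() - 1;                                 \
    }                                                                    \
    bysize[(size_t)slot].push_back(std::make_pair((a) + 1, (b)));        \
  } while (0)
      if (fast) {
        const unsigned long long lo64 =
            (n_sub >= 64) ? ~0ull : ((1ull << n_sub) - 1ull);
        const unsigned long long hi64 =
            (n_sub <= 64) ? 0ull : ((n_sub >= 128)
                                        ? ~0ull
                                        : ((1ull << (n_sub - 64)) - 1ull));
        unsigned long long act0 = 0, act1 = 0;
        for (int k = 0; k <= K; ++k) {
          unsigned long long B0, B1;
          if (k < K) {
            const unsigned key =
                (cu0[(size_t)k] << n_cases) | cu2[(size_t)k];
            if (!cachedF[key]) {
              unsigned long long b0 = 0, b1 = 0;
              for (int s = 0; s < n_sub; ++s) {
                const unsigned int mask = submask[(size_t)s];
                if ((cu0[(size_t)k] & mask) && (cu2[(size_t)k] & mask)) {
                  if (s < 64) b0 |= 1ull << s;
                  else b1 |= 1ull << (s - 64);
                }
              }
              cacheB0[key] = b0; cacheB1[key] = b1; cachedF[key] = 1;
            }
            B0 = cacheB0[key]; B1 = cacheB1[key];
          } else {
            B0 = ~0ull; B1 = ~0ull;  // close everything at chromosome end
          }
          const int pos = cpos[(size_t)k];
          unsigned long long close0 = act0 & B0, close1 = act1 & B1;
          while (close0) {
            const int b = __builtin_ctzll(close0);
            close0 &= close0 - 1;
            if (pos - starts[b] >= min_markers)
              SGSFAM_RECORD(b, starts[b], pos);
          }
          while (close1) {
            const int b = __builtin_ctzll(close1);
            close1 &= close1 - 1;
            if (pos - starts[b + 64] >= min_markers)
              SGSFAM_RECORD(b + 64, starts[b + 64], pos);
          }
          act0 &= ~B0; act1 &= ~B1;
          if (k < K) {
            unsigned long long open0 = ~act0 & ~B0 & lo64;
            unsigned long long open1 = ~act1 & ~B1 & hi64;
            act0 |= open0; act1 |= open1;
            while (open0) {
              const int b = __builtin_ctzll(open0);
              open0 &= open0 - 1;
              starts[b] = pos;
            }
            while (open1) {
              const int b = __builtin_ctzll(open1);
              open1 &= open1 - 1;
              starts[b + 64] = pos;
            }
          }
        }
      } else {
        for (int s = 0; s < n_sub; ++s) {
          const unsigned int mask = submask[(size_t)s];
          int run_start = -1;
          for (int k = 0; k <= K; ++k) {
            bool share =
                (k < K) &&
                !((cu0[(size_t)k] & mask) && (cu2[(size_t)k] & mask));
            if (run_start >= 0 && !share) {
              const int end = cpos[(size_t)k];  // one past the run
              if (end - run_start >= min_markers)
                SGSFAM_RECORD(s, run_start, end);
              run_start = -1;
            }
            if (k < K && share && run_start < 0)
              run_start = cpos[(size_t)k];
          }
        }
      }
#undef SGSFAM_RECORD
      for (size_t q = 0; q < sizes_seen.size(); ++q) {
        std::vector<std::pair<int, int> > &v = bysize[q];
        std::sort(v.begin(), v.end());
        v.erase(std::unique(v.begin(), v.end()), v.end());
        for (size_t r = 0; r < v.size(); ++r) {
          o_sim.push_back(sim + 1);
          o_size.push_back(sizes_seen[q]);
          o_chr.push_back(c + 1);
          o_sta.push_back(v[r].first);
          o_end.push_back(v[r].second);
        }
      }
      if (sim % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["sim"] = wrap(o_sim), _["size"] = wrap(o_size),
                      _["chrom"] = wrap(o_chr), _["start"] = wrap(o_sta),
                      _["end"] = wrap(o_end));
}

// Maximum covering run length per (simulation, marker).  Inputs are runs on
// one chromosome for one subset-size class: for every marker index covered
// by a run, record the longest covering run's bp length.
// [[Rcpp::export]]
NumericMatrix cpp_cover_matrix(IntegerVector sim, IntegerVector start,
                               IntegerVector end, NumericVector len,
                               int n_sims, int n_markers) {
  NumericMatrix out(n_sims, n_markers);
  const int n = sim.size();
  for (int i = 0; i < n; ++i) {
    const int r = sim[i] - 1;
    const double L = len[i];
    for (int j = start[i] - 1; j <= end[i] - 1; ++j)
      if (L > out(r, j)) out(r, j) = L;
  }
  return out;
}

// Tail counts against the null, one chromosome at a time.  Runs are the
// recorded null runs on the chromosome (marker-index coordinates, bp
// lengths, subset sizes).  Each query asks: in how many simulations does a
// run of subset size >= q_size cover marker column q_col with bp length
// >= q_len?  Computed by accumulating, over sizes in decreasing order, a
// per-(simulation, marker) maximum covering length and sorting the queried
// columns.
// [[Rcpp::export]]
IntegerVector cpp_cover_tail_counts(IntegerVector run_sim,
                                    IntegerVector run_start,
                                    IntegerVector run_end,
                                    NumericVector run_len,
                                    IntegerVector run_size, int n_sims,
                                    int n_markers, IntegerVector q_col,
                                    NumericVector q_len,
                                    IntegerVector q_size) {
  const int nr = run_sim.size(), nq = q_col.size();
  IntegerVector out(nq);
  std::vector<int> sizes;
  for (int i = 0; i < nr; ++i)
    if (std::find(sizes.begin(), sizes.end(), run_size[i]) == sizes.end())
      sizes.push_back(run_size[i]);
  for (int q = 0; q < nq; ++q)
    if (std::find(sizes.begin(), sizes.end(), q_size[q]) == sizes.end())
      sizes.push_back(q_size[q]);
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
  std::vector<double> cover((size_t)n_sims * (size_t)n_markers, 0.0);
  for (size_t si = 0; si < sizes.size(); ++si) {
    const int s = sizes[si];
    for (int i = 0; i < nr; ++i) {
      if (run_size[i] != s) continue;
      const size_t row = (size_t)(run_sim[i] - 1);
      const double L = run_len[i];
      for (int j = run_start[i] - 1; j <= run_end[i] - 1; ++j) {
        double &c = cover[row * (size_t)n_markers + (size_t)j];
        if (L > c) c = L;
      }
    }
    // queries at this size see runs of size >= s (already accumulated);
    // group queries by column and count with one bucketing pass per
    // column instead of sorting it
    std::vector<int> qids;
    for (int q = 0; q < nq; ++q) if (q_size[q] == s) qids.push_back(q);
    if (qids.empty()) continue;
    std::sort(qids.begin(), qids.end(),
              [&](int a, int b) { return q_col[a] < q_col[b]; });
    size_t k = 0;
    while (k < qids.size()) {
      const int col = q_col[qids[k]] - 1;
      size_t k2 = k;
      while (k2 < qids.size() && q_col[qids[k2]] - 1 == col) ++k2;
      // ascending query lengths for this column
      std::vector<std::pair<double, int> > lens;
      for (size_t j = k; j < k2; ++j)
        lens.push_back(std::make_pair(q_len[qids[j]], qids[j]));
      std::sort(lens.begin(), lens.end());
      const size_t nl = lens.size();
      std::vector<double> lv(nl);
      for (size_t j = 0; j < nl; ++j) lv[j] = lens[j].first;
      std::vector<int> bump(nl + 1, 0);
      const double *colp = &cover[(size_t)col];
      for (int r = 0; r < n_sims; ++r) {
        const double v = colp[(size_t)r * (size_t)n_markers];
        // number of query lengths <= v
        const size_t u =
            std::upper_bound(lv.begin(), lv.end(), v) - lv.begin();
        ++bump[u];
      }
      // count(len_j) = number of elements v with v >= len_j
      int suffix = 0;
      for (size_t j = nl; j >= 1; --j) {
        suffix += bump[j];
        out[lens[j - 1].second] = suffix;
      }
      k = k2;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
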