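// Core engine: bit-plane genotype encoding, popcount-based contingency
// counting, greedy dynamic clustering of genotype cells, exhaustive pair
// scan and stepwise candidate extension. Counts are exact integers; all
// chi-square statistics are Pearson without continuity correction.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

static inline int popcount64(uint64_t x) {
  return __builtin_popcountll(x);
}

// ---------------------------------------------------------------------------
// Bit planes
//
// Layout: one uint64 word block per (SNP, genotype) pair, cases and controls
// kept in separate raw buffers. Plane for SNP i, genotype g starts at word
// (i*3 + g) * W where W is the per-plane word count. Bit b of a case plane is
// set iff the b-th case individual (in file order) carries genotype g at SNP
// i. Missing genotypes (code 3) set no bit anywhere.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_encode_bitplanes(IntegerMatrix geno, IntegerVector pheno) {
  const int N = geno.nrow(), M = geno.ncol();
  int n_case = 0;
  for (int r = 0; r < N; ++r) if (pheno[r] == 1) ++n_case;
  const int n_ctrl = N - n_case;
  const int wc = (n_case + 63) / 64, wt = (n_ctrl + 63) / 64;

  RawVector case_raw((R_xlen_t)M * 3 * wc * 8);
  RawVector ctrl_raw((R_xlen_t)M * 3 * wt * 8);
  uint64_t* cw = reinterpret_cast<uint64_t*>(RAW(case_raw));
  uint64_t* tw = reinterpret_cast<uint64_t*>(RAW(ctrl_raw));

  std::vector<int> pos(N);  // within-phenotype ordinal of each row
  {
    int pc = 0, pt = 0;
    for (int r = 0; r < N; ++r) pos[r] = (pheno[r] == 1) ? pc++ : pt++;
  }
  for (int i = 0; i < M; ++i) {
    for (int r = 0; r < N; ++r) {
      const int g = geno(r, i);
      if (g < 0 || g > 2) continue;  // 3 = missing
      if (pheno[r] == 1) {
        uint64_t* p = cw + ((size_t)i * 3 + g) * wc;
        p[pos[r] >> 6] |= (uint64_t)1 << (pos[r] & 63);
      } else {
        uint64_t* p = tw + ((size_t)i * 3 + g) * wt;
        p[pos[r] >> 6] |= (uint64_t)1 << (pos[r] & 63);
      }
    }
  }
  return List::create(_["case_raw"] = case_raw, _["ctrl_raw"] = ctrl_raw,
                      _["n_case"] = n_case, _["n_ctrl"] = n_ctrl,
                      _["wc"] = wc, _["wt"] = wt, _["M"] = M);
}

// popcount of the AND of t planes for one phenotype group
static inline int and_popcount(const uint64_t* base, size_t plane_words,
                               const int* snps, const int* digits, int t,
                               int W) {
  int cnt = 0;
  for (int w = 0; w < W; ++w) {
    uint64_t acc = base[((size_t)snps[0] * 3 + digits[0]) * W + w];
    for (int k = 1; k < t; ++k)
      acc &= base[((size_t)snps[k] * 3 + digits[k]) * W + w];
    cnt += popcount64(acc);
  }
  (void)plane_words;
  return cnt;
}

static void count_cells(const uint64_t* cw, const uint64_t* tw, int wc, int wt,
                        const int* snps, int t, int* cc, int* tc) {
  int ncell = 1;
  for (int k = 0; k < t; ++k) ncell *= 3;
  int digits[4];
  for (int cell = 0; cell < ncell; ++cell) {
    int rem = cell;
    for (int k = t - 1; k >= 0; --k) { digits[k] = rem % 3; rem /= 3; }
    cc[cell] = and_popcount(cw, 0, snps, digits, t, wc);
    tc[cell] = and_popcount(tw, 0, snps, digits, t, wt);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_count_contingency(RawVector case_raw, RawVector ctrl_raw,
                                    int wc, int wt, int M,
                                    IntegerVector snps0) {
  const int t = snps0.size();
  if (t < 1 || t > 4) stop("tuple order must be between 1 and 4");
  int snps[4];
  for (int k = 0; k < t; ++k) {
    snps[k] = snps0[k];
    if (snps[k] < 0 || snps[k] >= M) stop("SNP index out of range");
    for (int j = 0; j < k; ++j)
      if (snps[j] == snps[k]) stop("degenerate tuple: duplicate SNP indices");
  }
  int ncell = 1;
  for (int k = 0; k < t; ++k) ncell *= 3;
  std::vector<int> cc(ncell), tc(ncell);
  count_cells(reinterpret_cast<const uint64_t*>(RAW(case_raw)),
              reinterpret_cast<const uint64_t*>(RAW(ctrl_raw)),
              wc, wt, snps, t, cc.data(), tc.data());
  IntegerMatrix out(2, ncell);
  for (int c = 0; c < ncell; ++c) { out(0, c) = cc[c]; out(1, c) = tc[c]; }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_plane_overlap(RawVector raw, int w, int M, int snp0) {
  if (snp0 < 0 || snp0 >= M) stop("SNP index out of range");
  const uint64_t* words = reinterpret_cast<const uint64_t*>(RAW(raw));
  IntegerMatrix out(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      const uint64_t* pa = words + ((size_t)snp0 * 3 + a) * w;
      const uint64_t* pb = words + ((size_t)snp0 * 3 + b) * w;
      int cnt = 0;
      for (int k = 0; k < w; ++k) cnt += popcount64(pa[k] & pb[k]);
      out(a, b) = cnt;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Dynamic clustering
// ---------------------------------------------------------------------------

static inline double chi2_2x2(double a1, double a2, double b1, double b2) {
  const double r1 = a1 + a2, r2 = b1 + b2, c1 = a1 + b1, c2 = a2 + b2;
  if (r1 <= 0 || r2 <= 0 || c1 <= 0 || c2 <= 0) return 0.0;
  const double det = a1 * b2 - a2 * b1;
  return (r1 + r2) * det * det / (r1 * r2 * c1 * c2);
}

static double chi2_2xk(const double* bc, const double* bt, int k) {
  double R1 = 0, R2 = 0;
  for (int i = 0; i < k; ++i) { R1 += bc[i]; R2 += bt[i]; }
  const double n = R1 + R2;
  double stat = 0;
  for (int i = 0; i < k; ++i) {
    const double col = bc[i] + bt[i];
    const double e1 = R1 * col / n, e2 = R2 * col / n;
    stat += (bc[i] - e1) * (bc[i] - e1) / e1 + (bt[i] - e2) * (bt[i] - e2) / e2;
  }
  return stat;
}

// One merge step on label/total vectors. Blocks are kept ordered by their
// label (smallest original cell index), so scanning pairs i<j visits ties in
// lexicographic (min label, max label) order and keeping the first strict
// minimum implements the deterministic tie rule.
static void merge_step(std::vector<int>& lab, std::vector<double>& bc,
                       std::vector<double>& bt,
                       std::vector<std::vector<int>>* members,
                       std::vector<std::array<double, 3>>* trace) {
  const int nb = (int)lab.size();
  int bi = -1, bj = -1;
  double best = R_PosInf;
  for (int i = 0; i < nb - 1; ++i)
    for (int j = i + 1; j < nb; ++j) {
      const double s = chi2_2x2(bc[i], bt[i], bc[j], bt[j]);
      if (s < best) { best = s; bi = i; bj = j; }
    }
  if (trace) trace->push_back({(double)lab[bi], (double)lab[bj], best});
  bc[bi] += bc[bj]; bt[bi] += bt[bj];
  if (members) {
    std::vector<int>& a = (*members)[bi];
    a.insert(a.end(), (*members)[bj].begin(), (*members)[bj].end());
    std::sort(a.begin(), a.end());
    members->erase(members->begin() + bj);
  }
  bc.erase(bc.begin() + bj); bt.erase(bt.begin() + bj);
  lab.erase(lab.begin() + bj);
}

static void init_blocks(const int* cc, const int* tc, int ncell,
                        std::vector<int>& lab, std::vector<double>& bc,
                        std::vector<double>& bt,
                        std::vector<std::vector<int>>* members) {
  for (int c = 0; c < ncell; ++c) {
    if (cc[c] + tc[c] > 0) {
      lab.push_back(c);
      bc.push_back(cc[c]);
      bt.push_back(tc[c]);
      if (members) members->push_back(std::vector<int>(1, c));
    }
  }
}

// Minimal-p evaluation used in the scans. Returns false when the table is
// untestable (fewer than two non-empty cells, or an empty phenotype row).
static bool table_best_p(const int* cc, const int* tc, int ncell,
                         double& out_p, double& out_chi2, int& out_df,
                         int& out_d) {
  std::vector<int> lab;
  std::vector<double> bc, bt;
  init_blocks(cc, tc, ncell, lab, bc, bt, nullptr);
  const int ne = (int)lab.size();
  if (ne < 2) return false;
  double R1 = 0, R2 = 0;
  for (int i = 0; i < ne; ++i) { R1 += bc[i]; R2 += bt[i]; }
  if (R1 <= 0 || R2 <= 0) return false;

  double best_p = R_PosInf, best_chi2 = 0;
  int best_df = 0, best_d = 0;
  for (;;) {
    const int nb = (int)lab.size();
    if (nb <= 6) {
      const double stat = chi2_2xk(bc.data(), bt.data(), nb);
      const int df = nb - 1;
      const double p = ::Rf_pchisq(stat, df, 0, 0);
      if (p <= best_p) { best_p = p; best_chi2 = stat; best_df = df; best_d = nb; }
    }
    if (nb <= 3) break;
    merge_step(lab, bc, bt, nullptr, nullptr);
  }
  out_p = best_p; out_chi2 = best_chi2; out_df = best_df; out_d = best_d;
  return true;
}

// [[Rcpp::export]]
List cpp_greedy_merge(IntegerVector case_counts, IntegerVector ctrl_counts,
                      int target_d) {
  const int ncell = case_counts.size();
  std::vector<int> lab;
  std::vector<double> bc, bt;
  std::vector<std::vector<int>> members;
  std::vector<std::array<double, 3>> trace;
  init_blocks(INTEGER(case_counts), INTEGER(ctrl_counts), ncell,
              lab, bc, bt, &members);
  const int ne = (int)lab.size();
  if (ne < 1) stop("untestable table: no non-empty cells");
  const bool warn = target_d > ne;
  while ((int)lab.size() > target_d)
    merge_step(lab, bc, bt, &members, &trace);

  List blk(members.size());
  for (size_t i = 0; i < members.size(); ++i) blk[i] = wrap(members[i]);
  NumericMatrix tr(trace.size(), 3);
  for (size_t i = 0; i < trace.size(); ++i) {
    tr(i, 0) = trace[i][0]; tr(i, 1) = trace[i][1]; tr(i, 2) = trace[i][2];
  }
  return List::create(_["blocks"] = blk,
                      _["case_totals"] = wrap(bc), _["ctrl_totals"] = wrap(bt),
                      _["trace"] = tr, _["warn_too_few_cells"] = warn);
}

// [[Rcpp::export]]
List cpp_dynamic_cluster(IntegerVector case_counts, IntegerVector ctrl_counts) {
  const int ncell = case_counts.size();
  std::vector<int> lab;
  std::vector<double> bc, bt;
  std::vector<std::vector<int>> members;
  std::vector<std::array<double, 3>> trace;
  init_blocks(INTEGER(case_counts), INTEGER(ctrl_counts), ncell,
              lab, bc, bt, &members);
  const int ne = (int)lab.size();
  if (ne < 2) stop("untestable table: fewer than 2 non-empty cells");
  double R1 = 0, R2 = 0;
  for (int i = 0; i < ne; ++i) { R1 += bc[i]; R2 += bt[i]; }
  if (R1 <= 0 || R2 <= 0)
    stop("untestable table: a phenotype row has zero total");

  std::vector<int> ev_d;
  std::vector<double> ev_chi2, ev_p;
  std::vector<List> ev_blocks;
  std::vector<NumericVector> ev_bc, ev_bt;
  for (;;) {
    const int nb = (int)lab.size();
    if (nb <= 6) {
      const double stat = chi2_2xk(bc.data(), bt.data(), nb);
      ev_d.push_back(nb);
      ev_chi2.push_back(stat);
      ev_p.push_back(::Rf_pchisq(stat, nb - 1, 0, 0));
      List blk(nb);
      for (int i = 0; i < nb; ++i) blk[i] = wrap(members[i]);
      ev_blocks.push_back(blk);
      ev_bc.push_back(wrap(bc));
      ev_bt.push_back(wrap(bt));
    }
    if (nb <= 3) break;
    merge_step(lab, bc, bt, &members, &trace);
  }
  // evaluations were recorded with d descending; ties go to smaller d
  int best = 0;
  for (size_t i = 1; i < ev_d.size(); ++i)
    if (ev_p[i] <= ev_p[best]) best = (int)i;
  IntegerVector ev_df(ev_d.size());
  for (size_t i = 0; i < ev_d.size(); ++i) ev_df[i] = ev_d[i] - 1;

  NumericMatrix tr(trace.size(), 3);
  for (size_t i = 0; i < trace.size(); ++i) {
    tr(i, 0) = trace[i][0]; tr(i, 1) = trace[i][1]; tr(i, 2) = trace[i][2];
  }
  return List::create(
      _["d"] = ev_d[best], _["chi2"] = ev_chi2[best],
      _["df"] = ev_d[best] - 1, _["p"] = ev_p[best],
      _["blocks"] = ev_blocks[best],
      _["case_totals"] = ev_bc[best], _["ctrl_totals"] = ev_bt[best],
      _["evaluations"] = DataFrame::create(_["d"] = wrap(ev_d),
                                           _["chi2"] = wrap(ev_chi2),
                                           _["df"] = ev_df,
                                           _["p"] = wrap(ev_p)),
      _["trace"] = tr, _["degenerate"] = (ne < 3));
}

// ---------------------------------------------------------------------------
// Scans
// ---------------------------------------------------------------------------

struct Rec {
  double p, chi2;
  int df, d;
  std::array<int, 4> snps;  // -1 padded
  int t;
};

static bool rec_less(const Rec& a, const Rec& b) {
  if (a.p != b.p) return a.p < b.p;
  for (int k = 0; k < a.t; ++k)
    if (a.snps[k] != b.snps[k]) return a.snps[k] < b.snps[k];
  return false;
}

static List recs_to_list(std::vector<Rec>& recs, int t, int l,
                         long long n_untestable) {
  std::sort(recs.begin(), recs.end(), rec_less);
  const int k = std::min<int>(l, (int)recs.size());
  IntegerMatrix idx(k, t);
  NumericVector p(k), chi2(k);
  IntegerVector df(k), d(k);
  for (int r = 0; r < k; ++r) {
    for (int c = 0; c < t; ++c) idx(r, c) = recs[r].snps[c];
    p[r] = recs[r].p; chi2[r] = recs[r].chi2;
    df[r] = recs[r].df; d[r] = recs[r].d;
  }
  return List::create(_["idx"] = idx, _["p"] = p, _["chi2"] = chi2,
                      _["df"] = df, _["d"] = d,
                      _["n_untestable"] = (double)n_untestable);
}

// [[Rcpp::export]]
List cpp_pair_scan(RawVector case_raw, RawVector ctrl_raw, int wc, int wt,
                   int M, IntegerVector i_set0, int l) {
  const uint64_t* cw = reinterpret_cast<const uint64_t*>(RAW(case_raw));
  const uint64_t* tw = reinterpret_cast<const uint64_t*>(RAW(ctrl_raw));
  std::vector<Rec> recs;
  long long n_untestable = 0;
  int cc[9], tc[9], snps[2];
  for (int a = 0; a < i_set0.size(); ++a) {
    const int i = i_set0[a];
    if (i < 0 || i >= M) stop("SNP index out of range");
    for (int j = i + 1; j < M; ++j) {
      snps[0] = i; snps[1] = j;
      count_cells(cw, tw, wc, wt, snps, 2, cc, tc);
      Rec r; r.t = 2; r.snps = {i, j, -1, -1};
      if (table_best_p(cc, tc, 9, r.p, r.chi2, r.df, r.d)) recs.push_back(r);
      else ++n_untestable;
    }
    Rcpp::checkUserInterrupt();
  }
  return recs_to_list(recs, 2, l, n_untestable);
}

// [[Rcpp::export]]
List cpp_extend_scan(RawVector case_raw, RawVector ctrl_raw, int wc, int wt,
                     int M, IntegerMatrix seeds0, int l) {
  const int t = seeds0.ncol() + 1;
  if (t < 3 || t > 4) stop("extension supports orders 3 and 4");
  if ((t == 3 && M >= (1 << 21)) || (t == 4 && M >= (1 << 16)))
    stop("extension tuple hashing supports M < 2^21 (t=3) / 2^16 (t=4)");
  const uint64_t* cw = reinterpret_cast<const uint64_t*>(RAW(case_raw));
  const uint64_t* tw = reinterpret_cast<const uint64_t*>(RAW(ctrl_raw));
  std::unordered_set<uint64_t> seen;
  std::vector<Rec> recs;
  long long n_untestable = 0;
  const int ncell = (t == 3) ? 27 : 81;
  std::vector<int> cc(ncell), tc(ncell);
  int tuple[4];
  for (int s = 0; s < seeds0.nrow(); ++s) {
    for (int m = 0; m < M; ++m) {
      bool dup = false;
      for (int k = 0; k < t - 1; ++k) {
        tuple[k] = seeds0(s, k);
        if (tuple[k] == m) dup = true;
      }
      if (dup) continue;
      tuple[t - 1] = m;
      std::sort(tuple, tuple + t);
      uint64_t key = 0;
      for (int k = 0; k < t; ++k)
        key = (key << ((t == 3) ? 21 : 16)) | (uint64_t)(tuple[k] + 1);
      if (!seen.insert(key).second) continue;
      count_cells(cw, tw, wc, wt, tuple, t, cc.data(), tc.data());
      Rec r; r.t = t;
      r.snps = {tuple[0], tuple[1], tuple[2], (t == 4) ? tuple[3] : -1};
      if (table_best_p(cc.data(), tc.data(), ncell, r.p, r.chi2, r.df, r.d))
        recs.push_back(r);
      else ++n_untestable;
    }
    Rcpp::checkUserInterrupt();
  }
  return recs_to_list(recs, t, l, n_untestable);
}
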