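#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Depth-first enumeration of admissible peak-to-compound assignments.
//
// Peaks are visited in retention-time order; compounds are identified by
// their 1-based position among the targets (positions strictly increase
// exactly when elution order is preserved).  `adm` holds, per peak, the
// ascending positions admissible under the RT cutoff window and the
// internal-standard partition; `allow_int`/`force_int` control interferent
// branches.  The full candidate set is never materialized beyond the output:
// state is one prefix per recursion depth.

namespace {

struct Cand {
  std::vector<int> a;  // 0 = interferent, else target position
  int lib;             // 0-based index into retained trajectories
  double ssr;
  double msr;
  int ninterf;
};

// ranking order: ascending msr, fewer interferents, lexicographically
// smaller assignment, smaller library index (= label order)
bool better(const Cand& x, const Cand& y) {
  if (x.msr != y.msr) return x.msr < y.msr;
  if (x.ninterf != y.ninterf) return x.ninterf < y.ninterf;
  if (x.a != y.a) return x.a < y.a;
  return x.lib < y.lib;
}

struct MatchCtx {
  int m, L, n_std, max_results;
  std::vector<std::vector<int> > adm;
  std::vector<char> allow_int, force_int;
  std::vector<char> int_ok;  // m x L: peak far enough from lib l's values
                             // to be a voluntary interferent there
  const double* lib_rt;  // n_tgt x L, column-major
  int n_tgt;
  std::vector<double> ssr_std;
  std::vector<double> peak_rt;
  std::vector<Cand> top;  // kept sorted by better()
  double n_candidates, n_vacuous;
  std::vector<int> cur;
  std::vector<double> resid;  // per-lib partial SSR (targets only)
  std::vector<int> viol;      // per-lib count of gate-violating interferents
};

void match_leaf(MatchCtx& c, int ninterf) {
  int denom = c.n_std + c.m - ninterf;
  if (denom <= 0) { c.n_vacuous += 1.0; return; }
  int best_lib = -1;
  double best_msr = 0.0, best_ssr = 0.0;
  for (int l = 0; l < c.L; ++l) {
    if (c.viol[l] > 0) continue;  // an interferent label is inconsistent here
    double ssr = c.ssr_std[l] + c.resid[l];
    double msr = ssr / denom;
    if (best_lib < 0 || msr < best_msr) {
      best_lib = l; best_msr = msr; best_ssr = ssr;
    }
  }
  if (best_lib < 0) return;  // no trajectory consistent with the labels
  c.n_candidates += 1.0;
  if ((int)c.top.size() == c.max_results && best_msr > c.top.back().msr)
    return;
  Cand cand;
  cand.a = c.cur; cand.lib = best_lib; cand.ssr = best_ssr;
  cand.msr = best_msr; cand.ninterf = ninterf;
  std::vector<Cand>::iterator it =
      std::upper_bound(c.top.begin(), c.top.end(), cand, better);
  c.top.insert(it, cand);
  if ((int)c.top.size() > c.max_results) c.top.pop_back();
}

void match_dfs(MatchCtx& c, int j, int last, int ninterf) {
  if (j == c.m) { match_leaf(c, ninterf); return; }
  // branch-and-bound: residuals only grow, denominator can only shrink
  if ((int)c.top.size() == c.max_results) {
    double min_num = R_PosInf;
    for (int l = 0; l < c.L; ++l) {
      if (c.viol[l] > 0) continue;
      double num = c.ssr_std[l] + c.resid[l];
      if (num < min_num) min_num = num;
    }
    int max_denom = c.n_std + c.m - ninterf;
    if (max_denom > 0 && min_num / max_denom > c.top.back().msr) return;
  }
  const std::vector<int>& opts = c.adm[j];
  if (!c.force_int[j]) {
    for (size_t i = 0; i < opts.size(); ++i) {
      int pos = opts[i];
      if (pos <= last) continue;
      c.cur[j] = pos;
      double d, *r = &c.resid[0];
      for (int l = 0; l < c.L; ++l) {
        d = c.lib_rt[(size_t)l * c.n_tgt + (pos - 1)] - c.peak_rt[j];
        r[l] += d * d;
      }
      match_dfs(c, j + 1, pos, ninterf);
      for (int l = 0; l < c.L; ++l) {
        d = c.lib_rt[(size_t)l * c.n_tgt + (pos - 1)] - c.peak_rt[j];
        c.resid[l] -= d * d;
      }
    }
  }
  if (c.force_int[j] || c.allow_int[j]) {
    c.cur[j] = 0;
    bool any_ok = false;
    if (!c.force_int[j]) {  // forced labels carry no gate obligation
      for (int l = 0; l < c.L; ++l) {
        if (!c.int_ok[(size_t)j * c.L + l]) c.viol[l] += 1;
        if (c.viol[l] == 0) any_ok = true;
      }
    } else {
      for (int l = 0; l < c.L; ++l)
        if (c.viol[l] == 0) { any_ok = true; break; }
    }
    if (any_ok) match_dfs(c, j + 1, last, ninterf + 1);
    if (!c.force_int[j])
      for (int l = 0; l < c.L; ++l)
        if (!c.int_ok[(size_t)j * c.L + l]) c.viol[l] -= 1;
  }
  c.cur[j] = -1;
}

}  // namespace

// [[Rcpp::export(name = ".rtt_dfs_match")]]
List rtt_dfs_match(NumericVector peak_rt, List adm, LogicalVector allow_int,
                   LogicalVector force_int, LogicalMatrix int_ok,
                   NumericMatrix lib_rt, NumericVector ssr_std, int n_std,
                   int max_results) {
  MatchCtx c;
  c.m = peak_rt.size();
  c.L = lib_rt.ncol();
  c.n_tgt = lib_rt.nrow();
  c.n_std = n_std;
  c.max_results = max_results;
  c.lib_rt = lib_rt.begin();
  c.ssr_std = as<std::vector<double> >(ssr_std);
  c.peak_rt = as<std::vector<double> >(peak_rt);
  c.adm.resize(c.m);
  for (int j = 0; j < c.m; ++j) c.adm[j] = as<std::vector<int> >(adm[j]);
  c.allow_int.assign(allow_int.begin(), allow_int.end());
  c.force_int.assign(force_int.begin(), force_int.end());
  c.int_ok.assign((size_t)c.m * c.L, 1);  // row-major: peak j, lib l
  for (int j = 0; j < c.m; ++j)
    for (int l = 0; l < c.L; ++l)
      c.int_ok[(size_t)j * c.L + l] = int_ok(j, l);
  c.cur.assign(c.m, -1);
  c.resid.assign(c.L, 0.0);
  c.viol.assign(c.L, 0);
  c.n_candidates = c.n_vacuous = 0.0;
  match_dfs(c, 0, 0, 0);

  int k = c.top.size();
  IntegerMatrix assign(k, c.m);
  IntegerVector lib(k), ninterf(k);
  NumericVector ssr(k), msr(k);
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < c.m; ++j) assign(i, j) = c.top[i].a[j];
    lib[i] = c.top[i].lib + 1;
    ninterf[i] = c.top[i].ninterf;
    ssr[i] = c.top[i].ssr;
    msr[i] = c.top[i].msr;
  }
  return List::create(_["n_candidates"] = c.n_candidates,
                      _["n_vacuous"] = c.n_vacuous,
                      _["assign"] = assign, _["lib"] = lib,
                      _["ssr"] = ssr, _["msr"] = msr,
                      _["n_interf"] = ninterf);
}

namespace {

struct EnumCtx {
  int m;
  std::vector<std::vector<int> > adm;
  std::vector<char> allow_int, force_int;
  bool collect;
  double max_collect;
  double count;
  std::vector<int> cur;
  std::vector<int> out;  // row-appended candidates
};

void enum_dfs(EnumCtx& c, int j, int last) {
  if (j == c.m) {
    c.count += 1.0;
    if (c.collect) {
      if (c.count > c.max_collect)
        stop("candidate stream exceeds max_collect; use collect = FALSE");
      c.out.insert(c.out.end(), c.cur.begin(), c.cur.end());
    }
    return;
  }
  if (!c.force_int[j]) {
    const std::vector<int>& opts = c.adm[j];
    for (size_t i = 0; i < opts.size(); ++i) {
      int pos = opts[i];
      if (pos <= last) continue;
      c.cur[j] = pos;
      enum_dfs(c, j + 1, pos);
    }
  }
  if (c.force_int[j] || c.allow_int[j]) {
    c.cur[j] = 0;
    enum_dfs(c, j + 1, last);
  }
}

}  // namespace

// [[Rcpp::export(name = ".rtt_dfs_enumerate")]]
List rtt_dfs_enumerate(int m, List adm, LogicalVector allow_int,
                       LogicalVector force_int, bool collect,
                       double max_collect) {
  EnumCtx c;
  c.m = m;
  c.adm.resize(m);
  for (int j = 0; j < m; ++j) c.adm[j] = as<std::vector<int> >(adm[j]);
  c.allow_int.assign(allow_int.begin(), allow_int.end());
  c.force_int.assign(force_int.begin(), force_int.end());
  c.collect = collect;
  c.max_collect = max_collect;
  c.count = 0.0;
  c.cur.assign(m, -1);
  enum_dfs(c, 0, 0);
  List res = List::create(_["count"] = c.count);
  if (collect) {
    int k = (int)c.count;
    IntegerMatrix out(k, m);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < m; ++j) out(i, j) = c.out[(size_t)i * m + j];
    res["assign"] = out;
  }
  return res;
}
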