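#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// beta-mean-nearest-taxon-distance between two communities given
// support indices, within-site relative-abundance weights, and a
// label permutation of the distance matrix (tip-shuffle null).
static double bmntd_pair(const std::vector<int>& ia,
                         const std::vector<double>& fa,
                         const std::vector<int>& ib,
                         const std::vector<double>& fb,
                         const NumericMatrix& D,
                         const IntegerVector& perm) {
  double acc = 0.0;
  for (size_t i = 0; i < ia.size(); ++i) {
    const int pi = perm[ia[i]];
    double mn = R_PosInf;
    for (size_t j = 0; j < ib.size(); ++j) {
      const double d = D(pi, perm[ib[j]]);
      if (d < mn) mn = d;
    }
    acc += fa[i] * mn;
  }
  for (size_t j = 0; j < ib.size(); ++j) {
    const int pj = perm[ib[j]];
    double mn = R_PosInf;
    for (size_t i = 0; i < ia.size(); ++i) {
      const double d = D(pj, perm[ia[i]]);
      if (d < mn) mn = d;
    }
    acc += fb[j] * mn;
  }
  return 0.5 * acc;
}

static void supports(const NumericMatrix& rel,
                     std::vector< std::vector<int> >& idx,
                     std::vector< std::vector<double> >& wt) {
  const int S = rel.nrow(), N = rel.ncol();
  idx.assign(S, std::vector<int>());
  wt.assign(S, std::vector<double>());
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < N; ++j)
      if (rel(s, j) > 0) {
        idx[s].push_back(j);
        wt[s].push_back(rel(s, j));
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix rel, NumericMatrix D) {
  const int S = rel.nrow();
  std::vector< std::vector<int> > idx;
  std::vector< std::vector<double> > wt;
  supports(rel, idx, wt);
  IntegerVector id(rel.ncol());
  for (int j = 0; j < rel.ncol(); ++j) id[j] = j;
  NumericMatrix out(S, S);
  for (int a = 0; a < S - 1; ++a)
    for (int b = a + 1; b < S; ++b)
      out(a, b) = out(b, a) =
        bmntd_pair(idx[a], wt[a], idx[b], wt[b], D, id);
  return out;
}

// observed betaMNTD plus null mean/sd over tip-label permutations
// (perms: reps x N, zero-based)
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix rel, NumericMatrix D,
                   IntegerMatrix perms) {
  const int S = rel.nrow(), reps = perms.nrow();
  std::vector< std::vector<int> > idx;
  std::vector< std::vector<double> > wt;
  supports(rel, idx, wt);
  IntegerVector id(rel.ncol());
  for (int j = 0; j < rel.ncol(); ++j) id[j] = j;
  NumericMatrix obs(S, S), msum(S, S), m2sum(S, S);
  for (int a = 0; a < S - 1; ++a)
    for (int b = a + 1; b < S; ++b)
      obs(a, b) = obs(b, a) =
        bmntd_pair(idx[a], wt[a], idx[b], wt[b], D, id);
  for (int r = 0; r < reps; ++r) {
    IntegerVector perm = perms(r, _);
    for (int a = 0; a < S - 1; ++a)
      for (int b = a + 1; b < S; ++b) {
        const double v =
          bmntd_pair(idx[a], wt[a], idx[b], wt[b], D, perm);
        msum(a, b) += v;
        m2sum(a, b) += v * v;
      }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix nmean(S, S), nsd(S, S);
  for (int a = 0; a < S - 1; ++a)
    for (int b = a + 1; b < S; ++b) {
      const double mu = msum(a, b) / reps;
      double var = (m2sum(a, b) - reps * mu * mu) / (reps - 1.0);
      if (var < 0) var = 0;
      nmean(a, b) = nmean(b, a) = mu;
      nsd(a, b) = nsd(b, a) = std::sqrt(var);
    }
  return List::create(_["obs"] = obs, _["nullMean"] = nmean,
                      _["nullSd"] = nsd);
}

// weighted sampling without replacement (Efraimidis-Spirakis keys),
// using R's RNG so results are reproducible under set.seed()
static void sample_wor(int k, const NumericVector& w, std::vector<int>& out) {
  const int N = w.size();
  std::vector< std::pair<double, int> > keys;
  keys.reserve(N);
  for (int j = 0; j < N; ++j)
    if (w[j] > 0)
      keys.push_back(std::make_pair(std::log(unif_rand()) / w[j], j));
  if ((int)keys.size() < k)
    stop("richness exceeds the number of taxa with positive weight");
  std::partial_sort(keys.begin(), keys.begin() + k, keys.end(),
                    std::greater< std::pair<double, int> >());
  out.resize(k);
  for (int i = 0; i < k; ++i) out[i] = keys[i].second;
}

// sequential-binomial multinomial draw of n individuals over probs p
static void rmultinom_seq(int n, const std::vector<double>& p,
                          std::vector<int>& out) {
  const int k = p.size();
  out.assign(k, 0);
  double rest = 0.0;
  for (int j = 0; j < k; ++j) rest += p[j];
  for (int j = 0; j < k && n > 0; ++j) {
    if (p[j] <= 0) continue;
    double pr = p[j] / rest;
    if (pr > 1) pr = 1;
    const int x = (j == k - 1 || pr >= 1.0)
      ? n : (int)::Rf_rbinom((double)n, pr);
    out[j] = x;
    n -= x;
    rest -= p[j];
    if (rest <= 0 && n > 0) { out[j] += n; n = 0; }
  }
}

// Raup-Crick (Bray-Curtis) null for one site pair: reassemble each
// community by drawing its observed richness (weights occw), giving each
// drawn taxon one individual, and distributing the remaining individuals
// multinomially in proportion to regional relative abundances (regp).
// Returns the reps null Bray-Curtis values, or the null communities
// themselves when return_null is true.
// [[Rcpp::export]]
SEXP cpp_rcbray_null(int rich1, int tot1, int rich2, int tot2,
                     NumericVector occw, NumericVector regp, int reps,
                     bool return_null = false) {
  const int N = occw.size();
  NumericVector bc(reps);
  IntegerMatrix nulls;
  if (return_null) nulls = IntegerMatrix(2 * reps, N);
  std::vector<int> s1, s2, c1(N), c2(N), extra;
  std::vector<double> psub;
  for (int r = 0; r < reps; ++r) {
    std::fill(c1.begin(), c1.end(), 0);
    std::fill(c2.begin(), c2.end(), 0);
    sample_wor(rich1, occw, s1);
    psub.resize(rich1);
    for (int i = 0; i < rich1; ++i) psub[i] = regp[s1[i]];
    rmultinom_seq(tot1 - rich1, psub, extra);
    for (int i = 0; i < rich1; ++i) c1[s1[i]] = 1 + extra[i];
    sample_wor(rich2, occw, s2);
    psub.resize(rich2);
    for (int i = 0; i < rich2; ++i) psub[i] = regp[s2[i]];
    rmultinom_seq(tot2 - rich2, psub, extra);
    for (int i = 0; i < rich2; ++i) c2[s2[i]] = 1 + extra[i];
    double num = 0;
    for (int j = 0; j < N; ++j) num += std::abs(c1[j] - c2[j]);
    bc[r] = num / (double)(tot1 + tot2);
    if (return_null)
      for (int j = 0; j < N; ++j) {
        nulls(2 * r, j) = c1[j];
        nulls(2 * r + 1, j) = c2[j];
      }
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  if (return_null)
    return List::create(_["bc"] = bc, _["nulls"] = nulls);
  return bc;
}
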