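// Forward Wright-Fisher simulation of a haploid population of haplotypes
// under the infinite-sites mutation model, with uniform recombination along a
// physical region and optional positive selection at a single site. Used by
// simulate_haplotypes(); randomness comes from R's RNG so set.seed() makes
// runs reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<signed char> Hap;

struct Pop {
  int N;
  double L;
  std::vector<Hap> hap;        // N haplotypes, each with S entries
  std::vector<double> pos;     // S site positions (unsorted during the run)
};

static inline int sample_weighted(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// One non-overlapping generation. sweep_col < 0 means neutral.
static void next_generation(Pop &P, double mu_region, double rec_region,
                            int sweep_col, double s) {
  const int N = P.N;
  const int S = (int)P.pos.size();
  std::vector<double> cumw(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (sweep_col >= 0 && P.hap[i][sweep_col]) w += s;
    acc += w;
    cumw[i] = acc;
  }
  std::vector<Hap> next(N);
  std::vector<double> bp;
  for (int i = 0; i < N; ++i) {
    int pa = sample_weighted(cumw);
    int nrec = (int)R::rpois(rec_region);
    if (nrec == 0 || S == 0) {
      next[i] = P.hap[pa];
    } else {
      int pb = sample_weighted(cumw);
      bp.resize(nrec);
      for (int k = 0; k < nrec; ++k) bp[k] = unif_rand() * P.L;
      std::sort(bp.begin(), bp.end());
      Hap &child = next[i];
      child.resize(S);
      const Hap &A = P.hap[pa];
      const Hap &B = P.hap[pb];
      for (int j = 0; j < S; ++j) {
        int seg = (int)(std::upper_bound(bp.begin(), bp.end(), P.pos[j]) -
                        bp.begin());
        child[j] = (seg % 2 == 0) ? A[j] : B[j];
      }
    }
  }
  P.hap.swap(next);
  int nmut = (int)R::rpois((double)N * mu_region);
  for (int m = 0; m < nmut; ++m) {
    double x = unif_rand() * P.L;
    int carrier = (int)(unif_rand() * N);
    if (carrier == N) carrier = N - 1;
    for (int i = 0; i < N; ++i) P.hap[i].push_back(i == carrier ? 1 : 0);
    P.pos.push_back(x);
  }
}

// Drop columns fixed or lost; returns the new index of tracked_col (or -1).
static int purge_monomorphic(Pop &P, int tracked_col) {
  const int N = P.N;
  const int S = (int)P.pos.size();
  std::vector<int> keep;
  keep.reserve(S);
  int new_tracked = -1;
  for (int j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < N; ++i) c += P.hap[i][j];
    bool poly = (c > 0 && c < N);
    if (poly || j == tracked_col) {
      if (j == tracked_col) new_tracked = (int)keep.size();
      keep.push_back(j);
    }
  }
  if ((int)keep.size() == S) return tracked_col;
  std::vector<double> npos(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) npos[k] = P.pos[keep[k]];
  for (int i = 0; i < N; ++i) {
    Hap nh(keep.size());
    for (size_t k = 0; k < keep.size(); ++k) nh[k] = P.hap[i][keep[k]];
    P.hap[i].swap(nh);
  }
  P.pos.swap(npos);
  return new_tracked;
}

static double allele_freq(const Pop &P, int col) {
  int c = 0;
  for (int i = 0; i < P.N; ++i) c += P.hap[i][col];
  return (double)c / P.N;
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_pop, int n_gen, double mu_region, double rec_region,
                double region_length, double sweep_pos = -1.0,
                double sel_coef = 0.0, double target_freq = 0.0,
                int max_sweep_gen = 10000, int max_restarts = 100) {
  Pop P;
  P.N = n_pop;
  P.L = region_length;
  P.hap.assign(n_pop, Hap());

  for (int g = 0; g < n_gen; ++g) {
    next_generation(P, mu_region, rec_region, -1, 0.0);
    if (g % 20 == 19) purge_monomorphic(P, -1);
    if (g % 200 == 0) Rcpp::checkUserInterrupt();
  }
  purge_monomorphic(P, -1);

  int sweep_col = -1;
  int restarts = 0;
  bool swept = false;
  if (sweep_pos >= 0.0) {
    Pop snapshot = P;  // state at the end of the neutral burn-in
    for (restarts = 0; restarts <= max_restarts && !swept; ++restarts) {
      P = snapshot;
      int carrier = (int)(unif_rand() * P.N);
      if (carrier == P.N) carrier = P.N - 1;
      for (int i = 0; i < P.N; ++i)
        P.hap[i].push_back(i == carrier ? 1 : 0);
      P.pos.push_back(sweep_pos);
      sweep_col = (int)P.pos.size() - 1;
      for (int g = 0; g < max_sweep_gen; ++g) {
        next_generation(P, mu_region, rec_region, sweep_col, sel_coef);
        double f = allele_freq(P, sweep_col);
        if (f <= 0.0) break;                 // lost: restart
        if (f >= target_freq) { swept = true; break; }
        if (g % 20 == 19) sweep_col = purge_monomorphic(P, sweep_col);
        if (g % 200 == 0) Rcpp::checkUserInterrupt();
      }
    }
    if (!swept)
      stop("sweep allele lost before reaching target frequency after %d restarts",
           restarts);
    restarts -= 1;  // loop increments once past the successful attempt
    sweep_col = purge_monomorphic(P, sweep_col);
  } else {
    // final purge already done above
  }

  // order sites by physical position
  const int S = (int)P.pos.size();
  std::vector<int> ord(S);
  for (int j = 0; j < S; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return P.pos[a] < P.pos[b]; });
  IntegerMatrix H(n_pop, S);
  NumericVector pos(S);
  int sweep_out = -1;
  for (int k = 0; k < S; ++k) {
    pos[k] = P.pos[ord[k]];
    if (ord[k] == sweep_col) sweep_out = k + 1;  // 1-based for R
    for (int i = 0; i < n_pop; ++i) H(i, k) = P.hap[i][ord[k]];
  }
  return List::create(_["haplotypes"] = H, _["positions"] = pos,
                      _["sweep_index"] = sweep_out,
                      _["restarts"] = restarts);
}
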