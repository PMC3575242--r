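#include <Rcpp.h>
using namespace Rcpp;

// 2x2 chi-square (no continuity correction) for a window of h sites each
// side of a candidate breakpoint: rows = left/right half-window, columns =
// match/mismatch of the sequence pair. Degenerate margins give 0.
static double chi2_2x2(int h, int misL, int misR) {
  double a = h - misL, b = misL, c = h - misR, d = misR;
  double colM = a + c, colX = b + d;
  if (colM <= 0.0 || colX <= 0.0) return 0.0;
  double det = a * d - b * c;
  return 2.0 * h * det * det / ((double)h * (double)h * colM * colX);
}

static double max_over_boundaries(const std::vector<int>& cum, int S, int h,
                                  int* argk) {
  double best = -1.0;
  int bestk = -1;
  for (int k = h; k <= S - h; ++k) {
    int L = cum[k] - cum[k - h];
    int R = cum[k + h] - cum[k];
    double c = chi2_2x2(h, L, R);
    if (c > best + 1e-12) { best = c; bestk = k; } // leftmost wins on ties
  }
  if (argk) *argk = bestk;
  return best;
}

// Observed maximum chi-square for a pair's mismatch indicator over the
// considered (segregating) sites. Returns the statistic and the 1-based
// boundary index k (breakpoint lies between considered sites k and k+1).
// [[Rcpp::export]]
List maxchi_stat_cpp(IntegerVector mis, int h) {
  int S = mis.size();
  if (S < 2 * h)
    return List::create(_["stat"] = NA_REAL, _["k"] = NA_INTEGER);
  std::vector<int> cum(S + 1, 0);
  for (int i = 0; i < S; ++i) cum[i + 1] = cum[i] + (mis[i] ? 1 : 0);
  int argk = -1;
  double best = max_over_boundaries(cum, S, h, &argk);
  return List::create(_["stat"] = best, _["k"] = argk);
}

// xorshift64: fast generator for the permutation inner loop, seeded from
// R's RNG so results remain reproducible under set.seed().
static inline uint64_t xorshift64(uint64_t& s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

// Monte-Carlo null distribution of the maximum chi-square, shared across
// half-widths. Permuting a 0/1 mismatch vector within blocks only depends
// on the per-block mismatch counts, so one null serves every pair with
// the same counts. `block_sizes` / `block_mis`: sites and mismatches per
// block (blocks delimit previously accepted breakpoints). Returns an
// nperm x length(hs) matrix of null maxima (NA where 2h > S). A random
// mismatch placement is drawn per block by partial Fisher-Yates (only the
// mismatch positions are shuffled), and the 2x2 chi-square is read from a
// per-h lookup table over (misL, misR).
// [[Rcpp::export]]
NumericMatrix maxchi_null_cpp(IntegerVector block_sizes, IntegerVector block_mis,
                              IntegerVector hs, int nperm) {
  int nb = block_sizes.size();
  int S = 0;
  for (int b = 0; b < nb; ++b) S += block_sizes[b];
  std::vector<int> starts(nb);
  {
    int s = 0;
    for (int b = 0; b < nb; ++b) { starts[b] = s; s += block_sizes[b]; }
  }
  int nh = hs.size();
  NumericMatrix out(nperm, nh);

  // chi2 lookup tables: lut[hi][misL * (h+1) + misR]
  std::vector< std::vector<double> > lut(nh);
  for (int hi = 0; hi < nh; ++hi) {
    int h = hs[hi];
    lut[hi].resize((h + 1) * (h + 1));
    for (int a = 0; a <= h; ++a)
      for (int b = 0; b <= h; ++b)
        lut[hi][a * (h + 1) + b] = chi2_2x2(h, a, b);
  }

  // per-block index pools for partial Fisher-Yates
  std::vector< std::vector<int> > pool(nb);
  for (int b = 0; b < nb; ++b) {
    pool[b].resize(block_sizes[b]);
    for (int i = 0; i < block_sizes[b]; ++i) pool[b][i] = starts[b] + i;
  }

  uint64_t state;
  {
    RNGScope scope;
    state = ((uint64_t)(unif_rand() * 4294967295.0) << 32) ^
            (uint64_t)(unif_rand() * 4294967295.0);
    if (state == 0) state = 0x9E3779B97F4A7C15ull;
  }

  std::vector<int> cum(S + 1, 0);
  std::vector<int> x(S, 0);
  for (int p = 0; p < nperm; ++p) {
    std::fill(x.begin(), x.end(), 0);
    for (int b = 0; b < nb; ++b) {
      int n = block_sizes[b], m = block_mis[b];
      std::vector<int>& idx = pool[b];
      // draw m positions without replacement; a partial shuffle of an
      // already-permuted pool still yields a uniform random subset
      for (int i = 0; i < m; ++i) {
        int j = i + (int)(xorshift64(state) % (uint64_t)(n - i));
        std::swap(idx[i], idx[j]);
        x[idx[i]] = 1;
      }
    }
    for (int i = 0; i < S; ++i) cum[i + 1] = cum[i] + x[i];
    for (int hi = 0; hi < nh; ++hi) {
      int h = hs[hi];
      if (S < 2 * h) { out(p, hi) = NA_REAL; continue; }
      const std::vector<double>& L = lut[hi];
      double best = 0.0;
      for (int k = h; k <= S - h; ++k) {
        int a = cum[k] - cum[k - h];
        int b = cum[k + h] - cum[k];
        double c = L[a * (h + 1) + b];
        if (c > best) best = c;
      }
      out(p, hi) = best;
    }
  }
  return out;
}
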