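// Compiled kernels: frequency-domain noise synthesis, threshold-free cluster
// enhancement (TFCE) on the electrode grid, and the max-statistic permutation
// loop. RcppArmadillo's alternative RNG draws from R's generator, so all
// randomness here is governed by set.seed() at the R level.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

// Gaussian noise with a prescribed amplitude spectrum.
//
// One complex spectrum per *pair* of output channels: for circularly
// symmetric complex Gaussian spectra the real and imaginary parts of the
// inverse FFT are two independent real signals with identical power spectra,
// halving FFT and RNG cost. `amp` holds per-FFT-bin amplitudes over the full
// (two-sided) frequency grid of length n_fft >= n_samples; output is trimmed
// to n_samples columns (channels x samples). When `shared_fraction > 0` one
// extra common-mode trace with the same spectrum (scaled by the fraction)
// is added to every channel.
//
// Synthesis runs in single precision (matching acquisition-hardware data
// width) with an internal xoshiro256++ stream seeded from R's generator, so
// set.seed() fully determines the output while synthesis stays fast.

namespace {
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 seeding
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54; }
};

void fill_spectrum(arma::cx_fmat& S, const arma::fvec& amp, Xoshiro256pp& rng) {
  const arma::uword nf = S.n_rows;
  for (arma::uword j = 0; j < S.n_cols; ++j) {
    std::complex<float>* col = S.colptr(j);
    for (arma::uword i = 0; i < nf; ++i) {
      const float r =
          std::sqrt(-2.0f * std::log((float)rng.unif())) * amp[i];
      const float th = (float)(2.0 * M_PI * rng.unif());
      col[i] = std::complex<float>(r * std::cos(th), r * std::sin(th));
    }
  }
}
}  // namespace

// [[Rcpp::export]]
arma::mat cpp_colored_noise(const int n_samples, const int n_channels,
                            const arma::vec& amp,
                            const double shared_fraction = 0.0) {
  const int nf = amp.n_elem;
  if (nf < n_samples) stop("amp shorter than n_samples");
  const int ncx = (n_channels + 1) / 2;
  // one draw from R's stream seeds the internal generator
  Xoshiro256pp rng((uint64_t)(unif_rand() * 9007199254740992.0));
  arma::fvec ampf = arma::conv_to<arma::fvec>::from(amp);
  arma::cx_fmat S(nf, ncx);
  fill_spectrum(S, ampf, rng);
  arma::cx_fmat y = arma::ifft(S);
  arma::mat out(n_channels, n_samples);
  for (int j = 0; j < ncx; ++j) {
    const std::complex<float>* col = y.colptr(j);
    double* r0 = out.memptr() + 2 * j;
    for (int i = 0; i < n_samples; ++i)
      r0[(size_t)i * n_channels] = col[i].real();
    if (2 * j + 1 < n_channels) {
      double* r1 = out.memptr() + 2 * j + 1;
      for (int i = 0; i < n_samples; ++i)
        r1[(size_t)i * n_channels] = col[i].imag();
    }
  }
  if (shared_fraction > 0.0) {
    arma::cx_fmat Ssh(nf, 1);
    fill_spectrum(Ssh, ampf * (float)shared_fraction, rng);
    arma::cx_fvec ysh = arma::ifft(Ssh.col(0));
    for (int i = 0; i < n_samples; ++i) {
      const double v = ysh[i].real();
      double* cptr = out.colptr(i);
      for (int c = 0; c < n_channels; ++c) cptr[c] += v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// TFCE on a rectangular grid with 8-neighbour connectivity.
//
// score(c) = sum over thresholds h in {dh, 2dh, ..., <= max(stat)} of
//            h^H * extent(c, h)^E * dh
// where extent(c, h) is the size of the 8-connected component of
// {cells >= h} containing c. NA cells are unoccupied (skipped).

static void tfce_accumulate(const double* stat, double* score, int nr, int nc,
                            double H, double E, double dh,
                            std::vector<int>& comp, std::vector<int>& stack) {
  const int n = nr * nc;
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    score[i] = 0.0;
    if (!ISNAN(stat[i]) && stat[i] > mx) mx = stat[i];
  }
  if (mx < dh) return;
  const int nlev = (int)std::floor(mx / dh + 1e-9);
  for (int lev = 1; lev <= nlev; ++lev) {
    const double h = lev * dh;
    const double hH = std::pow(h, H);
    std::fill(comp.begin(), comp.end(), -1);
    for (int i = 0; i < n; ++i) {
      if (comp[i] >= 0 || ISNAN(stat[i]) || stat[i] < h) continue;
      // flood fill the component seeded at i
      int sz = 0;
      stack.clear();
      stack.push_back(i);
      comp[i] = i;
      std::vector<int> members;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        members.push_back(cur);
        ++sz;
        const int r = cur % nr, c = cur / nr;  // column-major grid
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            const int idx = rr + cc * nr;
            if (comp[idx] >= 0 || ISNAN(stat[idx]) || stat[idx] < h) continue;
            comp[idx] = i;
            stack.push_back(idx);
          }
        }
      }
      const double add = hH * std::pow((double)sz, E) * dh;
      for (int m : members) score[m] += add;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_tfce(const NumericMatrix stat, const double H,
                       const double E, const double dh) {
  const int nr = stat.nrow(), nc = stat.ncol();
  NumericMatrix score(nr, nc);
  std::vector<int> comp(nr * nc), stack;
  tfce_accumulate(stat.begin(), score.begin(), nr, nc, H, E, dh, comp, stack);
  for (int i = 0; i < nr * nc; ++i)
    if (ISNAN(stat[i])) score[i] = NA_REAL;
  return score;
}

// ---------------------------------------------------------------------------
// Max-statistic permutation engine.
//
// power:   channels x trials matrix of per-trial band power
// labels:  0/1 per trial (1 = movement), defining the observed assignment
// perms:   n_perm x trials matrix of 0/1 permuted assignments
// cell_of: 0-based grid cell index (r + c*n_rows) per channel, -1 if unmapped
// stat_type: 0 = signed R^2 (pooled population variance is permutation-
//            invariant and precomputed), 1 = pooled-variance Student t.
// Returns observed stat per channel plus the per-permutation maxima of the
// positive- and negative-direction TFCE scores over the grid.

static void stat_map(const arma::mat& power, const std::vector<int>& mov_idx,
                     const std::vector<int>& rest_idx, const arma::vec& tot_sum,
                     const arma::vec& pooled_var, const int stat_type,
                     arma::vec& out) {
  const int C = power.n_rows;
  const int Nm = mov_idx.size(), Nr = rest_idx.size();
  const int N = Nm + Nr;
  arma::vec ms(C, arma::fill::zeros);
  for (int t : mov_idx) ms += power.col(t);
  const arma::vec rs = tot_sum - ms;
  const arma::vec mbar = ms / Nm, rbar = rs / Nr;
  if (stat_type == 0) {
    const double fac = (double)Nm * Nr / ((double)N * N);
    for (int c = 0; c < C; ++c) {
      const double d = mbar[c] - rbar[c];
      out[c] = (pooled_var[c] > 0.0)
                   ? ((d > 0) - (d < 0)) * d * d * fac / pooled_var[c]
                   : 0.0;
    }
  } else {
    // pooled-variance two-sample t
    arma::vec ssm(C, arma::fill::zeros), ssr(C, arma::fill::zeros);
    for (int t : mov_idx) ssm += arma::square(power.col(t));
    for (int t : rest_idx) ssr += arma::square(power.col(t));
    for (int c = 0; c < C; ++c) {
      const double vm = ssm[c] - Nm * mbar[c] * mbar[c];
      const double vr = ssr[c] - Nr * rbar[c] * rbar[c];
      const double sp2 = (vm + vr) / std::max(N - 2, 1);
      const double se = std::sqrt(sp2 * (1.0 / Nm + 1.0 / Nr));
      out[c] = (se > 0.0) ? (mbar[c] - rbar[c]) / se : 0.0;
    }
  }
}

// [[Rcpp::export]]
List cpp_perm_max_tfce(const arma::mat& power, const IntegerVector labels,
                       const IntegerMatrix perms, const IntegerVector cell_of,
                       const int n_rows, const int n_cols, const double H,
                       const double E, const double dh, const int stat_type) {
  const int C = power.n_rows, T = power.n_cols;
  const int n_perm = perms.nrow();
  if ((int)labels.size() != T) stop("labels length mismatch");
  if ((int)cell_of.size() != C) stop("cell_of length mismatch");

  const arma::vec tot_sum = arma::sum(power, 1);
  // population-convention pooled variance over the union of all trials
  arma::vec pooled_var(C);
  {
    const arma::vec mu = tot_sum / T;
    const arma::vec ss = arma::sum(arma::square(power), 1);
    pooled_var = ss / T - arma::square(mu);
    pooled_var.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  }

  const int ncell = n_rows * n_cols;
  std::vector<double> grid(ncell), score(ncell);
  std::vector<int> comp(ncell), stack;
  arma::vec st(C);

  auto embed_max = [&](const arma::vec& s, const double sign) -> double {
    std::fill(grid.begin(), grid.end(), NA_REAL);
    for (int c = 0; c < C; ++c)
      if (cell_of[c] >= 0) grid[cell_of[c]] = sign * s[c];
    tfce_accumulate(grid.data(), score.data(), n_rows, n_cols, H, E, dh, comp,
                    stack);
    double mx = 0.0;
    for (int i = 0; i < ncell; ++i)
      if (!ISNAN(grid[i]) && score[i] > mx) mx = score[i];
    return mx;
  };

  std::vector<int> mov, rest;
  for (int t = 0; t < T; ++t) (labels[t] == 1 ? mov : rest).push_back(t);
  if (mov.empty() || rest.empty()) stop("both conditions must be non-empty");
  stat_map(power, mov, rest, tot_sum, pooled_var, stat_type, st);
  NumericVector observed(st.begin(), st.end());

  NumericVector max_pos(n_perm), max_neg(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    mov.clear();
    rest.clear();
    for (int t = 0; t < T; ++t)
      (perms(p, t) == 1 ? mov : rest).push_back(t);
    if (mov.empty() || rest.empty()) stop("degenerate permutation");
    stat_map(power, mov, rest, tot_sum, pooled_var, stat_type, st);
    max_pos[p] = embed_max(st, 1.0);
    max_neg[p] = embed_max(st, -1.0);
  }
  return List::create(_["observed"] = observed, _["max_pos"] = max_pos,
                      _["max_neg"] = max_neg);
}

// Per-epoch multitaper band power.
//
// x: samples x channels voltage; starts: 0-based start sample per window;
// tapers: window_len x n_tapers DPSS matrix; bdft_re/bdft_im: n_band x
// window_len DFT rows for the retained band bins. Returns an
// (n_windows x n_band x channels)-shaped cube flattened as a list of
// matrices? No: returns n_windows x n_band power summed over tapers for each
// channel stacked row-wise: (n_windows*channels) x n_band.
// x is channels x samples (the session layout). `car_mean` (length
// n_samples) is subtracted from every channel during segment gather
// (common-average referencing fused into the windowing); pass a length-0
// vector to skip. `include[c] == 0` zero-imputes channel c.
// [[Rcpp::export]]
arma::mat cpp_window_band_power(const arma::mat& x, const IntegerVector starts,
                                const arma::mat& tapers, const arma::mat& bdft_re,
                                const arma::mat& bdft_im,
                                const arma::vec& car_mean,
                                const IntegerVector include) {
  const int L = tapers.n_rows, K = tapers.n_cols;
  const int nw = starts.size(), C = x.n_rows, nb = bdft_re.n_rows;
  const bool car = car_mean.n_elem > 0;
  if (car && (int)car_mean.n_elem != (int)x.n_cols)
    stop("car_mean length mismatch");
  if (include.size() != C) stop("include length mismatch");
  arma::mat out(nw * C, nb, arma::fill::zeros);
  // per taper, fold the taper into the band-restricted DFT rows once
  std::vector<arma::mat> Wre(K), Wim(K);
  for (int k = 0; k < K; ++k) {
    Wre[k] = bdft_re.each_row() % tapers.col(k).t();
    Wim[k] = bdft_im.each_row() % tapers.col(k).t();
  }
  arma::mat seg(L, nw);
  for (int ch = 0; ch < C; ++ch) {
    if (!include[ch]) continue;  // zero-imputed: power rows stay 0
    const double* xp = x.memptr() + ch;
    for (int w = 0; w < nw; ++w) {
      double* sp = seg.colptr(w);
      const int s0 = starts[w];
      if (car)
        for (int i = 0; i < L; ++i)
          sp[i] = xp[(size_t)(s0 + i) * C] - car_mean[s0 + i];
      else
        for (int i = 0; i < L; ++i) sp[i] = xp[(size_t)(s0 + i) * C];
    }
    arma::mat acc(nb, nw, arma::fill::zeros);
    for (int k = 0; k < K; ++k)
      acc += arma::square(Wre[k] * seg) + arma::square(Wim[k] * seg);
    out.rows(ch * nw, ch * nw + nw - 1) = acc.t() / K;
  }
  return out;
}
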