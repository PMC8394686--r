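// Amplitude-adjusted Fourier-transform (AAFT) surrogates with iterative
// spectrum/amplitude refinement. Per channel the surrogate is an exact
// permutation of the observed values whose power spectrum is matched to the
// original as closely as the iteration allows; phases are drawn from R's RNG
// so surrogate generation is reproducible via set.seed(). Real-input FFTs
// (FFTW, half-spectrum) keep the surrogate bootstrap tractable.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>

using arma::uvec;
using arma::vec;

// indices that sort x ascending; stable, so ties keep first-occurrence order
static uvec stable_order(const double *x, arma::uword n) {
  uvec idx = arma::regspace<uvec>(0, n - 1);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](arma::uword a, arma::uword b) { return x[a] < x[b]; });
  return idx;
}

// overwrite positions given by the rank pattern of `pattern` with the
// ascending values `sorted_vals`
static void rank_remap(const double *pattern, const vec &sorted_vals,
                       double *out, arma::uword n) {
  uvec ord = stable_order(pattern, n);
  for (arma::uword i = 0; i < n; ++i) out[ord[i]] = sorted_vals[i];
}

// RAII wrapper around one channel's FFTW state (half-spectrum r2c/c2r)
struct ChannelFFT {
  arma::uword T, nb;
  double *buf;
  fftw_complex *spec;
  fftw_plan fwd, bwd;
  explicit ChannelFFT(arma::uword T_)
      : T(T_), nb(T_ / 2 + 1),
        buf(fftw_alloc_real(T_)),
        spec(fftw_alloc_complex(T_ / 2 + 1)),
        fwd(fftw_plan_dft_r2c_1d((int)T_, buf, spec, FFTW_ESTIMATE)),
        bwd(fftw_plan_dft_c2r_1d((int)T_, spec, buf, FFTW_ESTIMATE)) {}
  ~ChannelFFT() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
    fftw_free(buf);
    fftw_free(spec);
  }
  void forward(const double *x) {
    std::copy(x, x + T, buf);
    fftw_execute(fwd);
  }
  // inverse transform of `spec` into `buf` (unnormalized; callers only use
  // the result through rank ordering, which is scale-invariant)
  void inverse() { fftw_execute(bwd); }
};

static double spec_abs(const fftw_complex &c) {
  return std::hypot(c[0], c[1]);
}

static vec aaft_channel(const vec &x, int max_iter, double tol) {
  const arma::uword T = x.n_elem;
  vec xs = arma::sort(x);
  if (xs[0] == xs[T - 1])
    Rcpp::stop("AAFT surrogate undefined for a constant channel");

  ChannelFFT f(T);
  const arma::uword nb = f.nb;
  const bool even = (T % 2 == 0);
  // target amplitude half-spectrum and L2 weights (interior bins count twice
  // in the full spectrum; DC and, for even T, Nyquist once)
  f.forward(x.memptr());
  vec S(nb), w(nb, arma::fill::value(2.0));
  for (arma::uword k = 0; k < nb; ++k) S[k] = spec_abs(f.spec[k]);
  w[0] = 1.0;
  if (even) w[nb - 1] = 1.0;
  const double Snorm2 = arma::accu(w % arma::square(S));

  // (a) remap onto an ordered Gaussian sample by the data's ranks
  vec g(T);
  for (arma::uword i = 0; i < T; ++i) g[i] = norm_rand();
  vec y(T);
  rank_remap(x.memptr(), arma::sort(g), y.memptr(), T);
  // (b) randomize the Fourier phases of the Gaussianized series
  // (amplitudes kept; DC and Nyquist bins untouched)
  f.forward(y.memptr());
  const arma::uword last = even ? nb - 2 : nb - 1;
  for (arma::uword k = 1; k <= last; ++k) {
    double amp = spec_abs(f.spec[k]);
    double phi = unif_rand() * 2.0 * M_PI;
    f.spec[k][0] = amp * std::cos(phi);
    f.spec[k][1] = amp * std::sin(phi);
  }
  f.inverse();
  // (c) remap back onto the original amplitudes
  vec s(T);
  rank_remap(f.buf, xs, s.memptr(), T);

  // iterative refinement: enforce the target spectrum, restore amplitudes,
  // until the relative spectral mismatch stops improving by more than tol
  double prev = arma::datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    f.forward(s.memptr());
    double acc = 0.0;
    for (arma::uword k = 0; k < nb; ++k) {
      double d = spec_abs(f.spec[k]) - S[k];
      acc += w[k] * d * d;
    }
    double err = std::sqrt(acc / Snorm2);
    if (prev - err < tol) break;
    prev = err;
    for (arma::uword k = 0; k < nb; ++k) {
      double m = spec_abs(f.spec[k]);
      if (m > 0.0) {
        double sc = S[k] / m;
        f.spec[k][0] *= sc;
        f.spec[k][1] *= sc;
      } else {
        f.spec[k][0] = S[k];
        f.spec[k][1] = 0.0;
      }
    }
    f.inverse();
    rank_remap(f.buf, xs, s.memptr(), T);
  }
  return s;
}

// [[Rcpp::export]]
arma::mat cpp_aaft_panel(const arma::mat &X, int max_iter, double tol) {
  arma::mat out(X.n_rows, X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j)
    out.col(j) = aaft_channel(X.col(j), max_iter, tol);
  return out;
}
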