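// IAAFT inner loop and windowed detrending.
//
// The IAAFT iteration alternates spectral adjustment (impose the original
// amplitude spectrum on the current surrogate's phases) with rank replacement
// (impose the original value distribution), tracking the relative L2
// discrepancy between the surrogate's and the original's amplitude spectra.
// Hot path: two length-N DFTs plus one stable sort per iteration. Envelope
// lengths are arbitrary (often with large prime factors, where generic
// mixed-radix FFTs degrade towards O(N^2)), so DFTs of non-smooth lengths go
// through Bluestein's chirp-z algorithm on a power-of-two grid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

bool smooth235(uword n) {
  for (uword p : {2u, 3u, 5u}) while (n % p == 0) n /= p;
  return n == 1;
}

// DFT plan for a fixed length: direct mixed-radix for 2^a 3^b 5^c lengths,
// Bluestein otherwise (chirp premultiply + circular convolution of length m,
// m a power of two >= 2n-1, with the chirp kernel's FFT cached).
struct DftPlan {
  uword n = 0, m = 0;
  bool direct = true;
  cx_vec chirp;  // exp(-i pi j^2 / n)
  cx_vec bfft;   // FFT of the circularly extended conjugate chirp

  explicit DftPlan(uword n_) : n(n_), direct(smooth235(n_)) {
    if (direct) return;
    m = 1;
    while (m < 2 * n - 1) m <<= 1;
    chirp.set_size(n);
    cx_vec b(m, fill::zeros);
    for (uword j = 0; j < n; ++j) {
      // reduce j^2 mod 2n before dividing: keeps the phase accurate
      double ang = datum::pi * static_cast<double>((j * j) % (2 * n)) / n;
      chirp(j) = cx_double(std::cos(ang), -std::sin(ang));
      b(j) = std::conj(chirp(j));
      if (j > 0) b(m - j) = b(j);
    }
    bfft = fft(b);
  }

  cx_vec forward(const cx_vec& x) const {
    if (direct) return fft(x);
    cx_vec a(m, fill::zeros);
    a.head(n) = x % chirp;
    cx_vec c = ifft(fft(a) % bfft);
    return c.head(n) % chirp;
  }

  cx_vec forward_real(const vec& x) const {
    return forward(conv_to<cx_vec>::from(x));
  }

  // unitary-up-to-1/n inverse DFT via conjugation
  cx_vec inverse(const cx_vec& x) const {
    if (direct) return ifft(x);
    return conj(forward(conj(x))) / static_cast<double>(n);
  }
};

} // namespace

// [[Rcpp::export]]
arma::cx_vec dft_ref(const arma::vec& x) {
  DftPlan plan(x.n_elem);
  return plan.forward_real(x);
}

// [[Rcpp::export]]
Rcpp::List iaaft_core(const arma::vec& x, const arma::vec& r0,
                      int max_iter, double tol) {
  const uword n = x.n_elem;
  DftPlan plan(n);
  vec amp = abs(plan.forward_real(x));
  const double amp_norm = norm(amp, 2);
  vec sorted_x = sort(x);

  vec best = r0;
  double best_disc = datum::inf;
  std::vector<double> trace;
  trace.reserve(max_iter);

  cx_vec F = plan.forward_real(r0);
  vec r_new(n);
  for (int it = 0; it < max_iter; ++it) {
    vec mod = abs(F);
    mod.replace(0.0, 1.0); // zero bin: phase undefined, keep unit gain
    cx_vec G = F % conv_to<cx_vec>::from(amp / mod);
    vec cand = real(plan.inverse(G));
    uvec idx = stable_sort_index(cand);
    for (uword j = 0; j < n; ++j) r_new(idx(j)) = sorted_x(j);
    cx_vec Fn = plan.forward_real(r_new);
    double disc = norm(abs(Fn) - amp, 2) / amp_norm;
    if (disc >= best_disc) break; // no further improvement
    double improved = best_disc - disc;
    best = r_new;
    best_disc = disc;
    trace.push_back(disc);
    F = Fn;
    if (std::isfinite(improved) && improved < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("surrogate") = best,
                            Rcpp::Named("trace") = trace);
}

// Per-window mean-square residuals of OLS line fits, both-ends windowing:
// floor(N/s) windows from the start, then the same number counted from the
// end. Closed-form line fit against t = 1..s.
// [[Rcpp::export]]
arma::vec f2_windows(const arma::vec& Y, int s) {
  const uword n = Y.n_elem;
  const uword m = n / s;
  vec t = linspace<vec>(1, s, s);
  const double tbar = (s + 1) / 2.0;
  vec tc = t - tbar;
  const double stt = dot(tc, tc);
  vec out(2 * m);
  for (uword v = 0; v < 2 * m; ++v) {
    uword start = (v < m) ? v * s : n - (v - m + 1) * s;
    vec w = Y.subvec(start, start + s - 1);
    double b = dot(tc, w) / stt;
    vec resid = w - mean(w) - b * tc;
    out(v) = dot(resid, resid) / s;
  }
  return out;
}
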