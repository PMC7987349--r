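// Inner loops of the pulse-echo simulator and the delay-and-sum beamformer.
// All quantities here are SI (metres, seconds, Hz); R wrappers convert from
// the mm/MHz/degree public interface.
#include <Rcpp.h>
using namespace Rcpp;

// Accumulate Gaussian-enveloped tone bursts from point scatterers into
// per-element channel data. Transmit delay is the steered plane-wave arrival
// plus the transducer-to-mirror path; receive delay is the Euclidean
// element-to-scatterer distance plus the same mirror path.
// [[Rcpp::export]]
NumericMatrix rf_sim_core(NumericVector sx, NumericVector sy, NumericVector sz,
                          NumericVector amp, NumericVector ex, double c,
                          double fs, int nt, double f0, double sigma_t,
                          double steer_rad, double path_offset) {
  const int ns = sx.size(), ne = ex.size();
  NumericMatrix out(nt, ne);
  const double cs = std::cos(steer_rad), sn = std::sin(steer_rad);
  const double win = 4.0 * sigma_t;
  const double inv2s2 = 1.0 / (2.0 * sigma_t * sigma_t);
  const double w0 = 2.0 * M_PI * f0;
  const double h = 1.0 / fs;
  // burst samples are uniformly spaced, so the Gaussian envelope factors into
  // exp(-a^2) * q^k * g[k] (g[k] = exp(-h^2 k^2 / (2 sigma^2)) tabulated) and
  // the carrier follows the two-term cosine recurrence; the inner loop is
  // then multiply/add only.
  const int kmax = (int)std::ceil(2.0 * win * fs) + 2;
  std::vector<double> gk(kmax + 1);
  for (int k = 0; k <= kmax; ++k) gk[k] = std::exp(-h * h * k * k * inv2s2);
  const double cb2 = 2.0 * std::cos(w0 * h);
  for (int e = 0; e < ne; ++e) {
    double *col = &out(0, e);
    for (int s = 0; s < ns; ++s) {
      if (amp[s] == 0.0) continue;
      const double tx = (path_offset + sz[s] * cs + sx[s] * sn) / c;
      const double dx = sx[s] - ex[e];
      const double rx =
          (path_offset + std::sqrt(dx * dx + sy[s] * sy[s] + sz[s] * sz[s])) / c;
      const double tau = tx + rx;
      int i0 = (int)std::ceil((tau - win) * fs);
      int i1 = (int)std::floor((tau + win) * fs);
      if (i0 < 0) i0 = 0;
      if (i1 > nt - 1) i1 = nt - 1;
      if (i1 < i0) continue;
      const double a = i0 * h - tau;
      double env = amp[s] * std::exp(-a * a * inv2s2);
      const double q = std::exp(-a * h * 2.0 * inv2s2);
      double c0 = std::cos(w0 * a);
      double c1 = std::cos(w0 * (a + h));
      int k = 0;
      for (int i = i0; i <= i1; ++i, ++k) {
        col[i] += env * gk[k] * c0;
        env *= q;
        const double c2 = cb2 * c1 - c0;
        c0 = c1;
        c1 = c2;
      }
    }
  }
  return out;
}

// Delay-and-sum on analytic (complex) channel data: for each pixel sum
// linearly interpolated channel samples at the two-way delay, with receive
// apodization weights. Pixels are given as flattened (px, pz) positions with
// pz the axial distance from the mirror plate centre.
// [[Rcpp::export]]
List das_core(NumericMatrix ch_re, NumericMatrix ch_im, NumericVector ex,
              NumericVector apod, double c, double fs, double t0,
              double steer_rad, double path_offset, NumericVector px,
              NumericVector pz) {
  const int nt = ch_re.nrow(), ne = ch_re.ncol(), np = px.size();
  NumericVector ore(np), oim(np);
  const double cs = std::cos(steer_rad), sn = std::sin(steer_rad);
  for (int p = 0; p < np; ++p) {
    const double txd = (path_offset + pz[p] * cs + px[p] * sn) / c;
    double re = 0.0, im = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double dx = px[p] - ex[e];
      const double tau =
          txd + (path_offset + std::sqrt(dx * dx + pz[p] * pz[p])) / c;
      const double u = (tau - t0) * fs;
      const int i = (int)std::floor(u);
      if (i < 0 || i + 1 >= nt) continue;
      const double f = u - i;
      re += apod[e] * ((1.0 - f) * ch_re(i, e) + f * ch_re(i + 1, e));
      im += apod[e] * ((1.0 - f) * ch_im(i, e) + f * ch_im(i + 1, e));
    }
    ore[p] = re;
    oim[p] = im;
  }
  return List::create(_["re"] = ore, _["im"] = oim);
}
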