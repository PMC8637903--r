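// Numerical cores: point-scatterer RF synthesis, delay-and-sum beamforming,
// and constant-velocity Kalman track likelihood. Units at this level are
// millimetres and microseconds (c ~ 1.54 mm/us, rates in MHz).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Insert a delayed, attenuated copy of `waveform` into every channel record
// for every scatterer. Transmit path is the steered plane-wave distance
// z*cos(theta) + x*sin(theta) (plus the t0 reference offset so delays stay
// positive across steering angles); receive path is the element distance.
// Amplitude: 1/r spherical spreading on receive, bulk frequency-independent
// attenuation over the round-trip path at the centre frequency, plus a global
// extra attenuation (skull stand-in) in dB.
// [[Rcpp::export]]
arma::mat simulateEchoesCpp(const arma::vec& bx, const arma::vec& bz,
                            const arma::vec& bamp, const arma::vec& elemX,
                            double angleRad, const arma::vec& waveform,
                            double cMmUs, double fsMhz, int nTime,
                            double attenDbPerCmMhz, double f0Mhz,
                            double extraAttenDb, double t0Us,
                            const arma::vec& channelDelayUs) {
  const int nch = elemX.n_elem;
  const int nb = bx.n_elem;
  const int lw = waveform.n_elem;
  arma::mat out(nTime, nch, arma::fill::zeros);
  const double st = std::sin(angleRad), ct = std::cos(angleRad);
  const double skull = std::pow(10.0, -extraAttenDb / 20.0);
  for (int b = 0; b < nb; ++b) {
    const double dtx = bz[b] * ct + bx[b] * st;  // mm
    for (int e = 0; e < nch; ++e) {
      const double dx = bx[b] - elemX[e];
      const double drx = std::sqrt(dx * dx + bz[b] * bz[b]);
      const double tau = t0Us + (dtx + drx) / cMmUs + channelDelayUs[e];
      const double pathCm = (dtx + drx) / 10.0;
      double amp = bamp[b] / std::max(drx, 1.0) * skull *
                   std::pow(10.0, -attenDbPerCmMhz * f0Mhz * pathCm / 20.0);
      const double s = tau * fsMhz;
      const int i0 = (int)std::floor(s);
      const double frac = s - i0;
      // linear-interpolation sub-sample shift of the waveform
      for (int j = 0; j <= lw; ++j) {
        const int k = i0 + j;
        if (k < 0 || k >= nTime) continue;
        double wj = 0.0;
        if (j < lw) wj += (1.0 - frac) * waveform[j];
        if (j >= 1) wj += frac * waveform[j - 1];
        out(k, e) += amp * wj;
      }
    }
  }
  return out;
}

// Delay-and-sum of analytic (complex) channel data onto a pixel list, with
// receive f-number aperture control and Hann apodization, normalized by the
// apodization sum. Pixel delays beyond the record contribute zero.
// [[Rcpp::export]]
arma::cx_vec dasBeamformCpp(const arma::cx_mat& rf, const arma::vec& elemX,
                            double angleRad, const arma::vec& px,
                            const arma::vec& pz, double cMmUs, double fsMhz,
                            double t0Us, double fNumber,
                            const arma::vec& channelDelayUs) {
  const int nt = rf.n_rows, nch = rf.n_cols;
  const int npix = px.n_elem;
  arma::cx_vec out(npix, arma::fill::zeros);
  const double st = std::sin(angleRad), ct = std::cos(angleRad);
  const double exMin = elemX.min(), exMax = elemX.max();
  const double pitch = (nch > 1) ? (exMax - exMin) / (nch - 1) : 1.0;
  for (int p = 0; p < npix; ++p) {
    const double x = px[p], z = pz[p];
    const double dtx = z * ct + x * st;
    const double halfAp =
        (fNumber > 0) ? z / (2.0 * fNumber) : arma::datum::inf;
    // the Hann taper must reach zero at whichever limit binds -- the
    // f-number aperture or the physical array edge -- else the truncated
    // window leaves strong lateral sidelobes for pixels near the edges
    const double halfL = std::min(halfAp, x - exMin + pitch);
    const double halfR = std::min(halfAp, exMax - x + pitch);
    std::complex<double> acc(0.0, 0.0);
    double wsum = 0.0;
    for (int e = 0; e < nch; ++e) {
      const double dx = x - elemX[e];
      const double half = (dx >= 0) ? halfL : halfR;
      if (half <= 0.0 || std::abs(dx) > half) continue;
      const double w = std::isfinite(half)
                           ? 0.5 + 0.5 * std::cos(M_PI * dx / half)
                           : 1.0;
      const double drx = std::sqrt(dx * dx + z * z);
      const double s =
          (t0Us + (dtx + drx) / cMmUs + channelDelayUs[e]) * fsMhz;
      const int i0 = (int)std::floor(s);
      if (i0 < 0 || i0 + 1 >= nt) continue;
      const double frac = s - i0;
      acc += w * ((1.0 - frac) * rf(i0, e) + frac * rf(i0 + 1, e));
      wsum += w;
    }
    out[p] = (wsum > 0.0) ? acc / wsum : std::complex<double>(0.0, 0.0);
  }
  return out;
}

// Raw delayed channel samples for one angle (no apodization/summing); the
// pixel x channel matrix feeds the eigenspace/minimum-variance beamformer.
// [[Rcpp::export]]
arma::cx_mat delayChannelsCpp(const arma::cx_mat& rf, const arma::vec& elemX,
                              double angleRad, const arma::vec& px,
                              const arma::vec& pz, double cMmUs, double fsMhz,
                              double t0Us, const arma::vec& channelDelayUs) {
  const int nt = rf.n_rows, nch = rf.n_cols;
  const int npix = px.n_elem;
  arma::cx_mat out(npix, nch, arma::fill::zeros);
  const double st = std::sin(angleRad), ct = std::cos(angleRad);
  for (int p = 0; p < npix; ++p) {
    const double x = px[p], z = pz[p];
    const double dtx = z * ct + x * st;
    for (int e = 0; e < nch; ++e) {
      const double dx = x - elemX[e];
      const double drx = std::sqrt(dx * dx + z * z);
      const double s =
          (t0Us + (dtx + drx) / cMmUs + channelDelayUs[e]) * fsMhz;
      const int i0 = (int)std::floor(s);
      if (i0 < 0 || i0 + 1 >= nt) continue;
      const double frac = s - i0;
      out(p, e) = (1.0 - frac) * rf(i0, e) + frac * rf(i0 + 1, e);
    }
  }
  return out;
}

// Innovation log-likelihood of a detection sequence under a nearly-constant-
// velocity model, run as two independent 1-D position/velocity Kalman
// filters (x and z). frames are integer frame indices (gaps allowed);
// sigmaP is the per-frame position diffusion, kappa the velocity-diffusion
// fraction (per-frame velocity noise = kappa * sigmaP * frameRate).
// [[Rcpp::export]]
double cvTrackLogLikCpp(const arma::ivec& frames, const arma::vec& x,
                        const arma::vec& z, double sigmaM, double sigmaP,
                        double kappa, double velPriorSd, double frameRate) {
  const int n = frames.n_elem;
  if (n < 2) return 0.0;
  const double r = sigmaM * sigmaM;
  const double sigVel = kappa * sigmaP * frameRate;
  double ll = 0.0;
  for (int dim = 0; dim < 2; ++dim) {
    const arma::vec& obs = (dim == 0) ? x : z;
    // state (p, v); covariance entries p00 p01 p11
    double sp = obs[0], sv = 0.0;
    double p00 = r, p01 = 0.0, p11 = velPriorSd * velPriorSd;
    for (int i = 1; i < n; ++i) {
      const double df = (double)(frames[i] - frames[i - 1]);
      const double dt = df / frameRate;
      // predict
      const double pp = sp + sv * dt;
      double q00 = sigmaP * sigmaP * df;
      double q11 = sigVel * sigVel * df;
      double a00 = p00 + 2.0 * dt * p01 + dt * dt * p11 + q00;
      double a01 = p01 + dt * p11;
      double a11 = p11 + q11;
      // innovation
      const double nu = obs[i] - pp;
      const double S = a00 + r;
      ll += -0.5 * (std::log(2.0 * M_PI * S) + nu * nu / S);
      // update
      const double k0 = a00 / S, k1 = a01 / S;
      sp = pp + k0 * nu;
      sv = sv + k1 * nu;
      p00 = (1.0 - k0) * a00;
      p01 = (1.0 - k0) * a01;
      p11 = a11 - k1 * a01;
    }
  }
  return ll;
}
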