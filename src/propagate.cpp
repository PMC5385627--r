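#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

inline void mat3_mult(const double *A, const double *B, double *C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

// Rodrigues matrix about unit axis w/||w|| by angle ||w||/fs (row-major).
inline void rodrigues(const double *w, double fs, double *T) {
  double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (nw == 0.0) {
    T[0] = 1; T[1] = 0; T[2] = 0;
    T[3] = 0; T[4] = 1; T[5] = 0;
    T[6] = 0; T[7] = 0; T[8] = 1;
    return;
  }
  double th = nw / fs;
  double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  double x = w[0] / nw, y = w[1] / nw, z = w[2] / nw;
  T[0] = t * x * x + c;     T[1] = t * x * y - s * z; T[2] = t * x * z + s * y;
  T[3] = t * x * y + s * z; T[4] = t * y * y + c;     T[5] = t * y * z - s * x;
  T[6] = t * x * z - s * y; T[7] = t * y * z + s * x; T[8] = t * z * z + c;
}

inline double ortho_error(const double *R) {
  double e = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double dot = R[3 * i] * R[3 * j] + R[3 * i + 1] * R[3 * j + 1] +
                   R[3 * i + 2] * R[3 * j + 2];
      double target = (i == j) ? 1.0 : 0.0;
      double d = std::fabs(dot - target);
      if (d > e) e = d;
    }
  return e;
}

// Newton iteration towards the orthogonal polar factor:
// R <- 1.5 R - 0.5 R R^T R (converges quadratically for small drift).
inline void reorthonormalize(double *R) {
  double RtR[9], RRtR[9];
  for (int it = 0; it < 3; ++it) {
    double Rt[9] = {R[0], R[3], R[6], R[1], R[4], R[7], R[2], R[5], R[8]};
    mat3_mult(Rt, R, RtR);
    mat3_mult(R, RtR, RRtR);
    for (int k = 0; k < 9; ++k) R[k] = 1.5 * R[k] - 0.5 * RRtR[k];
    if (ortho_error(R) < 1e-14) break;
  }
}

} // namespace

// [[Rcpp::export]]
List propagate_core(NumericMatrix gyro, double fs, NumericMatrix R0,
                    int start) {
  int n = gyro.nrow();
  NumericMatrix Rout(n, 9), euler(n, 3);
  NumericVector gwz(n);
  colnames(euler) = CharacterVector::create("roll", "pitch", "yaw");
  double R[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = R0(i, j);
  int n_reortho = 0;
  const double rad2deg = 180.0 / M_PI;
  for (int i = 0; i < n; ++i) {
    if (i + 1 > start) {
      // advance with the gyro sample at the left endpoint of the interval
      double wS[3] = {gyro(i - 1, 0), gyro(i - 1, 1), gyro(i - 1, 2)};
      double wG[3] = {R[0] * wS[0] + R[1] * wS[1] + R[2] * wS[2],
                      R[3] * wS[0] + R[4] * wS[1] + R[5] * wS[2],
                      R[6] * wS[0] + R[7] * wS[1] + R[8] * wS[2]};
      double T[9], Rn[9];
      rodrigues(wG, fs, T);
      mat3_mult(T, R, Rn);
      for (int k = 0; k < 9; ++k) R[k] = Rn[k];
      if (ortho_error(R) > 1e-6) {
        reorthonormalize(R);
        ++n_reortho;
      }
    }
    for (int k = 0; k < 9; ++k) Rout(i, k) = R[k];
    gwz[i] = R[6] * gyro(i, 0) + R[7] * gyro(i, 1) + R[8] * gyro(i, 2);
    double sp = -R[6];
    if (sp > 1.0) sp = 1.0;
    if (sp < -1.0) sp = -1.0;
    euler(i, 0) = std::atan2(R[7], R[8]) * rad2deg;
    euler(i, 1) = std::asin(sp) * rad2deg;
    double yaw = std::atan2(R[3], R[0]) * rad2deg;
    if (yaw <= -180.0) yaw += 360.0;
    euler(i, 2) = yaw;
  }
  return List::create(_["R"] = Rout, _["euler"] = euler, _["gwz"] = gwz,
                      _["n_reortho"] = n_reortho);
}
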