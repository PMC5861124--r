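// Monte Carlo kernels: half-molecule chain sampling, cube-binned pair
// counting under the closure tolerances, and tangent-correlation
// accumulation. Rotations are carried as unit quaternions throughout;
// the step rotation for a Cayley vector theta (|theta| = 2 tan(phi/2)) is
// the normalized quaternion (1, theta/2), and the midframe (half-step)
// rotation is the normalized quaternion midpoint with the identity.

#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct Quat {
  double w, x, y, z;
};

static inline Quat qmul(const Quat &a, const Quat &b) {
  return Quat{a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

// rotate vector v by unit quaternion q
static inline void qrotate(const Quat &q, const double *v, double *out) {
  // t = 2 q_vec x v ; out = v + w t + q_vec x t
  double tx = 2.0 * (q.y * v[2] - q.z * v[1]);
  double ty = 2.0 * (q.z * v[0] - q.x * v[2]);
  double tz = 2.0 * (q.x * v[1] - q.y * v[0]);
  out[0] = v[0] + q.w * tx + (q.y * tz - q.z * ty);
  out[1] = v[1] + q.w * ty + (q.z * tx - q.x * tz);
  out[2] = v[2] + q.w * tz + (q.x * ty - q.y * tx);
}

// Sample M half-molecule end states for the steps [i0, i1] (1-based,
// inclusive) of a molecule with intrinsic step coordinates thetaHat/transHat
// (3 x N), per-coordinate Gaussian sds sdTheta/sdTrans (length 3; a zero sd
// freezes that coordinate at its intrinsic value). For first halves the
// stored position is -T^{-1} r of the raw end state (so closure is a direct
// position comparison with second-half ends); the stored quaternion is always
// the raw accumulated rotation of the sub-chain.
// [[Rcpp::export(name = ".cpp_sample_half")]]
List cpp_sample_half(NumericMatrix thetaHat, NumericMatrix transHat,
                     NumericVector sdTheta, NumericVector sdTrans,
                     int i0, int i1, int M, double seed, bool firstHalf) {
  const int nstep = i1 - i0 + 1;
  if (nstep < 1) stop("empty step range");
  NumericMatrix pos(M, 3), quat(M, 4);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double st1 = sdTheta[0], st2 = sdTheta[1], st3 = sdTheta[2];
  const double sa1 = sdTrans[0], sa2 = sdTrans[1], sa3 = sdTrans[2];
  const bool ext = (sa1 > 0) || (sa2 > 0) || (sa3 > 0);

  // contiguous local copies of the intrinsic steps for the sampled range
  std::vector<double> hat(6 * nstep);
  for (int i = 0; i < nstep; ++i) {
    hat[6 * i]     = thetaHat(0, i0 - 1 + i);
    hat[6 * i + 1] = thetaHat(1, i0 - 1 + i);
    hat[6 * i + 2] = thetaHat(2, i0 - 1 + i);
    hat[6 * i + 3] = transHat(0, i0 - 1 + i);
    hat[6 * i + 4] = transHat(1, i0 - 1 + i);
    hat[6 * i + 5] = transHat(2, i0 - 1 + i);
  }

  for (int m = 0; m < M; ++m) {
    double r[3] = {0.0, 0.0, 0.0};
    Quat q{1.0, 0.0, 0.0, 0.0};
    const double *h = hat.data();
    for (int i = 0; i < nstep; ++i, h += 6) {
      double th[3], a[3];
      th[0] = h[0] + (st1 > 0 ? st1 * gauss(rng) : 0.0);
      th[1] = h[1] + (st2 > 0 ? st2 * gauss(rng) : 0.0);
      th[2] = h[2] + (st3 > 0 ? st3 * gauss(rng) : 0.0);
      if (ext) {
        a[0] = h[3] + (sa1 > 0 ? sa1 * gauss(rng) : 0.0);
        a[1] = h[4] + (sa2 > 0 ? sa2 * gauss(rng) : 0.0);
        a[2] = h[5] + (sa3 > 0 ? sa3 * gauss(rng) : 0.0);
      } else {
        a[0] = h[3]; a[1] = h[4]; a[2] = h[5];
      }
      // step quaternion (1, th/2) and its half-angle companion, normalized
      // by reciprocal square roots
      double n2 = 1.0 + 0.25 * (th[0] * th[0] + th[1] * th[1] + th[2] * th[2]);
      double inv = 1.0 / std::sqrt(n2);
      Quat qs{inv, 0.5 * inv * th[0], 0.5 * inv * th[1], 0.5 * inv * th[2]};
      double nh = 1.0 / std::sqrt(2.0 * (1.0 + qs.w));
      Quat qh{(qs.w + 1.0) * nh, qs.x * nh, qs.y * nh, qs.z * nh};
      Quat qmid = qmul(q, qh);
      double disp[3];
      qrotate(qmid, a, disp);
      r[0] += disp[0]; r[1] += disp[1]; r[2] += disp[2];
      q = qmul(q, qs);
      if ((i & 31) == 31) qnormalize(q);
    }
    qnormalize(q);
    if (firstHalf) {
      // store -T^{-1} r; T^{-1} is rotation by the conjugate quaternion
      Quat qc{q.w, -q.x, -q.y, -q.z};
      double rr[3];
      qrotate(qc, r, rr);
      pos(m, 0) = -rr[0]; pos(m, 1) = -rr[1]; pos(m, 2) = -rr[2];
    } else {
      pos(m, 0) = r[0]; pos(m, 1) = r[1]; pos(m, 2) = r[2];
    }
    quat(m, 0) = q.w; quat(m, 1) = q.x; quat(m, 2) = q.y; quat(m, 3) = q.z;
  }
  return List::create(_["pos"] = pos, _["quat"] = quat);
}

// Count closing pairs by cube binning. Points of the first ensemble are
// sorted into cells of size (wxy, wxy, wz); each second-half point queries
// its 3x3x3 cell neighborhood, prunes on |dz| <= eps, then the full
// Euclidean distance, then the SO(3) distance sin(phi/2) <= delta of the
// composed rotation T_first * T_second (quaternion scalar part test).
// Cell widths must be >= eps for the neighborhood search to be exhaustive;
// the R wrapper enforces that.
// [[Rcpp::export(name = ".cpp_pair_count")]]
double cpp_pair_count(NumericMatrix pos1, NumericMatrix quat1,
                      NumericMatrix pos2, NumericMatrix quat2,
                      double eps, double delta, double wxy, double wz) {
  const int M1 = pos1.nrow(), M2 = pos2.nrow();
  const double eps2 = eps * eps;
  // delta-test: sin(phi/2)^2 = 1 - w_tot^2 <= delta^2
  const double wmin2 = 1.0 - delta * delta;
  if (eps <= 0.0 || M1 == 0 || M2 == 0) return 0.0;

  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) {
    mn[d] = R_PosInf; mx[d] = R_NegInf;
  }
  for (int m = 0; m < M1; ++m)
    for (int d = 0; d < 3; ++d) {
      double v = pos1(m, d);
      if (v < mn[d]) mn[d] = v;
      if (v > mx[d]) mx[d] = v;
    }
  for (int m = 0; m < M2; ++m)
    for (int d = 0; d < 3; ++d) {
      double v = pos2(m, d);
      if (v < mn[d]) mn[d] = v;
      if (v > mx[d]) mx[d] = v;
    }

  const double w[3] = {wxy, wxy, wz};
  auto cellIndex = [&](double v, int d) -> std::int64_t {
    return static_cast<std::int64_t>(std::floor((v - mn[d]) / w[d]));
  };
  auto key = [](std::int64_t ix, std::int64_t iy, std::int64_t iz) -> std::uint64_t {
    return (static_cast<std::uint64_t>(ix) << 42) ^
           (static_cast<std::uint64_t>(iy) << 21) ^
            static_cast<std::uint64_t>(iz);
  };

  // bucket the first ensemble into contiguous per-cell blocks
  std::vector<std::uint64_t> k1(M1);
  std::unordered_map<std::uint64_t, std::int64_t> counts;
  counts.reserve(M1 * 2);
  for (int m = 0; m < M1; ++m) {
    k1[m] = key(cellIndex(pos1(m, 0), 0), cellIndex(pos1(m, 1), 1),
                cellIndex(pos1(m, 2), 2));
    ++counts[k1[m]];
  }
  std::unordered_map<std::uint64_t, std::pair<std::int64_t, std::int64_t>> cells;
  cells.reserve(counts.size() * 2);
  std::int64_t off = 0;
  for (auto &kv : counts) {
    cells[kv.first] = {off, 0};
    off += kv.second;
  }
  std::vector<double> p1(3 * M1), q1(4 * M1);
  for (int m = 0; m < M1; ++m) {
    auto &slot = cells[k1[m]];
    std::int64_t at = slot.first + slot.second++;
    p1[3 * at] = pos1(m, 0); p1[3 * at + 1] = pos1(m, 1); p1[3 * at + 2] = pos1(m, 2);
    q1[4 * at] = quat1(m, 0); q1[4 * at + 1] = quat1(m, 1);
    q1[4 * at + 2] = quat1(m, 2); q1[4 * at + 3] = quat1(m, 3);
  }

  double hits = 0.0;
  for (int m = 0; m < M2; ++m) {
    const double x = pos2(m, 0), y = pos2(m, 1), z = pos2(m, 2);
    const double w2w = quat2(m, 0), x2 = quat2(m, 1), y2 = quat2(m, 2),
                 z2 = quat2(m, 3);
    const std::int64_t ix = cellIndex(x, 0), iy = cellIndex(y, 1),
                       iz = cellIndex(z, 2);
    for (std::int64_t dz = -1; dz <= 1; ++dz)
      for (std::int64_t dy = -1; dy <= 1; ++dy)
        for (std::int64_t dx = -1; dx <= 1; ++dx) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          const std::int64_t start = it->second.first,
                             len = it->second.second;
          for (std::int64_t t = start; t < start + len; ++t) {
            double dzv = p1[3 * t + 2] - z;
            if (dzv > eps || dzv < -eps) continue;
            double dxv = p1[3 * t] - x;
            double dyv = p1[3 * t + 1] - y;
            double d2 = dxv * dxv + dyv * dyv + dzv * dzv;
            if (d2 > eps2) continue;
            // scalar part of quat1 * quat2
            double wtot = q1[4 * t] * w2w - q1[4 * t + 1] * x2 -
                          q1[4 * t + 2] * y2 - q1[4 * t + 3] * z2;
            if (wtot * wtot >= wmin2) hits += 1.0;
          }
        }
  }
  return hits;
}

// Mean tangent correlations <d3^1 . d3^{1+k}> for k = 0..nstep over M
// sampled chains; d3^1 = e3, so the dot product is the (3,3) entry of the
// accumulated rotation, 1 - 2(x^2 + y^2) in quaternion terms.
// [[Rcpp::export(name = ".cpp_tangent_correlation")]]
NumericVector cpp_tangent_correlation(NumericMatrix thetaHat,
                                      NumericMatrix transHat,
                                      NumericVector sdTheta,
                                      NumericVector sdTrans,
                                      int M, double seed) {
  const int nstep = thetaHat.ncol();
  NumericVector acc(nstep + 1);
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (int m = 0; m < M; ++m) {
    Quat q{1.0, 0.0, 0.0, 0.0};
    acc[0] += 1.0;
    for (int i = 0; i < nstep; ++i) {
      double th[3];
      for (int j = 0; j < 3; ++j)
        th[j] = thetaHat(j, i) + (sdTheta[j] > 0 ? sdTheta[j] * gauss(rng) : 0.0);
      // translations do not affect directors, but consume draws so that the
      // stream matches the end-state sampler coordinate for coordinate
      for (int j = 0; j < 3; ++j)
        if (sdTrans[j] > 0) gauss(rng);
      Quat qs{1.0, th[0] / 2.0, th[1] / 2.0, th[2] / 2.0};
      qnormalize(qs);
      q = qmul(q, qs);
      qnormalize(q);
      acc[i + 1] += 1.0 - 2.0 * (q.x * q.x + q.y * q.y);
    }
  }
  for (int k = 0; k <= nstep; ++k) acc[k] /= M;
  return acc;
}
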