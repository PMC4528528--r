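#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shoal kinematics.
//
// Overdamped steering in polar coordinates around the stimulus object:
// the distance to the object follows an Ornstein-Uhlenbeck relaxation toward
// the preferred ring radius (stationary sd = ring_tightness), while the
// angular coordinate advances at roughly cruise speed with rare direction
// reversals. Inspection bouts override the steering with a straight approach
// to a pre-drawn target point; freezes suspend motion entirely. All random
// draws come from R's RNG so trials are reproducible from set.seed().
// ---------------------------------------------------------------------------

static const double WALL_MARGIN = 0.3;
static const double OBJ_MARGIN = 0.2;

// Smallest admissible distance from the object centroid along direction phi
// such that the point clears a capsule footprint (half-segment a, radius rho)
// oriented at angle th, dilated by OBJ_MARGIN.
static double min_allowed(double phi, double th, double a, double rho) {
  double rm = rho + OBJ_MARGIN;
  if (a <= 1e-12 && rho <= 1e-12) return 0.0;
  double c = std::fabs(std::cos(phi - th));
  double s2 = 1.0 - c * c;
  if (s2 > 1e-12) {
    double t_side = rm / std::sqrt(s2);
    if (t_side * c <= a + 1e-9) return t_side;
  }
  double disc = rm * rm - a * a * s2;
  if (disc < 0) disc = 0;
  return a * c + std::sqrt(disc);
}

// obj: cx, cy, heading_deg, cap_half_seg, cap_radius
// par: cruise, ring_radius, ring_tightness, cohesion,
//      freeze_p_frame, freeze_mean_s, freeze_max_s
// [[Rcpp::export]]
List sim_trial_cpp(int n_fish, int n_frames, double fps,
                   double arena_l, double arena_w,
                   NumericVector obj, NumericVector par,
                   NumericMatrix tx, NumericMatrix ty) {
  const double cx = obj[0], cy = obj[1];
  const double th = obj[2] * M_PI / 180.0;
  const double cap_a = obj[3], cap_r = obj[4];
  const double cruise = par[0], ring_r = par[1], tight = par[2], coh = par[3];
  const double pfreeze = par[4], fmean = par[5], fmax = par[6];
  const double dt = 1.0 / fps;
  const double lam = std::min(dt / 5.0, 1.0);       // radial relaxation, tau = 5 s
  const double sigd = tight * std::sqrt(std::max(1.0 - (1.0 - lam) * (1.0 - lam), 0.0));
  const double prev = dt / 20.0;                    // orbit reversal hazard
  const double xlo = WALL_MARGIN, xhi = arena_l - WALL_MARGIN;
  const double ylo = WALL_MARGIN, yhi = arena_w - WALL_MARGIN;

  NumericMatrix X(n_frames, n_fish), Y(n_frames, n_fish);
  std::vector<double> d(n_fish), phi(n_fish), px(n_fish), py(n_fish);
  std::vector<double> frozen_until(n_fish, -1.0);
  std::vector<int> orbit(n_fish);

  for (int i = 0; i < n_fish; ++i) {
    phi[i] = 2.0 * M_PI * unif_rand();
    d[i] = ring_r + tight * norm_rand();
    double dmin = min_allowed(phi[i], th, cap_a, cap_r);
    if (d[i] < dmin) d[i] = dmin;
    px[i] = std::min(std::max(cx + d[i] * std::cos(phi[i]), xlo), xhi);
    py[i] = std::min(std::max(cy + d[i] * std::sin(phi[i]), ylo), yhi);
    d[i] = std::hypot(px[i] - cx, py[i] - cy);
    phi[i] = std::atan2(py[i] - cy, px[i] - cx);
    orbit[i] = unif_rand() < 0.5 ? -1 : 1;
  }

  for (int t = 0; t < n_frames; ++t) {
    for (int i = 0; i < n_fish; ++i) {
      X(t, i) = px[i];
      Y(t, i) = py[i];
    }
    for (int i = 0; i < n_fish; ++i) {
      if (t < frozen_until[i]) continue;
      double bx = tx(t, i), by = ty(t, i);
      bool inspecting = R_finite(bx);
      if (!inspecting) {
        if (pfreeze > 0 && unif_rand() < pfreeze) {
          double dur = exp_rand() * fmean;
          if (dur > fmax) dur = fmax;
          frozen_until[i] = t + dur * fps;
          continue;
        }
        // ring steering
        if (unif_rand() < prev) orbit[i] = -orbit[i];
        double dn = ring_r + (1.0 - lam) * (d[i] - ring_r) + sigd * norm_rand();
        double dphi = orbit[i] * cruise * dt / std::max(dn, 2.0) +
                      0.3 * dt * norm_rand();
        double pn = phi[i] + dphi;
        // weak cohesion toward the rest of the shoal, applied in polar
        // coordinates so grouping does not bias the ring radius inward
        if (n_fish > 1 && coh > 0) {
          double mx = 0, my = 0, dsum = 0;
          for (int k = 0; k < n_fish; ++k) {
            if (k == i) continue;
            mx += X(t, k); my += Y(t, k);
            dsum += std::hypot(X(t, k) - cx, Y(t, k) - cy);
          }
          mx /= (n_fish - 1); my /= (n_fish - 1);
          double dmean = dsum / (n_fish - 1); // mean ring distance of the others
          double qx = cx + dn * std::cos(pn), qy = cy + dn * std::sin(pn);
          if (std::hypot(mx - qx, my - qy) > coh) {
            double phic = std::atan2(my - cy, mx - cx);
            double dphic = std::remainder(phic - pn, 2.0 * M_PI);
            pn += 0.4 * dt * dphic;
            dn += 0.4 * dt * (dmean - dn);
          }
        }
        px[i] = cx + dn * std::cos(pn);
        py[i] = cy + dn * std::sin(pn);
      } else {
        // inspection bout: straight approach to the drawn target point
        double step = 1.5 * cruise * dt;
        double vx = bx - px[i], vy = by - py[i];
        double dist = std::hypot(vx, vy);
        if (dist <= step) {
          px[i] = bx + 0.2 * norm_rand();
          py[i] = by + 0.2 * norm_rand();
        } else {
          px[i] += step * vx / dist;
          py[i] += step * vy / dist;
        }
      }
      // hard constraints: inside arena, outside object footprint
      px[i] = std::min(std::max(px[i], xlo), xhi);
      py[i] = std::min(std::max(py[i], ylo), yhi);
      d[i] = std::hypot(px[i] - cx, py[i] - cy);
      phi[i] = std::atan2(py[i] - cy, px[i] - cx);
      double dmin = min_allowed(phi[i], th, cap_a, cap_r);
      if (d[i] < dmin) {
        d[i] = dmin;
        px[i] = std::min(std::max(cx + d[i] * std::cos(phi[i]), xlo), xhi);
        py[i] = std::min(std::max(cy + d[i] * std::sin(phi[i]), ylo), yhi);
        d[i] = std::hypot(px[i] - cx, py[i] - cy);
        phi[i] = std::atan2(py[i] - cy, px[i] - cx);
      }
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// ---------------------------------------------------------------------------
// Cell-wise Wilcoxon signed-rank test with the Pratt zero convention.
//
// For each column of D (one grid cell; rows are trials) the paired
// differences are ranked by absolute value *including* zeros, zeros are then
// dropped, and the two-sided p-value of the positive-rank sum is computed by
// exact enumeration of all 2^m sign assignments when m (non-zero count) is
// small, otherwise by the Pratt-corrected normal approximation. Ranks are
// midranks, doubled to stay in integer arithmetic.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List signed_rank_map_cpp(NumericMatrix D, int max_exact = 16) {
  const int n = D.nrow(), C = D.ncol();
  NumericVector p(C), dir(C);
  IntegerVector m_out(C);
  std::vector<double> absd(n), dvals(n);
  std::vector<int> ord(n);
  std::vector<long long> ranks2;
  std::vector<long long> sums;
  sums.reserve(1 << std::min(max_exact, 20));

  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < n; ++i) {
      dvals[i] = D(i, j);
      absd[i] = std::fabs(dvals[i]);
      ord[i] = i;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return absd[a] < absd[b]; });
    // doubled midranks over all n values
    std::vector<long long> r2(n);
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && absd[ord[k + 1]] == absd[ord[i]]) ++k;
      long long mid2 = (long long)(i + 1) + (long long)(k + 1); // 2 * midrank
      for (int q = i; q <= k; ++q) r2[ord[q]] = mid2;
      i = k + 1;
    }
    ranks2.clear();
    long long tpos2 = 0, ttot2 = 0;
    int m = 0, npos = 0, nneg = 0;
    for (int q = 0; q < n; ++q) {
      if (dvals[q] == 0.0) continue;
      ranks2.push_back(r2[q]);
      ttot2 += r2[q];
      ++m;
      if (dvals[q] > 0) { tpos2 += r2[q]; ++npos; } else { ++nneg; }
    }
    // direction: sign of the median difference (zeros included)
    std::vector<double> dv(dvals);
    std::nth_element(dv.begin(), dv.begin() + n / 2, dv.end());
    double med;
    if (n % 2 == 1) {
      med = dv[n / 2];
    } else {
      double hi = dv[n / 2];
      std::nth_element(dv.begin(), dv.begin() + n / 2 - 1, dv.end());
      med = 0.5 * (dv[n / 2 - 1] + hi);
    }
    dir[j] = (med > 0) - (med < 0);
    m_out[j] = m;
    if (m == 0) {
      p[j] = NA_REAL;
      dir[j] = 0;
      continue;
    }
    double pj;
    if (m <= max_exact) {
      size_t total = (size_t)1 << m;
      sums.assign(total, 0);
      for (int b = 0; b < m; ++b) {
        size_t blk = (size_t)1 << b;
        for (size_t msk = 0; msk < blk; ++msk)
          sums[blk + msk] = sums[msk] + ranks2[b];
      }
      long long dev_obs = std::llabs(2 * tpos2 - ttot2);
      size_t cnt = 0;
      for (size_t msk = 0; msk < total; ++msk)
        if (std::llabs(2 * sums[msk] - ttot2) >= dev_obs) ++cnt;
      pj = (double)cnt / (double)total;
    } else {
      int z0 = n - m;
      double N = n;
      double tplus = 0.5 * tpos2;
      double E = (N * (N + 1) - (double)z0 * (z0 + 1)) / 4.0;
      double V = (N * (N + 1) * (2 * N + 1) - (double)z0 * (z0 + 1) * (2.0 * z0 + 1)) / 24.0;
      // tie correction over non-zero |d| groups
      std::vector<long long> rs(ranks2);
      std::sort(rs.begin(), rs.end());
      size_t a = 0;
      double tiecor = 0;
      while (a < rs.size()) {
        size_t b = a;
        while (b + 1 < rs.size() && rs[b + 1] == rs[a]) ++b;
        double tlen = (double)(b - a + 1);
        tiecor += tlen * tlen * tlen - tlen;
        a = b + 1;
      }
      V -= tiecor / 48.0;
      if (V <= 0) {
        p[j] = NA_REAL;
        dir[j] = 0;
        continue;
      }
      double z = (tplus - E) / std::sqrt(V);
      pj = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    }
    if (pj > 1.0) pj = 1.0;
    p[j] = pj;
  }
  return List::create(_["p"] = p, _["direction"] = dir, _["m"] = m_out);
}

// Exact two-sided rank-sum p-values by full enumeration of the C(N, m)
// group assignments, with midranks, for small combined samples (the null of
// the rank-sum statistic is symmetric, so the two-sided p is the deviation
// probability). X holds the pooled values (first m rows = group A) per
// column. Intended for N <= 16 or so.
// [[Rcpp::export]]
NumericVector ranksum_exact_cpp(NumericMatrix X, int m) {
  const int N = X.nrow(), C = X.ncol();
  NumericVector p(C);
  std::vector<double> v(N);
  std::vector<int> ord(N), comb(m);
  std::vector<long long> r2(N);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < N; ++i) { v[i] = X(i, j); ord[i] = i; }
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return v[a] < v[b]; });
    int i = 0;
    while (i < N) {
      int k = i;
      while (k + 1 < N && v[ord[k + 1]] == v[ord[i]]) ++k;
      long long mid2 = (long long)(i + 1) + (long long)(k + 1);
      for (int q = i; q <= k; ++q) r2[ord[q]] = mid2;
      i = k + 1;
    }
    long long wobs2 = 0, tot2 = 0;
    for (int q = 0; q < N; ++q) tot2 += r2[q];
    for (int q = 0; q < m; ++q) wobs2 += r2[q];
    // E[W2] = m*tot2/N; scale deviations by N to stay in integers
    long long dev_obs = std::llabs(wobs2 * N - (long long)m * tot2);
    for (int q = 0; q < m; ++q) comb[q] = q;
    long long cnt = 0, total = 0;
    while (true) {
      long long w2 = 0;
      for (int q = 0; q < m; ++q) w2 += r2[comb[q]];
      if (std::llabs(w2 * N - (long long)m * tot2) >= dev_obs) ++cnt;
      ++total;
      int pos = m - 1;
      while (pos >= 0 && comb[pos] == N - m + pos) --pos;
      if (pos < 0) break;
      ++comb[pos];
      for (int q = pos + 1; q < m; ++q) comb[q] = comb[q - 1] + 1;
    }
    p[j] = (double)cnt / (double)total;
  }
  return p;
}

// Per-column tie bookkeeping for the rank-sum maps: sum of (t^3 - t) over
// tied groups, and whether any tie is present.
// [[Rcpp::export]]
List ranksum_tie_info_cpp(NumericMatrix X) {
  const int n = X.nrow(), C = X.ncol();
  NumericVector tie_sum(C);
  LogicalVector any_tie(C);
  std::vector<double> v(n);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < n; ++i) v[i] = X(i, j);
    std::sort(v.begin(), v.end());
    double s = 0;
    bool tied = false;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && v[k + 1] == v[i]) ++k;
      double t = k - i + 1;
      if (t > 1) {
        tied = true;
        s += t * t * t - t;
      }
      i = k + 1;
    }
    tie_sum[j] = s;
    any_tie[j] = tied;
  }
  return List::create(_["tie_sum"] = tie_sum, _["any_tie"] = any_tie);
}
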