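#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time correlated random walk (integrated Ornstein-Uhlenbeck
// velocity) Kalman filter / RTS smoother on an irregular time grid.
// State per coordinate: (position, velocity). The two coordinates share
// process and measurement variances, so one covariance recursion serves both
// mean recursions. Time in hours, coordinates in km.

static inline void ctcrw_fq(double dt, double b, double s2, bool frozen,
                            double F[2][2], double Q[2][2]) {
  if (frozen) {
    // haul-out: position held, velocity reset to zero, no process noise
    F[0][0] = 1.0; F[0][1] = 0.0; F[1][0] = 0.0; F[1][1] = 0.0;
    Q[0][0] = Q[0][1] = Q[1][0] = Q[1][1] = 0.0;
    return;
  }
  double bdt = b * dt;
  double f12, q11, q12, q22;
  if (bdt < 1e-6) {
    // series limits as beta -> 0 (integrated Brownian velocity)
    f12 = dt;
    q11 = s2 * dt * dt * dt / 3.0;
    q12 = s2 * dt * dt / 2.0;
    q22 = s2 * dt;
    F[0][0] = 1.0; F[0][1] = f12; F[1][0] = 0.0; F[1][1] = 1.0 - bdt;
  } else {
    double e1 = std::exp(-bdt), e2 = std::exp(-2.0 * bdt);
    f12 = (1.0 - e1) / b;
    q22 = s2 * (1.0 - e2) / (2.0 * b);
    q12 = s2 * (1.0 - 2.0 * e1 + e2) / (2.0 * b * b);
    q11 = s2 * (dt - 2.0 * (1.0 - e1) / b + (1.0 - e2) / (2.0 * b)) / (b * b);
    F[0][0] = 1.0; F[0][1] = f12; F[1][0] = 0.0; F[1][1] = e1;
  }
  Q[0][0] = q11; Q[0][1] = q12; Q[1][0] = q12; Q[1][1] = q22;
}

// [[Rcpp::export(name = ".ctcrw_kfs")]]
List ctcrw_kfs(NumericVector times, NumericVector obs_x, NumericVector obs_y,
               NumericVector obs_sd, LogicalVector frozen,
               double log_beta, double log_sigma, bool smooth) {
  int n = times.size();
  double b = std::exp(log_beta);
  double s = std::exp(log_sigma);
  double s2 = s * s;

  std::vector<double> mx(n), vx(n), my(n), vy(n);           // filtered means
  std::vector<double> P11(n), P12(n), P22(n);               // filtered cov
  std::vector<double> pmx(n), pvx(n), pmy(n), pvy(n);       // predicted means
  std::vector<double> Pp11(n), Pp12(n), Pp22(n);            // predicted cov
  std::vector<double> Fs01(n), Fs11(n);                     // transition used

  // initial state: first finite observation position, zero velocity
  double x0 = NA_REAL, y0 = NA_REAL, r0 = 25.0;
  for (int i = 0; i < n; ++i) {
    if (R_finite(obs_x[i])) { x0 = obs_x[i]; y0 = obs_y[i]; r0 = obs_sd[i]; break; }
  }
  if (!R_finite(x0)) stop("no finite observations");
  double vel_var = (b > 1e-8) ? s2 / (2.0 * b) : s2 * 100.0;

  double loglik = 0.0;
  double cmx = x0, cvx = 0.0, cmy = y0, cvy = 0.0;
  double c11 = r0 * r0, c12 = 0.0, c22 = vel_var;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = times[i] - times[i - 1];
      if (dt < 0) stop("times must be nondecreasing");
      double F[2][2], Q[2][2];
      ctcrw_fq(dt, b, s2, frozen[i - 1], F, Q);
      Fs01[i] = F[0][1]; Fs11[i] = F[1][1];
      double nmx = cmx + F[0][1] * cvx;
      double nvx = F[1][1] * cvx;
      double nmy = cmy + F[0][1] * cvy;
      double nvy = F[1][1] * cvy;
      // P' = F P F^T + Q with F = [[1,f],[0,g]]
      double f = F[0][1], g = F[1][1];
      double a11 = c11 + f * c12, a12 = c12 + f * c22;
      double n11 = a11 + f * a12 + Q[0][0];
      double n12 = g * a12 + Q[0][1];
      double n22 = g * g * c22 + Q[1][1];
      cmx = nmx; cvx = nvx; cmy = nmy; cvy = nvy;
      c11 = n11; c12 = n12; c22 = n22;
    } else {
      Fs01[i] = 0.0; Fs11[i] = 1.0;
    }
    pmx[i] = cmx; pvx[i] = cvx; pmy[i] = cmy; pvy[i] = cvy;
    Pp11[i] = c11; Pp12[i] = c12; Pp22[i] = c22;

    if (R_finite(obs_x[i])) {
      double r2 = obs_sd[i] * obs_sd[i];
      double S = c11 + r2;
      double k1 = c11 / S, k2 = c12 / S;
      double ix = obs_x[i] - cmx, iy = obs_y[i] - cmy;
      loglik += -0.5 * (2.0 * std::log(2.0 * M_PI * S) + (ix * ix + iy * iy) / S);
      cmx += k1 * ix; cvx += k2 * ix;
      cmy += k1 * iy; cvy += k2 * iy;
      double n11 = (1.0 - k1) * c11;
      double n12 = (1.0 - k1) * c12;
      double n22 = c22 - k2 * c12;
      c11 = n11; c12 = n12; c22 = n22;
    }
    mx[i] = cmx; vx[i] = cvx; my[i] = cmy; vy[i] = cvy;
    P11[i] = c11; P12[i] = c12; P22[i] = c22;
  }

  if (!smooth) return List::create(_["loglik"] = loglik);

  // RTS smoother
  std::vector<double> smx(n), svx(n), smy(n), svy(n), sP11(n);
  smx[n - 1] = mx[n - 1]; svx[n - 1] = vx[n - 1];
  smy[n - 1] = my[n - 1]; svy[n - 1] = vy[n - 1];
  double S11 = P11[n - 1], S12 = P12[n - 1], S22 = P22[n - 1];
  sP11[n - 1] = S11;
  for (int i = n - 2; i >= 0; --i) {
    double f = Fs01[i + 1], g = Fs11[i + 1];
    // A = P_f F^T, F = [[1,f],[0,g]]
    double A11 = P11[i], A12 = f * P11[i] + g * P12[i];
    double A21 = P12[i], A22 = f * P12[i] + g * P22[i];
    // invert predicted covariance (regularised)
    double p11 = Pp11[i + 1] + 1e-12, p12 = Pp12[i + 1], p22 = Pp22[i + 1] + 1e-12;
    double det = p11 * p22 - p12 * p12;
    if (det < 1e-24) det = 1e-24;
    double i11 = p22 / det, i12 = -p12 / det, i22 = p11 / det;
    double G11 = A11 * i11 + A12 * i12, G12 = A11 * i12 + A12 * i22;
    double G21 = A21 * i11 + A22 * i12, G22 = A21 * i12 + A22 * i22;
    double dxm = smx[i + 1] - pmx[i + 1], dxv = svx[i + 1] - pvx[i + 1];
    double dym = smy[i + 1] - pmy[i + 1], dyv = svy[i + 1] - pvy[i + 1];
    smx[i] = mx[i] + G11 * dxm + G12 * dxv;
    svx[i] = vx[i] + G21 * dxm + G22 * dxv;
    smy[i] = my[i] + G11 * dym + G12 * dyv;
    svy[i] = vy[i] + G21 * dym + G22 * dyv;
    // covariance: P_s = P_f + G (P_s_next - P_pred_next) G^T
    double D11 = S11 - Pp11[i + 1], D12 = S12 - Pp12[i + 1], D22 = S22 - Pp22[i + 1];
    double T11 = G11 * D11 + G12 * D12, T12 = G11 * D12 + G12 * D22;
    double T21 = G21 * D11 + G22 * D12, T22 = G21 * D12 + G22 * D22;
    double N11 = P11[i] + T11 * G11 + T12 * G12;
    double N12 = P12[i] + T11 * G21 + T12 * G22;
    double N22 = P22[i] + T21 * G21 + T22 * G22;
    S11 = N11; S12 = N12; S22 = N22;
    sP11[i] = S11;
  }

  return List::create(_["loglik"] = loglik,
                      _["x"] = wrap(smx), _["y"] = wrap(smy),
                      _["vx"] = wrap(svx), _["vy"] = wrap(svy),
                      _["pos_var"] = wrap(sP11));
}

static inline double hav_km(double lon1, double lat1, double lon2, double lat2) {
  const double R = 6371.0, d2r = M_PI / 180.0;
  double dlat = (lat2 - lat1) * d2r, dlon = (lon2 - lon1) * d2r;
  double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
             std::cos(lat1 * d2r) * std::cos(lat2 * d2r) *
             std::sin(dlon / 2) * std::sin(dlon / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * R * std::asin(std::sqrt(a));
}

// 3-D (time x horizontal x vertical) Gaussian-weighted running average of
// cast-level temperature/salinity at arbitrary target points. Cast levels
// must be sorted by time (days). trunc_sd = Inf disables windowing.
// [[Rcpp::export(name = ".gauss3_interp")]]
NumericMatrix gauss3_interp(NumericVector tt, NumericVector tlon,
                            NumericVector tlat, NumericVector tz,
                            NumericVector ct, NumericVector clon,
                            NumericVector clat, NumericVector cz,
                            NumericVector ctemp, NumericVector csal,
                            IntegerVector cid,
                            double sd_t, double sd_xy, double sd_z,
                            double trunc_sd, double floor_w) {
  int nt = tt.size(), nc = ct.size();
  NumericMatrix out(nt, 4);
  colnames(out) = CharacterVector::create("temp", "sal", "eff_weight", "n_casts");
  double tw = R_finite(trunc_sd) ? trunc_sd * sd_t : R_PosInf;
  for (int i = 0; i < nt; ++i) {
    int lo = 0, hi = nc;
    if (R_finite(tw)) {
      lo = std::lower_bound(ct.begin(), ct.end(), tt[i] - tw) - ct.begin();
      hi = std::upper_bound(ct.begin(), ct.end(), tt[i] + tw) - ct.begin();
    }
    double wsum = 0.0, tsum = 0.0, ssum = 0.0;
    int last_id = -2147483647; int ncasts = 0; double cast_w = 0.0;
    for (int j = lo; j < hi; ++j) {
      double dt = (ct[j] - tt[i]) / sd_t;
      double dd = hav_km(clon[j], clat[j], tlon[i], tlat[i]) / sd_xy;
      double dz = (cz[j] - tz[i]) / sd_z;
      double w = std::exp(-0.5 * (dt * dt + dd * dd + dz * dz));
      wsum += w; tsum += w * ctemp[j]; ssum += w * csal[j];
      if (cid[j] != last_id) {
        if (cast_w > 1e-12) ++ncasts;
        cast_w = 0.0; last_id = cid[j];
      }
      cast_w += w;
    }
    if (cast_w > 1e-12) ++ncasts;
    if (wsum >= floor_w) {
      out(i, 0) = tsum / wsum; out(i, 1) = ssum / wsum;
    } else {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL;
    }
    out(i, 2) = wsum; out(i, 3) = ncasts;
  }
  return out;
}

// Allocate elapsed time of track segments to square grid cells by exact
// segment-in-cell length fractions. Coordinates already in cell units
// (x/cell, y/cell); returns keys ix + 1e6*iy ... use two columns instead.
// [[Rcpp::export(name = ".tsa_alloc")]]
DataFrame tsa_alloc(NumericVector x, NumericVector y, NumericVector t_s,
                    LogicalVector skip) {
  // x, y: positions in cell units; t_s: time at each vertex (seconds);
  // skip[i]: drop segment i..i+1 (e.g. haul-out)
  int n = x.size();
  std::map<std::pair<int,int>, double> acc;
  for (int i = 0; i + 1 < n; ++i) {
    if (skip[i]) continue;
    double dt = t_s[i + 1] - t_s[i];
    if (dt <= 0) continue;
    double x0 = x[i], y0 = y[i], x1 = x[i + 1], y1 = y[i + 1];
    int cx0 = (int)std::floor(x0), cy0 = (int)std::floor(y0);
    int cx1 = (int)std::floor(x1), cy1 = (int)std::floor(y1);
    if (cx0 == cx1 && cy0 == cy1) {
      acc[std::make_pair(cx0, cy0)] += dt;
      continue;
    }
    // gather crossing parameters
    std::vector<double> ts; ts.push_back(0.0); ts.push_back(1.0);
    double dx = x1 - x0, dy = y1 - y0;
    if (dx != 0) {
      int a = std::min(cx0, cx1) + 1, b = std::max(cx0, cx1);
      for (int k = a; k <= b; ++k) ts.push_back((k - x0) / dx);
    }
    if (dy != 0) {
      int a = std::min(cy0, cy1) + 1, b = std::max(cy0, cy1);
      for (int k = a; k <= b; ++k) ts.push_back((k - y0) / dy);
    }
    std::sort(ts.begin(), ts.end());
    for (size_t k = 0; k + 1 < ts.size(); ++k) {
      double u0 = ts[k], u1 = ts[k + 1];
      if (u1 <= u0 || u0 < 0 || u1 > 1) continue;
      double um = 0.5 * (u0 + u1);
      int cx = (int)std::floor(x0 + um * dx), cy = (int)std::floor(y0 + um * dy);
      acc[std::make_pair(cx, cy)] += dt * (u1 - u0);
    }
  }
  int m = acc.size();
  IntegerVector ix(m), iy(m); NumericVector tt(m);
  int i = 0;
  for (auto &kv : acc) {
    ix[i] = kv.first.first; iy[i] = kv.first.second; tt[i] = kv.second; ++i;
  }
  return DataFrame::create(_["ix"] = ix, _["iy"] = iy, _["tsa_s"] = tt);
}

static inline double bearing_deg(double lon1, double lat1, double lon2, double lat2) {
  const double d2r = M_PI / 180.0;
  double dlon = (lon2 - lon1) * d2r;
  double y = std::sin(dlon) * std::cos(lat2 * d2r);
  double x = std::cos(lat1 * d2r) * std::sin(lat2 * d2r) -
             std::sin(lat1 * d2r) * std::cos(lat2 * d2r) * std::cos(dlon);
  return std::atan2(y, x) / d2r;
}

// Iterative speed-distance-angle filter core for one animal's track.
// Speed pass: remove the single worst violator (max implied speed) until no
// location implies speed > vmax against both neighbours (single leg for the
// last point; the first point is never removed). Spike pass: remove the
// smallest interior angle violating any (angle, dist) rule until none.
// [[Rcpp::export(name = ".sda_core")]]
List sda_core(NumericVector lon, NumericVector lat, NumericVector t_s,
              double vmax, NumericVector rule_ang, NumericVector rule_km) {
  int n = lon.size();
  std::vector<int> prev(n), nxt(n);
  std::vector<bool> keep(n, true);
  for (int i = 0; i < n; ++i) { prev[i] = i - 1; nxt[i] = i + 1; }
  int n_speed = 0, n_spike = 0;

  auto speed_to = [&](int a, int b) {
    double d = hav_km(lon[a], lat[a], lon[b], lat[b]) * 1000.0;
    double dt = t_s[b] - t_s[a];
    return d / std::max(dt, 1.0);
  };
  auto drop = [&](int i) {
    keep[i] = false;
    int p = prev[i], x = nxt[i];
    if (p >= 0) nxt[p] = x;
    if (x < n) prev[x] = p;
  };

  // speed pass
  for (;;) {
    int worst = -1; double wscore = -1.0;
    int i = nxt[0] >= n ? n : nxt[0];
    for (i = nxt[0]; i < n; i = nxt[i]) {
      int p = prev[i], x = nxt[i];
      bool viol; double score;
      if (x < n) {
        double v1 = speed_to(p, i), v2 = speed_to(i, x);
        viol = v1 > vmax && v2 > vmax;
        score = std::max(v1, v2);
      } else {
        double v1 = speed_to(p, i);
        viol = v1 > vmax; score = v1;
      }
      if (viol && score > wscore) { wscore = score; worst = i; }
    }
    if (worst < 0) break;
    drop(worst); ++n_speed;
  }

  // spike pass
  int nr = rule_ang.size();
  for (;;) {
    int worst = -1; double wang = 1e9;
    for (int i = nxt[0]; i < n; i = nxt[i]) {
      int p = prev[i], x = nxt[i];
      if (p < 0 || x >= n) continue;
      double l1 = hav_km(lon[p], lat[p], lon[i], lat[i]);
      double l2 = hav_km(lon[i], lat[i], lon[x], lat[x]);
      double b1 = bearing_deg(lon[i], lat[i], lon[p], lat[p]);
      double b2 = bearing_deg(lon[i], lat[i], lon[x], lat[x]);
      double dang = b2 - b1 + 540.0;          // in [180, 900]
      while (dang >= 360.0) dang -= 360.0;
      double ang = std::fabs(dang - 180.0);
      bool spike = false;
      for (int r = 0; r < nr; ++r) {
        if (ang < rule_ang[r] && l1 > rule_km[r] && l2 > rule_km[r]) spike = true;
      }
      if (spike && ang < wang) { wang = ang; worst = i; }
    }
    if (worst < 0) break;
    drop(worst); ++n_spike;
  }

  LogicalVector kv(n);
  for (int i = 0; i < n; ++i) kv[i] = keep[i];
  return List::create(_["keep"] = kv, _["n_speed"] = n_speed,
                      _["n_spike"] = n_spike);
}
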