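#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Membrane energy of a triangulated surface under internal pressure:
//   E = sum_edges  k_stretch/(2 l0) (l - l0)^2          (rest-length springs)
//     + sum_hinges k_bend/2 * theta^2                   (dihedral deviation)
//     - pressure * V                                    (pressure-volume work)
// V is the signed divergence-theorem volume over vol_faces (the mesh faces
// plus any fan-closure faces for pinned open boundaries). All indices are
// 0-based; `pos` may carry extra pinned closure-centroid rows at the end.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// pos: n x 3 (row-major flattened by caller into x[], y[], z[] columns kept
// as std::vector of length 3n with layout [x0,y0,z0, x1,y1,z1, ...]).
struct SimData {
  int n;                          // total rows incl. closure centroids
  std::vector<int> e0, e1;        // edges
  std::vector<double> rl;         // rest lengths
  std::vector<int> h0, h1, h2, h3; // hinges: edge (h0,h1), opposite (h2,h3)
  std::vector<int> f0, f1, f2;    // volume faces
  std::vector<char> pinned;
  double k_stretch, k_bend, pressure;
};

static double energy_grad(const std::vector<double>& p, const SimData& d,
                          std::vector<double>* grad) {
  const double* P = p.data();
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  double E = 0.0;

  // edge springs
  const size_t ne = d.e0.size();
  for (size_t e = 0; e < ne; ++e) {
    const double* a = P + 3 * d.e0[e];
    const double* b = P + 3 * d.e1[e];
    double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double l0 = d.rl[e];
    double dl = l - l0;
    E += d.k_stretch / (2.0 * l0) * dl * dl;
    if (grad && l > 1e-300) {
      double c = d.k_stretch * dl / (l0 * l);
      double gx = c * dx, gy = c * dy, gz = c * dz;
      double* ga = grad->data() + 3 * d.e0[e];
      double* gb = grad->data() + 3 * d.e1[e];
      ga[0] += gx; ga[1] += gy; ga[2] += gz;
      gb[0] -= gx; gb[1] -= gy; gb[2] -= gz;
    }
  }

  // hinge bending: theta = signed dihedral deviation from flat
  if (d.k_bend > 0.0) {
    const size_t nh = d.h0.size();
    for (size_t h = 0; h < nh; ++h) {
      const double* x0 = P + 3 * d.h0[h];
      const double* x1 = P + 3 * d.h1[h];
      const double* x2 = P + 3 * d.h2[h];
      const double* x3 = P + 3 * d.h3[h];
      double e[3] = {x1[0] - x0[0], x1[1] - x0[1], x1[2] - x0[2]};
      double u1[3] = {x2[0] - x0[0], x2[1] - x0[1], x2[2] - x0[2]};
      double u2[3] = {x3[0] - x0[0], x3[1] - x0[1], x3[2] - x0[2]};
      double n1[3], n2[3];
      cross3(e, u1, n1);          // CCW normal of face (x0,x1,x2)
      cross3(u2, e, n2);          // CCW normal of face (x1,x0,x3)
      double elen = std::sqrt(dot3(e, e));
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (elen < 1e-300 || n1sq < 1e-300 || n2sq < 1e-300) continue;
      double cr[3];
      cross3(n1, n2, cr);
      double theta = std::atan2(dot3(cr, e) / elen, dot3(n1, n2));
      E += 0.5 * d.k_bend * theta * theta;
      if (grad) {
        double c = d.k_bend * theta;
        double g2[3], g3[3], g0[3];
        for (int k = 0; k < 3; ++k) {
          g2[k] = -(elen / n1sq) * n1[k];
          g3[k] = -(elen / n2sq) * n2[k];
        }
        double w12[3] = {x1[0] - x2[0], x1[1] - x2[1], x1[2] - x2[2]};
        double w13[3] = {x1[0] - x3[0], x1[1] - x3[1], x1[2] - x3[2]};
        double a1 = dot3(w12, e) / (elen * n1sq);
        double a2 = dot3(w13, e) / (elen * n2sq);
        for (int k = 0; k < 3; ++k)
          g0[k] = a1 * n1[k] * 1.0 + a2 * n2[k];
        double* G0 = grad->data() + 3 * d.h0[h];
        double* G1 = grad->data() + 3 * d.h1[h];
        double* G2 = grad->data() + 3 * d.h2[h];
        double* G3 = grad->data() + 3 * d.h3[h];
        for (int k = 0; k < 3; ++k) {
          double g1k = -g0[k] - g2[k] - g3[k];
          G0[k] += c * g0[k];
          G1[k] += c * g1k;
          G2[k] += c * g2[k];
          G3[k] += c * g3[k];
        }
      }
    }
  }

  // pressure-volume work
  if (d.pressure != 0.0) {
    const size_t nf = d.f0.size();
    double vol6 = 0.0;
    for (size_t f = 0; f < nf; ++f) {
      const double* a = P + 3 * d.f0[f];
      const double* b = P + 3 * d.f1[f];
      const double* c = P + 3 * d.f2[f];
      double cr[3];
      cross3(b, c, cr);
      vol6 += dot3(a, cr);
      if (grad) {
        double* ga = grad->data() + 3 * d.f0[f];
        double* gb = grad->data() + 3 * d.f1[f];
        double* gc = grad->data() + 3 * d.f2[f];
        double cab[3], cca[3];
        cross3(c, a, cab);   // grad_b (a . (b x c)) = c x a
        cross3(a, b, cca);   // grad_c = a x b
        for (int k = 0; k < 3; ++k) {
          ga[k] += -d.pressure * cr[k] / 6.0;
          gb[k] += -d.pressure * cab[k] / 6.0;
          gc[k] += -d.pressure * cca[k] / 6.0;
        }
      }
    }
    E -= d.pressure * vol6 / 6.0;
  }

  if (grad) {
    for (int i = 0; i < d.n; ++i)
      if (d.pinned[i]) {
        (*grad)[3 * i] = 0.0; (*grad)[3 * i + 1] = 0.0; (*grad)[3 * i + 2] = 0.0;
      }
  }
  return E;
}

static SimData build_sim(NumericMatrix pos, IntegerMatrix edges,
                         NumericVector rest_len, IntegerMatrix hinges,
                         IntegerMatrix vol_faces, double k_stretch,
                         double k_bend, double pressure,
                         LogicalVector pinned) {
  SimData d;
  d.n = pos.nrow();
  d.k_stretch = k_stretch; d.k_bend = k_bend; d.pressure = pressure;
  int ne = edges.nrow();
  d.e0.resize(ne); d.e1.resize(ne); d.rl.resize(ne);
  for (int e = 0; e < ne; ++e) {
    d.e0[e] = edges(e, 0); d.e1[e] = edges(e, 1); d.rl[e] = rest_len[e];
  }
  int nh = hinges.nrow();
  d.h0.resize(nh); d.h1.resize(nh); d.h2.resize(nh); d.h3.resize(nh);
  for (int h = 0; h < nh; ++h) {
    d.h0[h] = hinges(h, 0); d.h1[h] = hinges(h, 1);
    d.h2[h] = hinges(h, 2); d.h3[h] = hinges(h, 3);
  }
  int nf = vol_faces.nrow();
  d.f0.resize(nf); d.f1.resize(nf); d.f2.resize(nf);
  for (int f = 0; f < nf; ++f) {
    d.f0[f] = vol_faces(f, 0); d.f1[f] = vol_faces(f, 1); d.f2[f] = vol_faces(f, 2);
  }
  d.pinned.resize(d.n);
  for (int i = 0; i < d.n; ++i) d.pinned[i] = pinned[i] ? 1 : 0;
  return d;
}

static std::vector<double> flatten(NumericMatrix pos) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pos(i, 0); p[3 * i + 1] = pos(i, 1); p[3 * i + 2] = pos(i, 2);
  }
  return p;
}

static NumericMatrix unflatten(const std::vector<double>& p, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = p[3 * i]; out(i, 1) = p[3 * i + 1]; out(i, 2) = p[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_energy_grad(NumericMatrix pos, IntegerMatrix edges,
                     NumericVector rest_len, IntegerMatrix hinges,
                     IntegerMatrix vol_faces, double k_stretch, double k_bend,
                     double pressure, LogicalVector pinned) {
  SimData d = build_sim(pos, edges, rest_len, hinges, vol_faces,
                        k_stretch, k_bend, pressure, pinned);
  std::vector<double> p = flatten(pos);
  std::vector<double> g(3 * d.n);
  double E = energy_grad(p, d, &g);
  return List::create(_["energy"] = E, _["gradient"] = unflatten(g, d.n));
}

// Descent minimization with a monotone backtracking line search. With
// lbfgs_memory > 0 the search direction is the L-BFGS two-loop direction
// (falling back to steepest descent whenever curvature information is
// unusable); with lbfgs_memory = 0 it is plain steepest descent with an
// adaptive step. Energy never increases across accepted iterates.
// Snapshots are recorded every `stride` accepted steps plus first and last.
// [[Rcpp::export]]
List cpp_inflate(NumericMatrix pos0, IntegerMatrix edges,
                 NumericVector rest_len, IntegerMatrix hinges,
                 IntegerMatrix vol_faces, double k_stretch, double k_bend,
                 double pressure, LogicalVector pinned, double step_size,
                 int max_steps, double grad_tol, int stride,
                 int lbfgs_memory = 8) {
  SimData d = build_sim(pos0, edges, rest_len, hinges, vol_faces,
                        k_stretch, k_bend, pressure, pinned);
  const int N = 3 * d.n;
  std::vector<double> p = flatten(pos0);
  std::vector<double> g(N), trial(N), dir(N), g_old(N), p_old(N);
  double E = energy_grad(p, d, &g);

  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_steps;
  std::vector<double> snap_E;
  snaps.push_back(unflatten(p, d.n));
  snap_steps.push_back(0);
  snap_E.push_back(E);

  const int m_mem = lbfgs_memory;
  std::vector<std::vector<double> > S, Y;
  std::vector<double> rho;

  double s_sd = step_size;                 // adaptive step for SD mode
  const double s_sd_max = step_size * 64.0;
  bool converged = false, stuck = false;
  int step = 0;

  for (step = 1; step <= max_steps; ++step) {
    double gmax = 0.0;
    for (int i = 0; i < d.n; ++i) {
      double gx = g[3 * i], gy = g[3 * i + 1], gz = g[3 * i + 2];
      double m = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (m > gmax) gmax = m;
    }
    if (gmax < grad_tol) { converged = true; --step; break; }

    // search direction
    bool used_lbfgs = false;
    if (m_mem > 0 && !S.empty()) {
      for (int i = 0; i < N; ++i) dir[i] = -g[i];
      int k = (int)S.size();
      std::vector<double> alpha(k);
      for (int j = k - 1; j >= 0; --j) {
        double a = 0.0;
        for (int i = 0; i < N; ++i) a += S[j][i] * dir[i];
        a *= rho[j];
        alpha[j] = a;
        for (int i = 0; i < N; ++i) dir[i] -= a * Y[j][i];
      }
      double yy = 0.0, sy = 0.0;
      for (int i = 0; i < N; ++i) {
        yy += Y[k - 1][i] * Y[k - 1][i];
        sy += S[k - 1][i] * Y[k - 1][i];
      }
      double gamma = (yy > 0.0) ? sy / yy : 1.0;
      for (int i = 0; i < N; ++i) dir[i] *= gamma;
      for (int j = 0; j < k; ++j) {
        double b = 0.0;
        for (int i = 0; i < N; ++i) b += Y[j][i] * dir[i];
        b *= rho[j];
        for (int i = 0; i < N; ++i) dir[i] += S[j][i] * (alpha[j] - b);
      }
      double descent = 0.0;
      for (int i = 0; i < N; ++i) descent += dir[i] * g[i];
      if (std::isfinite(descent) && descent < 0.0) used_lbfgs = true;
    }
    double s0;
    if (used_lbfgs) {
      s0 = 1.0;
    } else {
      for (int i = 0; i < N; ++i) dir[i] = -g[i];
      s0 = s_sd;
    }

    double Enew = 0.0, s = s0;
    int halvings = 0;
    for (;;) {
      for (int i = 0; i < N; ++i) trial[i] = p[i] + s * dir[i];
      Enew = energy_grad(trial, d, nullptr);
      if (std::isfinite(Enew) && Enew <= E) break;
      s *= 0.5;
      if (++halvings > 60) { stuck = true; break; }
    }
    if (stuck && used_lbfgs) {
      // curvature model failed: drop memory, retry as steepest descent
      S.clear(); Y.clear(); rho.clear();
      stuck = false;
      for (int i = 0; i < N; ++i) dir[i] = -g[i];
      s = s_sd;
      halvings = 0;
      for (;;) {
        for (int i = 0; i < N; ++i) trial[i] = p[i] + s * dir[i];
        Enew = energy_grad(trial, d, nullptr);
        if (std::isfinite(Enew) && Enew <= E) break;
        s *= 0.5;
        if (++halvings > 60) { stuck = true; break; }
      }
      used_lbfgs = false;
    }
    if (stuck) { --step; break; }

    p_old.swap(p);   // p_old <- previous p
    p = trial;
    g_old = g;
    E = Enew;
    energy_grad(p, d, &g);
    if (!used_lbfgs) s_sd = std::min(s * 1.3, s_sd_max);

    if (m_mem > 0) {
      std::vector<double> sv(N), yv(N);
      double sy = 0.0;
      for (int i = 0; i < N; ++i) {
        sv[i] = p[i] - p_old[i];
        yv[i] = g[i] - g_old[i];
        sy += sv[i] * yv[i];
      }
      if (std::isfinite(sy) && sy > 1e-300) {
        S.push_back(sv); Y.push_back(yv); rho.push_back(1.0 / sy);
        if ((int)S.size() > m_mem) {
          S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin());
        }
      }
    }

    if (step % stride == 0) {
      snaps.push_back(unflatten(p, d.n));
      snap_steps.push_back(step);
      snap_E.push_back(E);
      Rcpp::checkUserInterrupt();
    }
  }
  if (step > max_steps) step = max_steps;
  if (snap_steps.back() != step) {
    snaps.push_back(unflatten(p, d.n));
    snap_steps.push_back(step);
    snap_E.push_back(E);
  }

  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snap_list[i] = snaps[i];
  return List::create(
    _["snapshots"] = snap_list,
    _["steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
    _["energies"] = NumericVector(snap_E.begin(), snap_E.end()),
    _["converged"] = converged,
    _["stalled"] = stuck,
    _["n_steps"] = step);
}
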