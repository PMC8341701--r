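#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Deterministic per-call jitter for coincident centers (no R RNG inside kernels).
static inline double lcg_unit(unsigned int &s) {
  s = 1664525u * s + 1013904223u;
  return (s >> 8) * (1.0 / 16777216.0);
}

// Overdamped repulsive-force relaxation of an off-lattice disk packing.
// Movable elements (cells) relocate by explicit Euler steps of the overdamped
// spring equation dX/dt = F/nu; immobile elements (vessels) only exert forces.
// Neighbor search: uniform bins of width >= the largest movable-movable reach
// for cell-cell pairs (each pair visited once), plus a separate static grid
// for immobile elements whose bin width covers the cell-vessel reach.
// Forces are exactly those of the all-pairs sum.
// Termination: converged when the max per-step displacement drops below
// tol_disp; jammed when overlaps remain but neither the displacement nor the
// overlap count has improved for stall_window iterations.
// [[Rcpp::export]]
List relax_cells_cpp(NumericVector x0, NumericVector y0, NumericVector rad,
                     LogicalVector movable,
                     double F, double nu, double dt, double tol_disp,
                     int max_iter, double xmin, double xmax,
                     double ymin, double ymax,
                     double overlap_tol, int stall_window,
                     int trace_every, unsigned int jitter_seed) {
  const int n = x0.size();
  std::vector<int> mov, fix;
  double rmax_mov = 0.0, rmax_fix = 0.0;
  for (int i = 0; i < n; ++i) {
    if (movable[i]) { mov.push_back(i); rmax_mov = std::max(rmax_mov, (double)rad[i]); }
    else            { fix.push_back(i); rmax_fix = std::max(rmax_fix, (double)rad[i]); }
  }
  const int nm = (int)mov.size();
  const int nf = (int)fix.size();
  const double Lx = xmax - xmin, Ly = ymax - ymin;

  // working arrays for movables (struct-of-arrays, bin-sorted once for locality)
  std::vector<double> mx(nm), my(nm), mr(nm), fxv(nm), fyv(nm);
  for (int a = 0; a < nm; ++a) { mx[a] = x0[mov[a]]; my[a] = y0[mov[a]]; mr[a] = rad[mov[a]]; }

  const double bin = std::max(2.0 * rmax_mov, 1.0);
  const int nbx = std::max(1, (int)std::floor(Lx / bin));
  const int nby = std::max(1, (int)std::floor(Ly / bin));
  const double bw = Lx / nbx, bh = Ly / nby;

  // initial spatial sort of movables by bin for cache locality
  {
    std::vector<int> order(nm);
    for (int a = 0; a < nm; ++a) order[a] = a;
    std::vector<int> key(nm);
    for (int a = 0; a < nm; ++a) {
      int bx = std::min(nbx - 1, std::max(0, (int)((mx[a] - xmin) / bw)));
      int by = std::min(nby - 1, std::max(0, (int)((my[a] - ymin) / bh)));
      key[a] = by * nbx + bx;
    }
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return key[a] < key[b]; });
    std::vector<double> tx(nm), ty(nm), tr(nm); std::vector<int> tm(nm);
    for (int a = 0; a < nm; ++a) {
      tx[a] = mx[order[a]]; ty[a] = my[order[a]];
      tr[a] = mr[order[a]]; tm[a] = mov[order[a]];
    }
    mx.swap(tx); my.swap(ty); mr.swap(tr); mov.swap(tm);
  }

  // static grid for immobile elements; bin width covers the cell-vessel reach
  const double bvf = std::max(rmax_mov + rmax_fix, 1.0);
  const int nvx = std::max(1, (int)std::floor(Lx / bvf));
  const int nvy = std::max(1, (int)std::floor(Ly / bvf));
  const double vw = Lx / nvx, vh = Ly / nvy;
  std::vector< std::vector<int> > fgrid((size_t)nvx * nvy);
  for (int q = 0; q < nf; ++q) {
    int k = fix[q];
    int bx = std::min(nvx - 1, std::max(0, (int)((x0[k] - xmin) / vw)));
    int by = std::min(nvy - 1, std::max(0, (int)((y0[k] - ymin) / vh)));
    fgrid[(size_t)by * nvx + bx].push_back(k);
  }

  std::vector<int> head((size_t)nbx * nby), nxt(nm), binof(nm);
  std::vector<int> it_tr, ov_tr;
  std::vector<double> disp_tr, en_tr;

  double max_disp = R_PosInf, best_disp = R_PosInf;
  int best_iter = 0, n_overlap = 0, iter = 0;
  int best_ov = INT_MAX, best_ov_iter = 0;
  double energy = 0.0;
  bool converged = false;
  const double c = dt / nu;

  auto pair_force = [&](int a, int b2) {
    double Rij = mr[a] + mr[b2];
    double ddx = mx[a] - mx[b2], ddy = my[a] - my[b2];
    double d2 = ddx * ddx + ddy * ddy;
    if (d2 >= Rij * Rij) return;
    double d = std::sqrt(d2);
    double ov = Rij - d;
    if (d < 1e-12) {
      unsigned int s = jitter_seed ^ (2654435761u * (unsigned)iter + 97u * (unsigned)a);
      double th = 6.283185307179586 * lcg_unit(s);
      ddx = std::cos(th); ddy = std::sin(th); d = 1.0; ov = Rij;
    }
    double fmag = F * ov / d;
    fxv[a] += fmag * ddx;  fyv[a] += fmag * ddy;
    fxv[b2] -= fmag * ddx; fyv[b2] -= fmag * ddy;
    if (ov > overlap_tol) ++n_overlap;
    energy += ov * ov;
  };

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(head.begin(), head.end(), -1);
    for (int a = 0; a < nm; ++a) {
      int bx = std::min(nbx - 1, std::max(0, (int)((mx[a] - xmin) / bw)));
      int by = std::min(nby - 1, std::max(0, (int)((my[a] - ymin) / bh)));
      int b = by * nbx + bx;
      binof[a] = b; nxt[a] = head[b]; head[b] = a;
    }
    n_overlap = 0; energy = 0.0;
    std::fill(fxv.begin(), fxv.end(), 0.0);
    std::fill(fyv.begin(), fyv.end(), 0.0);
    for (int a = 0; a < nm; ++a) {
      int b = binof[a];
      int bx = b % nbx, by = b / nbx;
      // same bin: only partners later in the chain (j before a in list order)
      for (int b2 = nxt[a]; b2 >= 0; b2 = nxt[b2]) pair_force(a, b2);
      // half of the neighboring bins (E, NW, N, NE) so each pair is seen once
      const int offs[4][2] = { {1, 0}, {-1, 1}, {0, 1}, {1, 1} };
      for (int o = 0; o < 4; ++o) {
        int xx = bx + offs[o][0], yy = by + offs[o][1];
        if (xx < 0 || xx >= nbx || yy < 0 || yy >= nby) continue;
        for (int b2 = head[yy * nbx + xx]; b2 >= 0; b2 = nxt[b2]) pair_force(a, b2);
      }
      // immobile neighbors via the static grid (ring 1 by construction)
      int vbx = std::min(nvx - 1, std::max(0, (int)((mx[a] - xmin) / vw)));
      int vby = std::min(nvy - 1, std::max(0, (int)((my[a] - ymin) / vh)));
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = vby + dy; if (yy < 0 || yy >= nvy) continue;
        for (int dxx = -1; dxx <= 1; ++dxx) {
          int xx = vbx + dxx; if (xx < 0 || xx >= nvx) continue;
          const std::vector<int> &fb = fgrid[(size_t)yy * nvx + xx];
          for (size_t q = 0; q < fb.size(); ++q) {
            int j = fb[q];
            double Rij = mr[a] + rad[j];
            double ddx = mx[a] - x0[j], ddy = my[a] - y0[j];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 >= Rij * Rij) continue;
            double d = std::sqrt(d2);
            double ov = Rij - d;
            if (d < 1e-12) {
              unsigned int s = jitter_seed ^ (2654435761u * (unsigned)iter + 193u * (unsigned)a);
              double th = 6.283185307179586 * lcg_unit(s);
              ddx = std::cos(th); ddy = std::sin(th); d = 1.0; ov = Rij;
            }
            double fmag = F * ov / d;
            fxv[a] += fmag * ddx; fyv[a] += fmag * ddy;
            if (ov > overlap_tol) ++n_overlap;
            energy += ov * ov;
          }
        }
      }
    }
    // synchronous move
    max_disp = 0.0;
    for (int a = 0; a < nm; ++a) {
      double nx = mx[a] + c * fxv[a], ny = my[a] + c * fyv[a];
      if (nx < xmin) nx = xmin; else if (nx > xmax) nx = xmax;
      if (ny < ymin) ny = ymin; else if (ny > ymax) ny = ymax;
      double adx = nx - mx[a], ady = ny - my[a];
      double d2 = adx * adx + ady * ady;
      if (d2 > max_disp) max_disp = d2;
      mx[a] = nx; my[a] = ny;
    }
    max_disp = std::sqrt(max_disp);
    if (trace_every > 0 && (iter % trace_every == 0 || iter == 1)) {
      it_tr.push_back(iter); ov_tr.push_back(n_overlap);
      disp_tr.push_back(max_disp); en_tr.push_back(energy);
    }
    if (max_disp < tol_disp) { converged = true; break; }
    if (max_disp < best_disp * 0.99) { best_disp = max_disp; best_iter = iter; }
    if (n_overlap < best_ov) { best_ov = n_overlap; best_ov_iter = iter; }
    if (stall_window > 0 && n_overlap > 0 &&
        iter - best_iter > stall_window && iter - best_ov_iter > stall_window)
      break;
  }
  if (iter > max_iter) iter = max_iter;

  NumericVector xo(x0.begin(), x0.end()), yo(y0.begin(), y0.end());
  for (int a = 0; a < nm; ++a) { xo[mov[a]] = mx[a]; yo[mov[a]] = my[a]; }
  return List::create(
    _["x"] = xo, _["y"] = yo,
    _["iterations"] = iter,
    _["max_disp"] = max_disp,
    _["n_overlap"] = n_overlap,
    _["overlap_energy"] = energy,
    _["converged"] = converged,
    _["trace"] = List::create(_["iteration"] = IntegerVector(it_tr.begin(), it_tr.end()),
                              _["n_overlap"] = IntegerVector(ov_tr.begin(), ov_tr.end()),
                              _["max_disp"] = NumericVector(disp_tr.begin(), disp_tr.end()),
                              _["overlap_energy"] = NumericVector(en_tr.begin(), en_tr.end())));
}

// Exact all-pairs force sum on movable elements; oracle for the binned search.
// [[Rcpp::export]]
NumericMatrix pair_forces_cpp(NumericVector x, NumericVector y, NumericVector rad,
                              LogicalVector movable, double F) {
  const int n = x.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    if (!movable[i]) continue;
    double fx = 0.0, fy = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rij = rad[i] + rad[j];
      double ddx = x[i] - x[j], ddy = y[i] - y[j];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 >= Rij * Rij || d2 < 1e-24) continue;
      double d = std::sqrt(d2);
      double fmag = F * (Rij - d) / d;
      fx += fmag * ddx; fy += fmag * ddy;
    }
    out(i, 0) = fx; out(i, 1) = fy;
  }
  return out;
}

// Per-node counts of covering elements: node counted iff dist(node, center) < R.
// Nodes: x_j = x0 + j*dx (columns), y_i = y0 + i*dx (rows), matrix is rows x cols.
// [[Rcpp::export]]
IntegerMatrix cover_counts_cpp(NumericVector cx, NumericVector cy, double R,
                               int nrow, int ncol, double x0, double y0, double dx) {
  IntegerMatrix m(nrow, ncol);
  const double R2 = R * R;
  for (int k = 0; k < cx.size(); ++k) {
    int jlo = std::max(0, (int)std::ceil((cx[k] - R - x0) / dx));
    int jhi = std::min(ncol - 1, (int)std::floor((cx[k] + R - x0) / dx));
    int ilo = std::max(0, (int)std::ceil((cy[k] - R - y0) / dx));
    int ihi = std::min(nrow - 1, (int)std::floor((cy[k] + R - y0) / dx));
    for (int j = jlo; j <= jhi; ++j) {
      double ddx = x0 + j * dx - cx[k];
      for (int i = ilo; i <= ihi; ++i) {
        double ddy = y0 + i * dx - cy[k];
        if (ddx * ddx + ddy * ddy < R2) m(i, j) += 1;
      }
    }
  }
  return m;
}

// Forward-Euler stepping of the oxygen reaction-diffusion equation.
//   gamma' = influx + D*Lap(gamma) - uptake * gamma/(km+gamma), clipped at 0.
// src  = dt * delta_V * gamma_max * vessel_count   (per node)
// upt  = dt * uptake_scale * (delta_T*T_max*tumor_count + S_max*stromal_count)
// dF   = D * dt / dx^2. Zero-flux boundaries via the conservative stencil
// (missing neighbors contribute nothing: lap = sum(nb) - k*c with k = #existing).
// Per-step change is accumulated as ss = sum((new-old)^2); the normalized error
// is sqrt(ss)/(Ni*Nj) ("euclidean") or ss/(Ni*Nj) ("sum_of_squares").
// When `clamp_idx` is non-empty the vessel nodes are held at `clamp_value`
// after every step (vessels as local oxygen reservoirs at delta_V*gamma_max)
// and `src` is ignored at those nodes.
// [[Rcpp::export]]
List ox_run_cpp(NumericMatrix gamma0, NumericMatrix src, NumericMatrix upt,
                double dF, double km, int nsteps,
                bool check_eps, double eps_tol, bool eps_sumsq,
                int trace_every,
                IntegerVector clamp_idx = IntegerVector(0),
                double clamp_value = 0.0) {
  const int nr = gamma0.nrow(), nc = gamma0.ncol();
  const double NN = (double)nr * (double)nc;
  std::vector<double> a(gamma0.begin(), gamma0.end()), b((size_t)nr * nc);
  const double *S = src.begin(), *U = upt.begin();
  const int ncl = clamp_idx.size();
  for (int q = 0; q < ncl; ++q) a[clamp_idx[q]] = clamp_value;
  std::vector<double> avg_tr; std::vector<int> step_tr;
  double eps = NA_REAL;
  bool converged = false, diverged = false;
  int step = 0;

  for (step = 1; step <= nsteps; ++step) {
    double ss = 0.0;
    for (int j = 0; j < nc; ++j) {
      const double *cl = &a[(size_t)j * nr];
      const double *lf = (j > 0) ? &a[(size_t)(j - 1) * nr] : nullptr;
      const double *rt = (j < nc - 1) ? &a[(size_t)(j + 1) * nr] : nullptr;
      const double *sc = &S[(size_t)j * nr];
      const double *uc = &U[(size_t)j * nr];
      double *ot = &b[(size_t)j * nr];
      // node update shared by every stencil variant
      auto upd = [&](int i, double lap) {
        double c = cl[i];
        double nv = c + dF * lap + sc[i] - uc[i] * c / (km + c);
        nv = nv < 0.0 ? 0.0 : nv;
        double d = nv - c;
        ss += d * d;
        ot[i] = nv;
      };
      if (lf && rt) {
        upd(0, cl[1] + lf[0] + rt[0] - 3.0 * cl[0]);
        for (int i = 1; i < nr - 1; ++i) { // branch-free interior, vectorizes
          double c = cl[i];
          double lap = cl[i - 1] + cl[i + 1] + lf[i] + rt[i] - 4.0 * c;
          double nv = c + dF * lap + sc[i] - uc[i] * c / (km + c);
          nv = nv < 0.0 ? 0.0 : nv;
          double d = nv - c;
          ss += d * d;
          ot[i] = nv;
        }
        upd(nr - 1, cl[nr - 2] + lf[nr - 1] + rt[nr - 1] - 3.0 * cl[nr - 1]);
      } else {
        const double *sd = lf ? lf : rt; // the single lateral neighbor
        if (nr == 1) {
          upd(0, (sd ? sd[0] - cl[0] : 0.0));
        } else {
          upd(0, cl[1] + (sd ? sd[0] : 0.0) - (sd ? 2.0 : 1.0) * cl[0]);
          for (int i = 1; i < nr - 1; ++i)
            upd(i, cl[i - 1] + cl[i + 1] + (sd ? sd[i] : 0.0) -
                   (sd ? 3.0 : 2.0) * cl[i]);
          upd(nr - 1, cl[nr - 2] + (sd ? sd[nr - 1] : 0.0) -
                      (sd ? 2.0 : 1.0) * cl[nr - 1]);
        }
      }
    }
    for (int q = 0; q < ncl; ++q) {
      int k = clamp_idx[q];
      double d0 = b[k] - a[k]; // undo the free-evolution contribution to ss
      ss -= d0 * d0;
      double d1 = clamp_value - a[k];
      ss += d1 * d1;
      b[k] = clamp_value;
    }
    a.swap(b);
    if (!std::isfinite(ss)) { diverged = true; break; }
    if (check_eps) {
      eps = eps_sumsq ? (ss / NN) : (std::sqrt(ss) / NN);
      if (eps <= eps_tol) { converged = true; break; }
    }
    if (trace_every > 0 && step % trace_every == 0) {
      double s = 0.0;
      for (size_t q = 0; q < a.size(); ++q) s += a[q];
      avg_tr.push_back(s / NN); step_tr.push_back(step);
    }
  }
  if (step > nsteps) step = nsteps;
  if (check_eps && !converged && !diverged) {
    // eps of the last executed step is already in `eps`
  }
  NumericMatrix out(nr, nc);
  std::copy(a.begin(), a.end(), out.begin());
  double s = 0.0;
  for (size_t q = 0; q < a.size(); ++q) s += a[q];
  return List::create(_["field"] = out,
                      _["steps"] = step,
                      _["eps"] = eps,
                      _["converged"] = converged,
                      _["diverged"] = diverged,
                      _["average"] = s / NN,
                      _["trace"] = List::create(_["step"] = IntegerVector(step_tr.begin(), step_tr.end()),
                                                _["average"] = NumericVector(avg_tr.begin(), avg_tr.end())));
}
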