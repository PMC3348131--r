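#include <Rcpp.h>
using namespace Rcpp;

// Distance-constraint correction sweeps (Gauss-Seidel pairwise projection).
// Each sweep visits every constraint in a freshly randomised order (R's RNG,
// so results are reproducible under set.seed) and, when the pair distance
// falls outside [lo, hi], moves both atoms half-way each along their
// separation vector onto the nearest bound. Stops when the summed violation
// drops to converge_tol or after max_iter sweeps.
// [[Rcpp::export]]
List cpp_correct_sweeps(NumericMatrix coords, IntegerVector ai, IntegerVector aj,
                        NumericVector lo, NumericVector hi,
                        int max_iter, double converge_tol) {
  const int m = ai.size();
  const int n = coords.nrow();
  NumericMatrix x = clone(coords);
  double total = 0.0;
  int sweeps = 0;

  auto total_violation = [&]() {
    double s = 0.0;
    for (int k = 0; k < m; ++k) {
      const int i = ai[k], j = aj[k];
      const double dx = x(j,0)-x(i,0), dy = x(j,1)-x(i,1), dz = x(j,2)-x(i,2);
      const double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < lo[k]) s += lo[k] - d; else if (d > hi[k]) s += d - hi[k];
    }
    return s;
  };

  total = total_violation();
  if (n == 0 || m == 0) {
    return List::create(_["coords"] = x, _["iterations"] = 0, _["total_violation"] = total);
  }

  for (sweeps = 0; sweeps < max_iter && total > converge_tol; ) {
    IntegerVector ord = sample(m, m, false) - 1; // R RNG; 0-based
    for (int kk = 0; kk < m; ++kk) {
      const int k = ord[kk];
      const int i = ai[k], j = aj[k];
      double dx = x(j,0)-x(i,0), dy = x(j,1)-x(i,1), dz = x(j,2)-x(i,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      double target;
      if (d < lo[k]) target = lo[k];
      else if (d > hi[k]) target = hi[k];
      else continue;
      if (d < 1e-12) { // coincident atoms: separate along a fixed axis
        dx = 1.0; dy = 0.0; dz = 0.0; d = 1.0;
      }
      const double f = 0.5 * (target - d) / d; // each atom takes half the move
      x(i,0) -= f*dx; x(i,1) -= f*dy; x(i,2) -= f*dz;
      x(j,0) += f*dx; x(j,1) += f*dy; x(j,2) += f*dz;
    }
    ++sweeps;
    total = total_violation();
  }
  return List::create(_["coords"] = x, _["iterations"] = sweeps,
                      _["total_violation"] = total);
}

// Fraction of rays (unit directions `dirs`, cast to max_range) from each
// query point that hit any atom sphere. Segment-sphere intersection with the
// entry point required inside [0, max_range].
// [[Rcpp::export]]
NumericVector cpp_ray_blocked(NumericMatrix points, NumericMatrix atoms,
                              NumericVector radii, NumericMatrix dirs,
                              double max_range) {
  const int np = points.nrow(), na = atoms.nrow(), nd = dirs.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double px = points(p,0), py = points(p,1), pz = points(p,2);
    int blocked = 0;
    for (int d = 0; d < nd; ++d) {
      const double ux = dirs(d,0), uy = dirs(d,1), uz = dirs(d,2);
      bool hit = false;
      for (int a = 0; a < na && !hit; ++a) {
        const double cx = atoms(a,0)-px, cy = atoms(a,1)-py, cz = atoms(a,2)-pz;
        const double r = radii[a];
        const double c2 = cx*cx + cy*cy + cz*cz;
        if (c2 <= r*r) { hit = true; break; } // ray origin inside the sphere
        const double b = cx*ux + cy*uy + cz*uz;
        if (b <= 0.0) continue;
        const double d2 = c2 - b*b;
        if (d2 > r*r) continue;
        const double t = b - std::sqrt(r*r - d2);
        if (t >= 0.0 && t <= max_range) hit = true;
      }
      if (hit) ++blocked;
    }
    out[p] = static_cast<double>(blocked) / nd;
  }
  return out;
}

// Signed distance from each point to the nearest atom van der Waals surface
// (negative: inside an atom sphere).
// [[Rcpp::export]]
NumericVector cpp_surface_distance(NumericMatrix points, NumericMatrix atoms,
                                   NumericVector radii) {
  const int np = points.nrow(), na = atoms.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf;
    for (int a = 0; a < na; ++a) {
      const double dx = atoms(a,0)-points(p,0);
      const double dy = atoms(a,1)-points(p,1);
      const double dz = atoms(a,2)-points(p,2);
      const double s = std::sqrt(dx*dx + dy*dy + dz*dz) - radii[a];
      if (s < best) best = s;
    }
    out[p] = best;
  }
  return out;
}

// Index (1-based) of the nearest atom to each point.
// [[Rcpp::export]]
IntegerVector cpp_nearest_atom(NumericMatrix points, NumericMatrix atoms) {
  const int np = points.nrow(), na = atoms.nrow();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double best = R_PosInf; int bi = 0;
    for (int a = 0; a < na; ++a) {
      const double dx = atoms(a,0)-points(p,0);
      const double dy = atoms(a,1)-points(p,1);
      const double dz = atoms(a,2)-points(p,2);
      const double s = dx*dx + dy*dy + dz*dz;
      if (s < best) { best = s; bi = a; }
    }
    out[p] = bi + 1;
  }
  return out;
}

// Count, for each point, atoms within `cutoff` whose flag is TRUE
// (used for the restrictive hydrophobicity rule).
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericMatrix points, NumericMatrix atoms,
                               LogicalVector flag, double cutoff) {
  const int np = points.nrow(), na = atoms.nrow();
  const double c2 = cutoff * cutoff;
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    int cnt = 0;
    for (int a = 0; a < na; ++a) {
      if (!flag[a]) continue;
      const double dx = atoms(a,0)-points(p,0);
      const double dy = atoms(a,1)-points(p,1);
      const double dz = atoms(a,2)-points(p,2);
      if (dx*dx + dy*dy + dz*dz <= c2) ++cnt;
    }
    out[p] = cnt;
  }
  return out;
}
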