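// Numerical kernels: Shrake-Rupley sphere sampling, two-level contact/clash
// counting for rigid docking, pair enumeration for contact energies, and the
// Monte-Carlo cell classification used by the packing-density estimator.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Per-atom solvent accessible surface area by sphere-point sampling.
// coords: n x 3, radii: n, sphere: m x 3 unit vectors, subset: 1-based atom
// indices to evaluate. Returns area (A^2) per subset atom.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii, double probe,
                       NumericMatrix sphere, IntegerVector subset) {
  const int n = coords.nrow(), m = sphere.nrow(), ns = subset.size();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i) {
    xyz[3 * i] = coords(i, 0);
    xyz[3 * i + 1] = coords(i, 1);
    xyz[3 * i + 2] = coords(i, 2);
  }
  NumericVector out(ns);
  std::vector<int> nbr;
  std::vector<double> nbr_r2;
  for (int s = 0; s < ns; ++s) {
    const int i = subset[s] - 1;
    const double Ri = radii[i] + probe;
    nbr.clear(); nbr_r2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double lim = Ri + Rj;
      if (dist2(&xyz[3 * i], &xyz[3 * j]) < lim * lim) {
        nbr.push_back(j);
        nbr_r2.push_back(Rj * Rj);
      }
    }
    int acc = 0;
    const int nn = (int)nbr.size();
    for (int k = 0; k < m; ++k) {
      double p[3] = {xyz[3 * i] + Ri * sphere(k, 0),
                     xyz[3 * i + 1] + Ri * sphere(k, 1),
                     xyz[3 * i + 2] + Ri * sphere(k, 2)};
      bool free_pt = true;
      for (int q = 0; q < nn; ++q) {
        if (dist2(p, &xyz[3 * nbr[q]]) < nbr_r2[q]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[s] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)m;
  }
  return out;
}

// Residue-level bounding spheres for the two-level contact scan.
static void group_spheres(const NumericMatrix& X, const IntegerVector& grp,
                          int ngrp, std::vector<double>& ctr,
                          std::vector<double>& rad,
                          std::vector<std::vector<int> >& members) {
  ctr.assign(3 * ngrp, 0.0);
  rad.assign(ngrp, 0.0);
  members.assign(ngrp, std::vector<int>());
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) members[grp[i] - 1].push_back(i);
  for (int g = 0; g < ngrp; ++g) {
    const std::vector<int>& mem = members[g];
    if (mem.empty()) continue;
    for (size_t k = 0; k < mem.size(); ++k)
      for (int d = 0; d < 3; ++d) ctr[3 * g + d] += X(mem[k], d);
    for (int d = 0; d < 3; ++d) ctr[3 * g + d] /= (double)mem.size();
    double r2max = 0.0;
    for (size_t k = 0; k < mem.size(); ++k) {
      double c[3] = {X(mem[k], 0), X(mem[k], 1), X(mem[k], 2)};
      double d2 = dist2(c, &ctr[3 * g]);
      if (d2 > r2max) r2max = d2;
    }
    rad[g] = std::sqrt(r2max);
  }
}

// Exhaustive contact/clash counting between a fixed atom set A and a mobile
// set B evaluated at many candidate translations. B is supplied already
// rotated; placement k uses coordinates B + trans[k,]. A contact is a pair
// closer than contact_cut (clashing pairs included); a clash is a pair closer
// than clash_cut; a region contact is a contact with both atoms flagged in
// their respective region masks. Returns a k x 3 matrix
// (contacts, clashes, region_contacts).
// [[Rcpp::export]]
IntegerMatrix cpp_dock_scan(NumericMatrix A, NumericMatrix B,
                            NumericMatrix trans,
                            IntegerVector grpA, IntegerVector grpB,
                            LogicalVector regA, LogicalVector regB,
                            double contact_cut, double clash_cut) {
  const int nt = trans.nrow();
  const int ngA = max(grpA), ngB = max(grpB);
  std::vector<double> ctrA, radA, ctrB, radB;
  std::vector<std::vector<int> > memA, memB;
  group_spheres(A, grpA, ngA, ctrA, radA, memA);
  group_spheres(B, grpB, ngB, ctrB, radB, memB);
  const double c2 = contact_cut * contact_cut, k2 = clash_cut * clash_cut;
  IntegerMatrix out(nt, 3);
  for (int t = 0; t < nt; ++t) {
    const double tv[3] = {trans(t, 0), trans(t, 1), trans(t, 2)};
    int ncon = 0, ncl = 0, nreg = 0;
    for (int ga = 0; ga < ngA; ++ga) {
      if (memA[ga].empty()) continue;
      for (int gb = 0; gb < ngB; ++gb) {
        if (memB[gb].empty()) continue;
        double cb[3] = {ctrB[3 * gb] + tv[0], ctrB[3 * gb + 1] + tv[1],
                        ctrB[3 * gb + 2] + tv[2]};
        double lim = radA[ga] + radB[gb] + contact_cut;
        if (dist2(&ctrA[3 * ga], cb) >= lim * lim) continue;
        for (size_t ia = 0; ia < memA[ga].size(); ++ia) {
          const int i = memA[ga][ia];
          const double ai[3] = {A(i, 0), A(i, 1), A(i, 2)};
          for (size_t ib = 0; ib < memB[gb].size(); ++ib) {
            const int j = memB[gb][ib];
            const double bj[3] = {B(j, 0) + tv[0], B(j, 1) + tv[1],
                                  B(j, 2) + tv[2]};
            const double d2 = dist2(ai, bj);
            if (d2 < c2) {
              ++ncon;
              if (d2 < k2) ++ncl;
              if (regA[i] && regB[j]) ++nreg;
            }
          }
        }
      }
    }
    out(t, 0) = ncon; out(t, 1) = ncl; out(t, 2) = nreg;
  }
  return out;
}

// All pairs (i < j, 1-based) within cutoff inside one coordinate set.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_self(NumericMatrix X, double cutoff) {
  const int n = X.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> pi, pj;
  for (int i = 0; i < n - 1; ++i) {
    const double a[3] = {X(i, 0), X(i, 1), X(i, 2)};
    for (int j = i + 1; j < n; ++j) {
      const double b[3] = {X(j, 0), X(j, 1), X(j, 2)};
      if (dist2(a, b) < c2) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// Minimum pairwise distance between two coordinate sets.
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    const double a[3] = {A(i, 0), A(i, 1), A(i, 2)};
    for (int j = 0; j < B.nrow(); ++j) {
      const double b[3] = {B(j, 0), B(j, 1), B(j, 2)};
      const double d2 = dist2(a, b);
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Monte-Carlo classification of sample points for the packing-density cell
// of one atom. pts are absolute sample positions; a point belongs to the
// atom's cell when its surface distance to the atom (|x - c| - r) does not
// exceed the surface distance to any neighbour; it is occupied when it lies
// inside any van der Waals sphere. Returns (n_in_cell, n_occupied_in_cell).
// [[Rcpp::export]]
IntegerVector cpp_cell_mc(NumericVector center, double r_atom,
                          NumericMatrix pts, NumericMatrix nbr,
                          NumericVector nbr_r) {
  const int np = pts.nrow(), nn = nbr.nrow();
  const double c[3] = {center[0], center[1], center[2]};
  int in_cell = 0, occ = 0;
  for (int k = 0; k < np; ++k) {
    const double p[3] = {pts(k, 0), pts(k, 1), pts(k, 2)};
    const double di = std::sqrt(dist2(p, c)) - r_atom;
    bool mine = true, inside = di < 0.0;
    for (int j = 0; j < nn; ++j) {
      const double b[3] = {nbr(j, 0), nbr(j, 1), nbr(j, 2)};
      const double dj = std::sqrt(dist2(p, b)) - nbr_r[j];
      if (dj < di) { mine = false; break; }
      if (dj < 0.0) inside = true;
    }
    if (mine) {
      ++in_cell;
      if (inside) ++occ;
    }
  }
  return IntegerVector::create(in_cell, occ);
}
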