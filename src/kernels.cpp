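// Numerical kernels: Shrake-Rupley SASA, minimum-image RDF histogramming,
// and overlap tests used by the synthetic solvent generator. These are the
// only per-frame inner loops tight enough to need compiled code.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// coords/radii describe all candidate occluders (the solute heavy atoms);
// `subset` (1-based) selects the atoms whose area is wanted. `sphere` is a
// precomputed n x 3 matrix of unit vectors (deterministic golden-spiral
// lattice built on the R side).
// [[Rcpp::export]]
NumericVector cpp_sasa(const NumericMatrix& coords,
                       const NumericVector& radii,
                       const IntegerVector& subset,
                       const NumericMatrix& sphere,
                       double probe) {
  const int n = coords.nrow();
  const int npts = sphere.nrow();
  NumericVector areas(subset.size());
  std::vector<double> spx(npts), spy(npts), spz(npts);
  for (int p = 0; p < npts; ++p) {
    spx[p] = sphere(p, 0); spy[p] = sphere(p, 1); spz[p] = sphere(p, 2);
  }

  // contiguous neighbor buffers (coords + squared expanded radius), sorted
  // by distance so buried points exit the scan early
  std::vector<double> nx, ny, nz, nr2, nd2;
  std::vector<int> order;
  for (int k = 0; k < subset.size(); ++k) {
    const int i = subset[k] - 1;
    const double ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);

    nx.clear(); ny.clear(); nz.clear(); nr2.clear(); nd2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rj;
      if (d2 < rr * rr) {
        nx.push_back(coords(j, 0));
        ny.push_back(coords(j, 1));
        nz.push_back(coords(j, 2));
        nr2.push_back(rj * rj);
        nd2.push_back(d2);
      }
    }
    const int nn = (int)nx.size();
    order.resize(nn);
    for (int q = 0; q < nn; ++q) order[q] = q;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return nd2[a] < nd2[b]; });
    std::vector<double> sx(nn), sy(nn), sz(nn), sr2(nn);
    for (int q = 0; q < nn; ++q) {
      sx[q] = nx[order[q]]; sy[q] = ny[order[q]];
      sz[q] = nz[order[q]]; sr2[q] = nr2[order[q]];
    }

    int accessible = 0;
    for (int p = 0; p < npts; ++p) {
      const double px = xi + ri * spx[p];
      const double py = yi + ri * spy[p];
      const double pz = zi + ri * spz[p];
      bool buried = false;
      for (int q = 0; q < nn; ++q) {
        const double dx = px - sx[q];
        const double dy = py - sy[q];
        const double dz = pz - sz[q];
        if (dx * dx + dy * dy + dz * dz < sr2[q]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++accessible;
    }
    areas[k] = 4.0 * M_PI * ri * ri * (double)accessible / (double)npts;
  }
  return areas;
}

// Histogram of site-to-point distances under the orthorhombic minimum-image
// convention. Returns integer counts for bins [b*dr, (b+1)*dr), b in
// 0..nbins-1 with nbins = round(r_max / dr).
// [[Rcpp::export]]
IntegerVector cpp_rdf_hist(const NumericVector& site,
                           const NumericMatrix& points,
                           const NumericVector& box,
                           double r_max, double dr) {
  const int nbins = (int)std::lround(r_max / dr);
  IntegerVector counts(nbins);
  const double bx = box[0], by = box[1], bz = box[2];
  for (int i = 0; i < points.nrow(); ++i) {
    double dx = points(i, 0) - site[0];
    double dy = points(i, 1) - site[1];
    double dz = points(i, 2) - site[2];
    dx -= bx * std::nearbyint(dx / bx);
    dy -= by * std::nearbyint(dy / by);
    dz -= bz * std::nearbyint(dz / bz);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < r_max) {
      int b = (int)(r / dr);
      if (b >= nbins) b = nbins - 1;  // guard r == r_max - eps rounding
      ++counts[b];
    }
  }
  return counts;
}

// True for each point lying within `cutoff` of any atom (no periodic
// images; used for solvent overlap rejection against a centered solute).
// [[Rcpp::export]]
LogicalVector cpp_too_close(const NumericMatrix& points,
                            const NumericMatrix& atoms,
                            double cutoff) {
  const double c2 = cutoff * cutoff;
  LogicalVector out(points.nrow());
  for (int i = 0; i < points.nrow(); ++i) {
    bool close = false;
    for (int j = 0; j < atoms.nrow(); ++j) {
      const double dx = points(i, 0) - atoms(j, 0);
      const double dy = points(i, 1) - atoms(j, 1);
      const double dz = points(i, 2) - atoms(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) {
        close = true;
        break;
      }
    }
    out[i] = close;
  }
  return out;
}

// Minimum distance between two atom groups (no periodic images).
// [[Rcpp::export]]
double cpp_min_group_dist(const NumericMatrix& a, const NumericMatrix& b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
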