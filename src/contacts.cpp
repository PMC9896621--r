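#include <Rcpp.h>
using namespace Rcpp;

// Binary contact bits: bit j = 1 iff min_i ||ligand_i - site_j|| <= cutoff.
// Coordinates are in the shared docking frame; both sides may include
// hydrogens (the caller decides which atoms participate).
// [[Rcpp::export]]
IntegerVector cpp_contact_bits(NumericMatrix ligand, NumericMatrix site,
                               double cutoff) {
  const int nl = ligand.nrow(), ns = site.nrow();
  const double c2 = cutoff * cutoff;
  IntegerVector bits(ns);
  for (int j = 0; j < ns; ++j) {
    const double sx = site(j, 0), sy = site(j, 1), sz = site(j, 2);
    int hit = 0;
    for (int i = 0; i < nl; ++i) {
      const double dx = ligand(i, 0) - sx;
      const double dy = ligand(i, 1) - sy;
      const double dz = ligand(i, 2) - sz;
      if (dx * dx + dy * dy + dz * dz <= c2) { hit = 1; break; }
    }
    bits[j] = hit;
  }
  return bits;
}

// RMSD over paired rows, no superposition (docking frame).
// [[Rcpp::export]]
double cpp_rmsd(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow();
  if (n != b.nrow()) stop("atom-count mismatch in RMSD");
  if (n == 0) stop("empty coordinate set in RMSD");
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = a(i, 0) - b(i, 0);
    const double dy = a(i, 1) - b(i, 1);
    const double dz = a(i, 2) - b(i, 2);
    acc += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(acc / n);
}
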