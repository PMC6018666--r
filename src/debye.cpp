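#include <Rcpp.h>
using namespace Rcpp;

// Debye double sum over atom pairs for a set of q values.
// ff is a (nq x natoms) matrix of per-atom form factors; xyz is
// (natoms x 3). Uses the pair symmetry: I(q) = sum_i f_i^2 +
// 2 * sum_{i<j} f_i f_j sin(q r_ij)/(q r_ij).
// [[Rcpp::export(name = ".debye_kernel")]]
NumericVector debye_kernel(NumericMatrix xyz, NumericMatrix ff,
                           NumericVector q) {
  const int n = xyz.nrow();
  const int nq = q.size();
  NumericVector I(nq);

  // pair distances (upper triangle)
  const int npair = n * (n - 1) / 2;
  std::vector<double> d(npair);
  {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
      for (int j = i + 1; j < n; ++j, ++k) {
        const double dx = xi - xyz(j, 0);
        const double dy = yi - xyz(j, 1);
        const double dz = zi - xyz(j, 2);
        d[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
  }

  for (int m = 0; m < nq; ++m) {
    const double qm = q[m];
    double acc = 0.0;
    // diagonal
    for (int i = 0; i < n; ++i) acc += ff(m, i) * ff(m, i);
    // off-diagonal
    int k = 0;
    if (qm == 0.0) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j, ++k)
          acc += 2.0 * ff(m, i) * ff(m, j);
    } else {
      for (int i = 0; i < n; ++i) {
        const double fi = ff(m, i);
        for (int j = i + 1; j < n; ++j, ++k) {
          const double x = qm * d[k];
          const double s = (x == 0.0) ? 1.0 : std::sin(x) / x;
          acc += 2.0 * fi * ff(m, j) * s;
        }
      }
    }
    I[m] = acc;
  }
  return I;
}

// Surrogate physical term: harmonic virtual bonds plus soft-sphere
// repulsion between non-bonded pairs closer than d0 (pairs within the
// same or adjacent residue of one chain are excluded).
// [[Rcpp::export(name = ".physical_kernel")]]
double physical_kernel(NumericMatrix xyz, IntegerVector bond_i,
                       IntegerVector bond_j, NumericVector bond_d0,
                       double k_bond, IntegerVector resno,
                       IntegerVector chain_id, double d0, double k_rep) {
  double e = 0.0;
  const int nb = bond_i.size();
  for (int b = 0; b < nb; ++b) {
    const int i = bond_i[b] - 1, j = bond_j[b] - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += k_bond * (d - bond_d0[b]) * (d - bond_d0[b]);
  }
  const int n = xyz.nrow();
  const double d02 = d0 * d0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain_id[i] == chain_id[j] &&
          std::abs(resno[i] - resno[j]) <= 1) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      if (dx > d0 || dx < -d0) continue;
      const double dy = xyz(i, 1) - xyz(j, 1);
      if (dy > d0 || dy < -d0) continue;
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < d02) {
        const double d = std::sqrt(r2);
        e += k_rep * (d0 - d) * (d0 - d);
      }
    }
  }
  return e;
}
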