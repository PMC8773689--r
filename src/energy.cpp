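#include <Rcpp.h>
using namespace Rcpp;

// Surrogate intermolecular nonbonded energy between two molecules:
//   Coulomb with distance-dependent dielectric eps(r) = 4r over formal-charge
//   centers:  E_c = coul_k * qi * qj / r^2, with r soft-floored at sigma so
//   the attraction between opposite charges stays bounded at contact
//   soft-sphere repulsion over heavy-atom pairs: min((sigma/r)^12, cap)
// Returns c(total, coulomb, repulsion, min_dist).
// [[Rcpp::export]]
NumericVector cpp_nonbonded(NumericMatrix xyzA, NumericVector qA,
                            LogicalVector heavyA, NumericMatrix xyzB,
                            NumericVector qB, LogicalVector heavyB,
                            double coul_k, double sigma, double cap) {
  int nA = xyzA.nrow(), nB = xyzB.nrow();
  double ecoul = 0.0, erep = 0.0, mind = R_PosInf;
  double sig2 = sigma * sigma;
  for (int i = 0; i < nA; ++i) {
    double xi = xyzA(i, 0), yi = xyzA(i, 1), zi = xyzA(i, 2);
    double qi = qA[i];
    bool hi = heavyA[i];
    for (int j = 0; j < nB; ++j) {
      double dx = xi - xyzB(j, 0), dy = yi - xyzB(j, 1), dz = zi - xyzB(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12) r2 = 1e-12;
      if (r2 < mind) mind = r2;
      if (qi != 0.0 && qB[j] != 0.0)
        ecoul += coul_k * qi * qB[j] / (r2 < sig2 ? sig2 : r2);
      if (hi && heavyB[j]) {
        double s6 = (sig2 / r2);
        s6 = s6 * s6 * s6;       // (sigma/r)^6
        double rep = s6 * s6;    // (sigma/r)^12
        erep += (rep > cap) ? cap : rep;
      }
    }
  }
  return NumericVector::create(ecoul + erep, ecoul, erep, std::sqrt(mind));
}

// Minimum inter-molecular atom distance.
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix xyzA, NumericMatrix xyzB) {
  double mind = R_PosInf;
  for (int i = 0; i < xyzA.nrow(); ++i)
    for (int j = 0; j < xyzB.nrow(); ++j) {
      double dx = xyzA(i, 0) - xyzB(j, 0);
      double dy = xyzA(i, 1) - xyzB(j, 1);
      double dz = xyzA(i, 2) - xyzB(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < mind) mind = r2;
    }
  return std::sqrt(mind);
}

// r^-6-averaged effective distance per restraint group.
// ip, il: 1-based atom indices into xyzP / xyzL; grp: 1-based group index.
// [[Rcpp::export]]
NumericVector cpp_group_deff(NumericMatrix xyzP, NumericMatrix xyzL,
                             IntegerVector ip, IntegerVector il,
                             IntegerVector grp, int ngroups) {
  NumericVector acc(ngroups, 0.0);
  int n = ip.size();
  for (int k = 0; k < n; ++k) {
    int i = ip[k] - 1, j = il[k] - 1;
    double dx = xyzP(i, 0) - xyzL(j, 0);
    double dy = xyzP(i, 1) - xyzL(j, 1);
    double dz = xyzP(i, 2) - xyzL(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0.0) stop("coincident atoms in restraint (distance 0)");
    acc[grp[k] - 1] += 1.0 / (r2 * r2 * r2);
  }
  NumericVector out(ngroups);
  for (int g = 0; g < ngroups; ++g)
    out[g] = (acc[g] > 0.0) ? std::pow(acc[g], -1.0 / 6.0) : NA_REAL;
  return out;
}
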