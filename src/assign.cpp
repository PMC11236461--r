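#include <Rcpp.h>
using namespace Rcpp;

// Capacity-constrained weighted assignment of individual groups to patches.
//
// unit_species : 0-based species index of each group, in assignment order
// unit_size    : number of individuals in each group
// W            : n_species x n_patches positive assignment weights
//                (W[s, p] = Area_p ^ beta_s)
// cap          : per-patch carrying capacity (individuals); a patch is
//                removed from the pool once its assigned total reaches cap
//
// Uses R's RNG stream so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix assign_groups_cpp(const IntegerVector& unit_species,
                                const IntegerVector& unit_size,
                                const NumericMatrix& W,
                                const NumericVector& cap) {
  const int n_units = unit_species.size();
  const int n_patch = W.ncol();
  const int n_sp = W.nrow();
  if (unit_size.size() != n_units) stop("unit_species and unit_size lengths differ");
  if (cap.size() != n_patch) stop("cap length must equal ncol(W)");

  IntegerMatrix N(n_patch, n_sp);
  std::vector<double> filled(n_patch, 0.0);
  std::vector<bool> full(n_patch, false);
  int n_open = n_patch;
  for (int p = 0; p < n_patch; ++p) {
    if (cap[p] <= 0) { full[p] = true; --n_open; }
  }

  for (int u = 0; u < n_units; ++u) {
    if (n_open == 0)
      stop("no non-full patch available for remaining individuals");
    const int s = unit_species[u];
    if (s < 0 || s >= n_sp) stop("species index out of range");
    double tot = 0.0;
    for (int p = 0; p < n_patch; ++p)
      if (!full[p]) tot += W(s, p);
    if (!(tot > 0.0))
      stop("assignment weights sum to zero over open patches");
    const double r = unif_rand() * tot;
    double acc = 0.0;
    int chosen = -1;
    for (int p = 0; p < n_patch; ++p) {
      if (full[p]) continue;
      acc += W(s, p);
      if (r <= acc) { chosen = p; break; }
    }
    if (chosen < 0) {  // guard against floating-point undershoot
      for (int p = n_patch - 1; p >= 0; --p)
        if (!full[p]) { chosen = p; break; }
    }
    N(chosen, s) += unit_size[u];
    filled[chosen] += unit_size[u];
    if (filled[chosen] >= cap[chosen]) { full[chosen] = true; --n_open; }
  }
  return N;
}
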