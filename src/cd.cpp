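#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Cyclic coordinate descent for one response column, Gram form.
//
// C  : p x p Gram matrix (1/n) X'X with unit diagonal
// cv : length-p cross-products (1/n) X'y
// Coordinate update: beta_j <- S(cv_j - sum_{k != j, beta_k != 0} C_jk beta_k, lam)
// (unit denominator because C_jj = 1). Gradients are accumulated over the
// active (nonzero) set only -- the "covariance updates" strategy; no
// residual vector is maintained.
//
// Schedule: (1) one full sweep over all p coordinates; (2) sweeps over the
// active set until the max absolute coordinate change in a sweep < tol;
// (3) one more full sweep -- if it activates a new coordinate or changes
// any coordinate by >= tol, back to (2), else converged. One "iteration"
// is one sweep (full or active); n_iter_max bounds total sweeps.
//
// capacity bounds the number of simultaneously nonzero coefficients; an
// activation beyond it sets the overflow flag and aborts.
// [[Rcpp::export]]
List cd_solve_voxel_cpp(NumericMatrix C, NumericVector cv, double lam,
                        NumericVector init, int n_iter_max, double tol,
                        int capacity) {
  const int p = C.ncol();
  const double *Cp = REAL(C);

  std::vector<double> beta(init.begin(), init.end());
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  active.reserve(64);
  int nnz = 0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      active.push_back(j);
      in_active[j] = 1;
      ++nnz;
    }
  }

  int sweeps = 0;
  bool converged = false, overflow = false, activated = false;

  // one pass over the coordinates listed in `order`
  auto sweep = [&](const std::vector<int> &order, bool full) -> double {
    double maxchange = 0.0;
    for (size_t ii = 0; ii < order.size(); ++ii) {
      const int j = order[ii];
      const double *Cj = Cp + (size_t)j * p;  // column j (= row j, symmetric)
      double g = cv[j];
      for (size_t a = 0; a < active.size(); ++a) {
        const int k = active[a];
        if (k != j && beta[k] != 0.0) g -= Cj[k] * beta[k];
      }
      const double bnew = soft(g, lam);
      const double d = std::fabs(bnew - beta[j]);
      if (d > maxchange) maxchange = d;
      if (bnew != 0.0 && beta[j] == 0.0) {
        ++nnz;
        if (nnz > capacity) {
          overflow = true;
          beta[j] = bnew;
          return maxchange;
        }
        if (!in_active[j]) {
          active.push_back(j);
          in_active[j] = 1;
          if (full) activated = true;
        }
      } else if (bnew == 0.0 && beta[j] != 0.0) {
        --nnz;
      }
      beta[j] = bnew;
    }
    return maxchange;
  };

  // drop zeroed coordinates from the active list (after full sweeps)
  auto prune = [&]() {
    std::vector<int> keep;
    keep.reserve(active.size());
    for (size_t a = 0; a < active.size(); ++a) {
      const int k = active[a];
      if (beta[k] != 0.0) keep.push_back(k); else in_active[k] = 0;
    }
    active.swap(keep);
  };

  std::vector<int> fullorder(p);
  for (int j = 0; j < p; ++j) fullorder[j] = j;

  bool budget = false;
  if (sweeps >= n_iter_max) {
    budget = true;
  } else {
    ++sweeps;
    activated = false;
    double mc = sweep(fullorder, true);
    if (!overflow) {
      prune();
      if (mc < tol && !activated) converged = true;
    }
  }

  while (!converged && !overflow && !budget) {
    // (2) active-set sweeps until stable
    for (;;) {
      if (sweeps >= n_iter_max) { budget = true; break; }
      ++sweeps;
      const double m = sweep(active, false);
      if (overflow || m < tol) break;
    }
    if (budget || overflow) break;
    // (3) full sweep to admit newcomers
    if (sweeps >= n_iter_max) { budget = true; break; }
    ++sweeps;
    activated = false;
    const double mc = sweep(fullorder, true);
    if (overflow) break;
    prune();
    if (mc < tol && !activated) converged = true;
  }

  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iterations"] = sweeps,
                      _["converged"] = converged,
                      _["overflow"] = overflow,
                      _["n_nonzero"] = nnz);
}
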