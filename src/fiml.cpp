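// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// FIML -2LL contribution of one group from per-missingness-pattern
// sufficient statistics. Rows sharing a pattern contribute
//   n * (k*log(2*pi) + log|S_p|) + n * tr(S_p^-1 C) + n * (m - mu_p)' S_p^-1 (m - mu_p)
// where S_p, mu_p are the sub-covariance / sub-mean on the observed
// coordinates, m the pattern sample mean and C the (ML, /n) scatter.
// A non-positive-definite sub-covariance yields a large finite penalty that
// grows with the most negative eigenvalue, so optimizers are pushed back
// into the feasible region rather than stopped by an error.
static double fiml_group(List pats, const arma::vec& mu_g,
                         const arma::mat& sig_g) {
    const double log2pi = std::log(2.0 * M_PI);
    double total = 0.0;
    int n_pat = pats.size();
    for (int p = 0; p < n_pat; ++p) {
        List pat = pats[p];
        arma::uvec idx = as<arma::uvec>(pat["idx"]) - 1;
        double n = as<double>(pat["n"]);
        arma::vec xbar = as<arma::vec>(pat["xbar"]);
        arma::mat scat = as<arma::mat>(pat["scatter"]);
        arma::mat sub = sig_g.submat(idx, idx);
        arma::vec mu_p = mu_g.elem(idx);
        arma::mat L;
        bool ok = arma::chol(L, sub, "lower");
        if (!ok) {
            arma::vec ev;
            bool eok = arma::eig_sym(ev, arma::symmatu(sub));
            double worst = eok ? ev.min() : -1.0;
            total += 1e10 + 1e10 * std::abs(std::min(worst, 0.0));
            continue;
        }
        double logdet = 2.0 * arma::sum(arma::log(L.diag()));
        arma::vec d = xbar - mu_p;
        arma::vec z = arma::solve(arma::trimatl(L), d);
        // tr(sub^-1 scat) via the Cholesky factor
        arma::mat W = arma::solve(arma::trimatl(L), scat);
        arma::mat V = arma::solve(arma::trimatl(L), W.t());
        double k = static_cast<double>(idx.n_elem);
        total += n * (k * log2pi + logdet) + n * arma::trace(V) +
                 n * arma::dot(z, z);
    }
    return total;
}

// General entry point: per-group mean vectors and covariance matrices
// supplied from R (used by the saturated models and sex-limitation fits).
// [[Rcpp::export(name = ".fiml_m2ll_cpp")]]
double fiml_m2ll_cpp(List stats, List mu, List sigma) {
    double total = 0.0;
    int n_groups = stats.size();
    for (int g = 0; g < n_groups; ++g) {
        total += fiml_group(stats[g], as<arma::vec>(mu[g]),
                            as<arma::mat>(sigma[g]));
    }
    return total;
}

// Fast path for models without sex differences: the expected pair
// covariance is assembled here from the free lower-triangular path
// matrices. `par` is laid out as the concatenated (11, 21, 22) entries of
// the free matrices flagged in `free_mats` (X, Y, Z order), followed by
// the two wave means. `kA`/`kY` give each group's co-twin sharing
// coefficient for the A and C-or-D factors.
// [[Rcpp::export(name = ".m2ll_nosex_cpp")]]
double m2ll_nosex_cpp(NumericVector par, List stats,
                      NumericVector kA, NumericVector kY,
                      LogicalVector free_mats) {
    int pos = 0;
    arma::mat A(2, 2, arma::fill::zeros), C(2, 2, arma::fill::zeros),
        E(2, 2, arma::fill::zeros);
    arma::mat* mats[3] = { &A, &C, &E };
    for (int m = 0; m < 3; ++m) {
        if (!free_mats[m]) continue;
        arma::mat L(2, 2, arma::fill::zeros);
        L(0, 0) = par[pos]; L(1, 0) = par[pos + 1]; L(1, 1) = par[pos + 2];
        pos += 3;
        *mats[m] = L * L.t();
    }
    arma::vec mu(4);
    mu(0) = par[pos]; mu(1) = par[pos + 1];
    mu(2) = par[pos]; mu(3) = par[pos + 1];
    arma::mat W = A + C + E;
    double total = 0.0;
    int n_groups = stats.size();
    for (int g = 0; g < n_groups; ++g) {
        arma::mat B = kA[g] * A + kY[g] * C;
        arma::mat sig(4, 4);
        sig.submat(0, 0, 1, 1) = W;
        sig.submat(2, 2, 3, 3) = W;
        sig.submat(0, 2, 1, 3) = B;
        sig.submat(2, 0, 3, 1) = B.t();
        total += fiml_group(stats[g], mu, sig);
    }
    return total;
}
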