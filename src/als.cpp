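#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Alternating least squares low-rank completion on observed entries.
//
// M       n x d matrix with NA (NaN) marking missing entries
// U0      n x r initial row-factor matrix (caller seeds it)
// maxIter maximum number of full sweeps (solve V, then solve U)
// tol     stop when the relative change of the observed-entry residual
//         norm between sweeps drops below tol
// ridge   small Tikhonov term stabilising the per-row/column solves
//
// Returns the low-rank reconstruction U * V^T with observed entries
// restored to their input values, plus convergence diagnostics.
// [[Rcpp::export]]
Rcpp::List als_complete_cpp(const arma::mat& M, const arma::mat& U0,
                            int maxIter, double tol, double ridge) {
    const uword n = M.n_rows, d = M.n_cols;
    const uword r = U0.n_cols;

    // Per-row and per-column observed index sets.
    std::vector<uvec> rowObs(n), colObs(d);
    for (uword i = 0; i < n; ++i)
        rowObs[i] = find_finite(M.row(i).t());
    for (uword j = 0; j < d; ++j)
        colObs[j] = find_finite(M.col(j));

    mat U = U0;
    mat V(d, r, fill::zeros);
    const uvec obsAll = find_finite(M);
    const vec mObs = M.elem(obsAll);

    // Residual of the zero reconstruction; the first sweep's relative
    // change is measured against this baseline.
    double prev = norm(mObs, 2);
    if (prev <= 0.0) prev = 1e-12;

    int it = 0;
    double res = prev, rel = datum::inf;
    mat eyeR = ridge * eye<mat>(r, r);

    for (it = 1; it <= maxIter; ++it) {
        // Solve each measure's factor from the individuals observing it.
        for (uword j = 0; j < d; ++j) {
            const uvec& o = colObs[j];
            mat Uo = U.rows(o);
            vec y = M.col(j);
            V.row(j) = solve(Uo.t() * Uo + eyeR, Uo.t() * y.elem(o),
                             solve_opts::likely_sympd).t();
        }
        // Solve each individual's factor from their observed measures.
        for (uword i = 0; i < n; ++i) {
            const uvec& o = rowObs[i];
            mat Vo = V.rows(o);
            vec y = M.row(i).t();
            U.row(i) = solve(Vo.t() * Vo + eyeR, Vo.t() * y.elem(o),
                             solve_opts::likely_sympd).t();
        }
        mat R = U * V.t();
        res = norm(mObs - R.elem(obsAll), 2);
        rel = std::fabs(prev - res) / std::max(prev, 1e-12);
        if (rel < tol) break;
        prev = res;
    }
    if (it > maxIter) it = maxIter;

    mat completed = U * V.t();
    completed.elem(obsAll) = mObs;

    return Rcpp::List::create(
        Rcpp::Named("completed") = completed,
        Rcpp::Named("iterations") = it,
        Rcpp::Named("residual") = res,
        Rcpp::Named("relChange") = rel);
}
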