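// Weighted graphical lasso: block coordinate descent (Friedman-style)
// generalized to an elementwise penalty matrix Lambda (Lambda_ii = 0).
// Maximizes logdet(Omega) - tr(Omega S) - sum_ij Lambda_ij |Omega_ij|.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// coordinate descent for the block subproblem
//   min_b 0.5 b' W11 b - s12' b + sum_k lam_k |b_k|
static void lassoCD(const mat& W11, const vec& s12, const vec& lam,
                    vec& beta, double tol, int maxIter) {
    const uword q = beta.n_elem;
    vec Wb = W11 * beta;
    for (int it = 0; it < maxIter; ++it) {
        double maxDiff = 0.0;
        for (uword k = 0; k < q; ++k) {
            const double bk = beta(k);
            const double r = s12(k) - (Wb(k) - W11(k, k) * bk);
            double bNew = 0.0;
            if (r > lam(k))       bNew = (r - lam(k)) / W11(k, k);
            else if (r < -lam(k)) bNew = (r + lam(k)) / W11(k, k);
            const double d = bNew - bk;
            if (d != 0.0) {
                beta(k) = bNew;
                Wb += d * W11.col(k);
                const double ad = std::fabs(d);
                if (ad > maxDiff) maxDiff = ad;
            }
        }
        if (maxDiff < tol) break;
    }
}

// One full solve. W, B are modified in place (warm starts across rho).
// B column j holds the lasso coefficients for block j (entry j unused).
static void wglassoCore(const mat& S, const mat& Lambda, double tol,
                        int maxIter, mat& W, mat& B,
                        int& nIter, bool& converged) {
    const uword p = S.n_rows;
    const double offAvg = p > 1 ?
        (accu(abs(S)) - accu(abs(S.diag()))) / (p * (p - 1.0)) : 0.0;
    const double thr = tol * std::max(offAvg, 1e-12);
    const double innerTol = thr / 10.0;

    uvec all = regspace<uvec>(0, p - 1);
    converged = false;
    nIter = 0;
    for (int it = 0; it < maxIter; ++it) {
        double change = 0.0;
        for (uword j = 0; j < p; ++j) {
            uvec idx = find(all != j);
            mat W11 = W.submat(idx, idx);
            vec s12 = S.col(j);  s12 = s12.elem(idx);
            vec lam = Lambda.col(j); lam = lam.elem(idx);
            vec beta = B.col(j); beta = beta.elem(idx);
            lassoCD(W11, s12, lam, beta, innerTol, 10000);
            vec w12 = W11 * beta;
            for (uword k = 0; k < p - 1; ++k) {
                const uword r = idx(k);
                change += std::fabs(W(r, j) - w12(k));
                W(r, j) = w12(k);
                W(j, r) = w12(k);
                B(r, j) = beta(k);
            }
        }
        nIter = it + 1;
        if (change / (p * (p - 1.0)) < thr) { converged = true; break; }
    }
}

static mat recoverTheta(const mat& S, const mat& W, const mat& B) {
    const uword p = S.n_rows;
    mat Theta(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
        double dot = 0.0;
        for (uword r = 0; r < p; ++r)
            if (r != j) dot += W(r, j) * B(r, j);
        const double tjj = 1.0 / (W(j, j) - dot);
        Theta(j, j) = tjj;
        for (uword r = 0; r < p; ++r)
            if (r != j) Theta(r, j) = -B(r, j) * tjj;
    }
    return (Theta + Theta.t()) / 2.0;
}

// [[Rcpp::export]]
Rcpp::List wglasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                       double tol, int maxIter) {
    mat W = S;
    mat B(S.n_rows, S.n_cols, fill::zeros);
    int nIter; bool converged;
    wglassoCore(S, Lambda, tol, maxIter, W, B, nIter, converged);
    mat Theta = recoverTheta(S, W, B);
    return Rcpp::List::create(
        Rcpp::Named("theta") = Theta,
        Rcpp::Named("w") = W,
        Rcpp::Named("n_iter") = nIter,
        Rcpp::Named("converged") = converged);
}

// Full regularization path with warm starts, largest rho first.
// rhos must be sorted decreasing; P is the prior (weight) matrix.
// [[Rcpp::export]]
Rcpp::List wglasso_path_cpp(const arma::mat& S, const arma::mat& P,
                            const arma::vec& rhos, double tol, int maxIter) {
    const uword m = rhos.n_elem;
    mat W = S;
    mat B(S.n_rows, S.n_cols, fill::zeros);
    Rcpp::List thetas(m);
    Rcpp::IntegerVector iters(m);
    Rcpp::LogicalVector conv(m);
    for (uword k = 0; k < m; ++k) {
        mat Lambda = rhos(k) * P;
        Lambda.diag().zeros();
        int nIter; bool converged;
        wglassoCore(S, Lambda, tol, maxIter, W, B, nIter, converged);
        thetas[k] = recoverTheta(S, W, B);
        iters[k] = nIter;
        conv[k] = converged;
    }
    return Rcpp::List::create(
        Rcpp::Named("thetas") = thetas,
        Rcpp::Named("n_iter") = iters,
        Rcpp::Named("converged") = conv);
}
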