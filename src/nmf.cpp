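#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Fast NNLS (Bro & de Jong 1997) on the normal equations:
// min ||Z x - f||^2 s.t. x >= 0, given G = Z'Z and b = Z'f.
// Exact active-set solution; G may be rank deficient (pinv fallback).
static vec fnnls(const mat& G, const vec& b) {
    const uword n = G.n_cols;
    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = b;
    const double tol = 10.0 * datum::eps * norm(G, 1) * (double)n;
    const uword max_outer = 30 * n + 10;

    for (uword outer = 0; outer < max_outer; ++outer) {
        // most violating free coordinate
        int t = -1;
        double wmax = tol;
        for (uword i = 0; i < n; ++i) {
            if (!passive[i] && w(i) > wmax) { wmax = w(i); t = (int)i; }
        }
        if (t < 0) break;
        passive[t] = true;

        for (uword inner = 0; inner < max_outer; ++inner) {
            uvec P(n);
            uword np = 0;
            for (uword i = 0; i < n; ++i) if (passive[i]) P(np++) = i;
            P.resize(np);

            vec sP;
            mat GPP = G.submat(P, P);
            bool ok = solve(sP, GPP, b.elem(P),
                            solve_opts::likely_sympd + solve_opts::no_approx);
            if (!ok) sP = pinv(GPP) * b.elem(P);

            if (np > 0 && sP.min() > 0) {
                x.zeros();
                x.elem(P) = sP;
                break;
            }
            // step back to the feasible boundary
            double alpha = datum::inf;
            for (uword idx = 0; idx < np; ++idx) {
                uword i = P(idx);
                if (sP(idx) <= 0) {
                    double denom = x(i) - sP(idx);
                    double a = denom > 0 ? x(i) / denom : 0.0;
                    if (a < alpha) alpha = a;
                }
            }
            vec s(n, fill::zeros);
            s.elem(P) = sP;
            x += alpha * (s - x);
            for (uword idx = 0; idx < np; ++idx) {
                uword i = P(idx);
                if (x(i) <= tol) { passive[i] = false; x(i) = 0.0; }
            }
        }
        w = b - G * x;
    }
    return x;
}

//' @noRd
// [[Rcpp::export(name = ".nnls_cols_cpp")]]
arma::mat nnls_cols_cpp(const arma::mat& A, const arma::mat& B) {
    mat G = A.t() * A;
    mat AtB = A.t() * B;
    mat X(A.n_cols, B.n_cols);
    for (uword j = 0; j < B.n_cols; ++j) X.col(j) = fnnls(G, AtB.col(j));
    return X;
}

static Rcpp::List nmf_result(const mat& E, const mat& W, const mat& C,
                             const std::vector<double>& res,
                             int it, bool converged) {
    return Rcpp::List::create(
        Rcpp::Named("W") = W,
        Rcpp::Named("C") = C,
        Rcpp::Named("residuals") = res,
        Rcpp::Named("iterations") = it,
        Rcpp::Named("converged") = converged);
}

// Exact block-coordinate NMF (HALS): each synergy's W column / C row is
// replaced by the exact NNLS minimizer given all other components.
// [[Rcpp::export(name = ".nmf_hals_cpp")]]
Rcpp::List nmf_hals_cpp(const arma::mat& E, arma::mat W, arma::mat C,
                        int max_iter, double tol) {
    std::vector<double> res;
    res.reserve(max_iter);
    double prev = datum::inf;
    bool converged = false;
    int it = 0;
    const uword k = W.n_cols;

    for (it = 1; it <= max_iter; ++it) {
        mat WtW = W.t() * W;
        mat WtE = W.t() * E;
        for (uword j = 0; j < k; ++j) {
            double d = WtW(j, j);
            if (d <= 0) { C.row(j).zeros(); continue; }
            rowvec numer = WtE.row(j) - WtW.row(j) * C + d * C.row(j);
            C.row(j) = clamp(numer / d, 0.0, datum::inf);
        }
        mat CCt = C * C.t();
        mat ECt = E * C.t();
        for (uword j = 0; j < k; ++j) {
            double d = CCt(j, j);
            if (d <= 0) { W.col(j).zeros(); continue; }
            vec numer = ECt.col(j) - W * CCt.col(j) + d * W.col(j);
            W.col(j) = clamp(numer / d, 0.0, datum::inf);
        }
        double r = accu(square(E - W * C));
        res.push_back(r);
        if (it > 1 && std::abs(prev - r) <= tol * std::max(prev, 1e-300)) {
            converged = true;
            break;
        }
        prev = r;
    }
    if (it > max_iter) it = max_iter;
    return nmf_result(E, W, C, res, it, converged);
}

// Alternating NNLS: at each iteration every column of C (and, transposed,
// every row of W) is solved exactly by FNNLS given the other factor.
// [[Rcpp::export(name = ".nmf_anls_cpp")]]
Rcpp::List nmf_anls_cpp(const arma::mat& E, arma::mat W, arma::mat C,
                        int max_iter, double tol) {
    std::vector<double> res;
    res.reserve(max_iter);
    double prev = datum::inf;
    bool converged = false;
    int it = 0;

    for (it = 1; it <= max_iter; ++it) {
        mat G = W.t() * W;
        mat WtE = W.t() * E;
        for (uword j = 0; j < C.n_cols; ++j) C.col(j) = fnnls(G, WtE.col(j));
        mat CCt = C * C.t();
        mat ECt = E * C.t();   // m x k; row i holds C * E.row(i)'
        for (uword i = 0; i < W.n_rows; ++i)
            W.row(i) = fnnls(CCt, ECt.row(i).t()).t();
        double r = accu(square(E - W * C));
        res.push_back(r);
        if (it > 1 && std::abs(prev - r) <= tol * std::max(prev, 1e-300)) {
            converged = true;
            break;
        }
        prev = r;
    }
    if (it > max_iter) it = max_iter;
    return nmf_result(E, W, C, res, it, converged);
}

// Lee-Seung multiplicative updates (Frobenius objective).
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& E, arma::mat W, arma::mat C,
                      int max_iter, double tol) {
    const double eps = 1e-12;
    std::vector<double> res;
    res.reserve(max_iter);
    double prev = datum::inf;
    bool converged = false;
    int it = 0;

    for (it = 1; it <= max_iter; ++it) {
        C %= (W.t() * E) / (W.t() * W * C + eps);
        W %= (E * C.t()) / (W * C * C.t() + eps);
        double r = accu(square(E - W * C));
        res.push_back(r);
        if (it > 1 && std::abs(prev - r) <= tol * std::max(prev, 1e-300)) {
            converged = true;
            break;
        }
        prev = r;
    }
    if (it > max_iter) it = max_iter;
    return nmf_result(E, W, C, res, it, converged);
}
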