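// Kabsch superposition and batched C-alpha RMSD kernels.
// Coordinates are n x 3 row-point matrices (Angstrom); decoy sets are
// n x 3 x N cubes so one-vs-many and all-pairs loops stay in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Optimal proper rotation R (applied as x * R to row points) mapping the
// centered A onto the centered B, plus the minimized RMSD.
static double kabsch_core(const mat& A, const mat& B, mat& R) {
    mat Ac = A.each_row() - mean(A, 0);
    mat Bc = B.each_row() - mean(B, 0);
    mat M = Ac.t() * Bc;          // 3 x 3 cross-covariance
    mat U, V;
    vec s;
    if (!svd(U, s, V, M)) Rcpp::stop("SVD failed in superposition");
    double sgn = (det(U) * det(V) < 0.0) ? -1.0 : 1.0;
    vec dvec = {1.0, 1.0, sgn};   // reflection correction
    R = U * diagmat(dvec) * V.t();
    mat resid = Ac * R - Bc;
    double msd = accu(resid % resid) / static_cast<double>(A.n_rows);
    return std::sqrt(std::max(msd, 0.0));
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
Rcpp::List kabsch_cpp(const arma::mat& A, const arma::mat& B) {
    if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
        Rcpp::stop("coordinate matrices must be n x 3 with equal n");
    mat R;
    double rmsd = kabsch_core(A, B, R);
    rowvec t = mean(B, 0) - mean(A, 0) * R;
    return Rcpp::List::create(Rcpp::Named("rmsd") = rmsd,
                              Rcpp::Named("rotation") = R,
                              Rcpp::Named("translation") = t.t());
}

// [[Rcpp::export(name = ".rmsd_one_to_many_cpp")]]
arma::vec rmsd_one_to_many_cpp(const arma::cube& coords, int i,
                               const arma::ivec& idx) {
    mat A = coords.slice(i - 1);
    vec out(idx.n_elem);
    mat R;
    for (uword k = 0; k < idx.n_elem; ++k)
        out(k) = kabsch_core(A, coords.slice(idx(k) - 1), R);
    return out;
}

// [[Rcpp::export(name = ".rmsd_pairwise_cpp")]]
arma::mat rmsd_pairwise_cpp(const arma::cube& coords) {
    uword N = coords.n_slices;
    mat D(N, N, fill::zeros);
    mat R;
    for (uword i = 0; i + 1 < N; ++i)
        for (uword j = i + 1; j < N; ++j) {
            double r = kabsch_core(coords.slice(i), coords.slice(j), R);
            D(i, j) = r;
            D(j, i) = r;
        }
    return D;
}
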