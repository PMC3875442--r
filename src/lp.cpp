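// Mehrotra predictor-corrector interior-point solver for the sparse
// weight-estimation linear program
//
//   min  sum_j (wplus_j + wminus_j) + sum_t theta*c_t (rplus_t + rminus_t)
//   s.t. B (wplus - wminus stacked with bias split) + rplus - rminus = z,
//        all variables >= 0,
//
// written in standard equality form  min c'x  s.t.  A x = b, x >= 0  with
// A = [B | I | -I].  The normal matrix A D A' = B D1 B' + diag(d2 + d3) is
// formed explicitly (m x m) and factorized by Cholesky; m is the number of
// valid transformed equations, so this stays small.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// y = A v with v split as (v1: p, v2: m, v3: m)
vec Aprod(const mat& B, const vec& v) {
    const uword p = B.n_cols, m = B.n_rows;
    return B * v.subvec(0, p - 1) + v.subvec(p, p + m - 1) -
           v.subvec(p + m, p + 2 * m - 1);
}

// v = A' y
vec Atprod(const mat& B, const vec& y) {
    vec v(B.n_cols + 2 * B.n_rows);
    v.subvec(0, B.n_cols - 1) = B.t() * y;
    v.subvec(B.n_cols, B.n_cols + B.n_rows - 1) = y;
    v.subvec(B.n_cols + B.n_rows, v.n_elem - 1) = -y;
    return v;
}

mat normalMatrix(const mat& B, const vec& d) {
    const uword p = B.n_cols, m = B.n_rows;
    mat Bd = B;
    Bd.each_row() %= d.subvec(0, p - 1).t();
    mat M = Bd * B.t();
    M.diag() += d.subvec(p, p + m - 1) + d.subvec(p + m, p + 2 * m - 1);
    return M;
}

bool cholSolve(const mat& M, const vec& rhs, vec& sol) {
    mat L;
    mat Mreg = symmatu(M);
    double reg = 1e-13 * (1.0 + M.diag().max());
    for (int k = 0; k < 8; ++k) {
        try {
            if (chol(L, Mreg, "lower") &&
                solve(sol, trimatl(L), rhs,
                      solve_opts::no_approx + solve_opts::fast)) {
                if (solve(sol, trimatu(L.t()), vec(sol),
                          solve_opts::no_approx + solve_opts::fast) &&
                    sol.is_finite())
                    return true;
            }
        } catch (...) {
            // fall through to regularized retry
        }
        Mreg.diag() += reg;
        reg *= 100.0;
    }
    return false;
}

double maxStep(const vec& x, const vec& dx) {
    double a = 1.0;
    for (uword i = 0; i < x.n_elem; ++i)
        if (dx[i] < 0) a = std::min(a, -x[i] / dx[i]);
    return a;
}

} // namespace

// Revised simplex fallback for the same LP.  The structure supplies a
// starting basic feasible solution for free (r+_t or r-_t = |z_t|), so no
// phase-1 is needed.  The basis factor is recomputed every iteration for
// numerical stability; Bland's rule guards against cycling on the highly
// degenerate exact-fit instances this fallback exists for.
// [[Rcpp::export(name = ".simplexLadLP")]]
Rcpp::List simplexLadLP(const arma::mat& B, const arma::vec& z,
                        const arma::vec& costB, const arma::vec& costR) {
    const uword p = B.n_cols, m = B.n_rows;
    const uword N = p + 2 * m;
    mat A = join_rows(B, eye(m, m), -eye(m, m));
    vec c(N);
    c.subvec(0, p - 1) = costB;
    c.subvec(p, p + m - 1) = costR;
    c.subvec(p + m, N - 1) = costR;
    const double cscale = std::max(1.0, norm(c, "inf"));
    c /= cscale;

    uvec basis(m);
    for (uword t = 0; t < m; ++t) basis[t] = (z[t] >= 0) ? p + t : p + m + t;
    std::vector<bool> inBasis(N, false);
    for (uword t = 0; t < m; ++t) inBasis[basis[t]] = true;

    const uword maxit = 200 * m + 5000;
    const uword blandAfter = 20 * m + 500;
    std::string status = "iteration_limit";
    vec xB = abs(z);

    for (uword iter = 0; iter < maxit; ++iter) {
        mat Bmat = A.cols(basis);
        vec y, xb;
        bool ok1, ok2;
        try {
            ok1 = solve(y, Bmat.t(), c.elem(basis));
            ok2 = solve(xb, Bmat, z);
        } catch (...) {
            ok1 = ok2 = false;
        }
        if (!ok1 || !ok2 || !y.is_finite() || !xb.is_finite())
            return Rcpp::List::create(Rcpp::Named("status") = "singular_basis");
        xB = clamp(xb, 0.0, datum::inf);  // wipe round-off negatives

        vec red = c - A.t() * y;
        const double tolr = 1e-9 * (1.0 + norm(c, "inf"));
        sword enter = -1;
        if (iter < blandAfter) {  // Dantzig: most negative reduced cost
            double best = -tolr;
            for (uword j = 0; j < N; ++j)
                if (!inBasis[j] && red[j] < best) { best = red[j]; enter = j; }
        } else {                  // Bland: first eligible index
            for (uword j = 0; j < N; ++j)
                if (!inBasis[j] && red[j] < -tolr) { enter = j; break; }
        }
        if (enter < 0) { status = "solved"; break; }

        vec dir;
        try {
            if (!solve(dir, Bmat, A.col((uword)enter))) dir.reset();
        } catch (...) { dir.reset(); }
        if (dir.n_elem == 0 || !dir.is_finite())
            return Rcpp::List::create(Rcpp::Named("status") = "singular_basis");

        sword leave = -1;
        double step = datum::inf;
        for (uword i = 0; i < m; ++i) {
            if (dir[i] > 1e-10) {
                double ratio = xB[i] / dir[i];
                if (ratio < step - 1e-12 ||
                    (iter >= blandAfter && ratio < step + 1e-12 &&
                     (leave < 0 || basis[i] < basis[leave]))) {
                    step = ratio;
                    leave = i;
                }
            }
        }
        if (leave < 0) { status = "unbounded"; break; }

        inBasis[basis[leave]] = false;
        inBasis[enter] = true;
        basis[leave] = enter;
    }

    if (status != "solved")
        return Rcpp::List::create(Rcpp::Named("status") = status);

    vec x(N, fill::zeros);
    x.elem(basis) = xB;
    return Rcpp::List::create(
        Rcpp::Named("beta") = x.subvec(0, p - 1),
        Rcpp::Named("rplus") = x.subvec(p, p + m - 1),
        Rcpp::Named("rminus") = x.subvec(p + m, N - 1),
        Rcpp::Named("objective") = cscale * dot(c, x),
        Rcpp::Named("status") = status);
}

// [[Rcpp::export(name = ".ladL1LP")]]
Rcpp::List ladL1LP(const arma::mat& B, const arma::vec& z,
                   const arma::vec& costB, const arma::vec& costR,
                   double tol = 1e-9, int maxit = 100) {
    const uword p = B.n_cols, m = B.n_rows;
    const uword N = p + 2 * m;

    vec c(N);
    c.subvec(0, p - 1) = costB;
    c.subvec(p, p + m - 1) = costR;
    c.subvec(p + m, N - 1) = costR;
    const double cscale = std::max(1.0, norm(c, "inf"));
    c /= cscale;
    const vec b = z;

    // Mehrotra starting point from least-squares heuristics; AA' = BB' + 2I
    mat AAt = B * B.t();
    AAt.diag() += 2.0;
    vec x, y, s, tmp;
    if (!cholSolve(AAt, b, tmp))
        return Rcpp::List::create(Rcpp::Named("status") = "start_failure");
    x = Atprod(B, tmp);
    if (!cholSolve(AAt, Aprod(B, c), tmp))
        return Rcpp::List::create(Rcpp::Named("status") = "start_failure");
    y = tmp;
    s = c - Atprod(B, y);
    double dx = std::max(0.0, -1.5 * x.min());
    double ds = std::max(0.0, -1.5 * s.min());
    x += dx;
    s += ds;
    double xs = dot(x, s);
    x += 0.5 * xs / accu(s);
    s += 0.5 * xs / accu(x);

    const double bn = 1.0 + norm(b, 2), cn = 1.0 + norm(c, 2);
    std::string status = "iteration_limit";
    int iter = 0;
    // best iterate seen, by worst KKT measure; double precision cannot
    // push the normal equations much below ~1e-9, so the loop may thrash
    // after effective convergence and the snapshot is what we return
    vec xBest = x, yBest = y, sBest = s;
    double qBest = datum::inf;

    for (iter = 0; iter < maxit; ++iter) {
        vec rb = Aprod(B, x) - b;
        vec rc = Atprod(B, y) + s - c;
        double mu = dot(x, s) / N;
        double gap = dot(x, s) / (1.0 + std::abs(dot(c, x)));
        double q = std::max({norm(rb, 2) / bn, norm(rc, 2) / cn, gap});
        if (x.is_finite() && q < qBest) {
            qBest = q;
            xBest = x;
            yBest = y;
            sBest = s;
        }
        if (q < tol) {
            status = "solved";
            break;
        }
        if (!x.is_finite() || !s.is_finite() || !y.is_finite()) {
            status = "numerical_failure";
            break;
        }

        // clamp the scaling to keep the normal matrix finite when primal
        // and dual variables vanish together (degenerate exact-fit systems)
        vec d = clamp(x / s, 1e-14, 1e14);
        mat M = normalMatrix(B, d);

        // affine scaling (predictor) direction
        vec rhs = Aprod(B, x - d % rc) - rb;
        vec dy_aff;
        if (!cholSolve(M, rhs, dy_aff)) {
            status = "numerical_failure";
            break;
        }
        vec ds_aff = -rc - Atprod(B, dy_aff);
        vec dx_aff = -x - d % ds_aff;

        double ap = maxStep(x, dx_aff), ad = maxStep(s, ds_aff);
        double mu_aff = dot(x + ap * dx_aff, s + ad * ds_aff) / N;
        double sigma = std::pow(mu_aff / mu, 3);

        // corrector
        vec v = (sigma * mu - dx_aff % ds_aff) / s;
        vec dy;
        if (!cholSolve(M, rhs - Aprod(B, v), dy)) {
            status = "numerical_failure";
            break;
        }
        vec dsv = -rc - Atprod(B, dy);
        vec dxv = -x - d % dsv + v;

        double eta = (mu < 1e-6) ? 0.999 : 0.995;
        ap = std::min(1.0, eta * maxStep(x, dxv));
        ad = std::min(1.0, eta * maxStep(s, dsv));
        if (ap < 1e-8 && ad < 1e-8) {
            status = "stalled";
            break;
        }
        x += ap * dxv;
        y += ad * dy;
        s += ad * dsv;
    }

    // report the best iterate; a stalled run whose snapshot is already at
    // near-machine KKT quality is still usable ("acceptable")
    if (status != "solved" && qBest < 1e-7) status = "acceptable";

    vec beta = xBest.subvec(0, p - 1);
    vec rplus = xBest.subvec(p, p + m - 1);
    vec rminus = xBest.subvec(p + m, N - 1);
    return Rcpp::List::create(
        Rcpp::Named("beta") = beta, Rcpp::Named("rplus") = rplus,
        Rcpp::Named("rminus") = rminus,
        Rcpp::Named("objective") = cscale * dot(c, xBest),
        Rcpp::Named("iterations") = iter, Rcpp::Named("status") = status,
        Rcpp::Named("quality") = qBest);
}
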