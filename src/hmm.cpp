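#include <Rcpp.h>
using namespace Rcpp;

// Two-state scaled forward-backward over possibly many chains laid out
// back-to-back.  Step t (0-based, between sites t and t+1) is a chain break
// when tc[t] == 0; there the recursion restarts from pi.
//
// emis:  T x 2 emission probabilities (state U in column 0, M in column 1)
// expd:  length T-1, exp(-d/D) per step (ignored at breaks)
// tc:    length T-1, 1-based transition-context index, 0 = chain break
// A0:    2 x 2 x K zero-distance transition matrices, column-major
//        (A0[(k-1)*4 + i + 2*j] = A0[i,j,k])
// pi:    initial state distribution, length 2
//
// Returns gamma (T x 2, rows sum to 1), xi (T-1 x 4, columns U->U, U->M,
// M->U, M->M; NA rows at chain breaks) and the exact log-likelihood.

static inline void step_matrix(const double *A0k, double e, double A[4]) {
    // A[i + 2*j] = A0[i,j] * e + 0.5 * (1 - e)  (N = 2 states)
    double mix = 0.5 * (1.0 - e);
    A[0] = A0k[0] * e + mix;
    A[1] = A0k[1] * e + mix;
    A[2] = A0k[2] * e + mix;
    A[3] = A0k[3] * e + mix;
}

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix emis, NumericVector expd, IntegerVector tc,
            NumericVector A0, NumericVector pi) {
    const int T = emis.nrow();
    if (T == 0) stop("empty observation sequence");
    if (expd.size() != T - 1 || tc.size() != T - 1)
        stop("step vectors must have length T-1");

    NumericMatrix alpha(T, 2), gamma(T, 2);
    NumericVector scale(T);
    NumericMatrix xi(std::max(T - 1, 0), 4);

    // forward
    double a0 = pi[0] * emis(0, 0), a1 = pi[1] * emis(0, 1);
    scale[0] = a0 + a1;
    if (!(scale[0] > 0) || !R_finite(scale[0]))
        stop("non-finite forward scale at position 1");
    alpha(0, 0) = a0 / scale[0];
    alpha(0, 1) = a1 / scale[0];
    double A[4];
    for (int t = 1; t < T; ++t) {
        if (tc[t - 1] == 0) {           // new chain
            a0 = pi[0] * emis(t, 0);
            a1 = pi[1] * emis(t, 1);
        } else {
            step_matrix(&A0[(tc[t - 1] - 1) * 4], expd[t - 1], A);
            a0 = (alpha(t - 1, 0) * A[0] + alpha(t - 1, 1) * A[1]) * emis(t, 0);
            a1 = (alpha(t - 1, 0) * A[2] + alpha(t - 1, 1) * A[3]) * emis(t, 1);
        }
        scale[t] = a0 + a1;
        if (!(scale[t] > 0) || !R_finite(scale[t]))
            stop("non-finite forward scale at position %d", t + 1);
        alpha(t, 0) = a0 / scale[t];
        alpha(t, 1) = a1 / scale[t];
    }

    // backward (scaled); beta at chain ends is 1
    NumericMatrix beta(T, 2);
    beta(T - 1, 0) = beta(T - 1, 1) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
        if (tc[t] == 0) {               // site t ends its chain
            beta(t, 0) = beta(t, 1) = 1.0;
        } else {
            step_matrix(&A0[(tc[t] - 1) * 4], expd[t], A);
            double e0 = emis(t + 1, 0) * beta(t + 1, 0) / scale[t + 1];
            double e1 = emis(t + 1, 1) * beta(t + 1, 1) / scale[t + 1];
            beta(t, 0) = A[0] * e0 + A[2] * e1;
            beta(t, 1) = A[1] * e0 + A[3] * e1;
        }
    }

    double loglik = 0.0;
    for (int t = 0; t < T; ++t) {
        double g0 = alpha(t, 0) * beta(t, 0), g1 = alpha(t, 1) * beta(t, 1);
        double s = g0 + g1;
        gamma(t, 0) = g0 / s;
        gamma(t, 1) = g1 / s;
        loglik += std::log(scale[t]);
    }

    for (int t = 0; t < T - 1; ++t) {
        if (tc[t] == 0) {
            xi(t, 0) = xi(t, 1) = xi(t, 2) = xi(t, 3) = NA_REAL;
        } else {
            step_matrix(&A0[(tc[t] - 1) * 4], expd[t], A);
            double e0 = emis(t + 1, 0) * beta(t + 1, 0) / scale[t + 1];
            double e1 = emis(t + 1, 1) * beta(t + 1, 1) / scale[t + 1];
            // column order: U->U, U->M, M->U, M->M
            xi(t, 0) = alpha(t, 0) * A[0] * e0;
            xi(t, 1) = alpha(t, 0) * A[2] * e1;
            xi(t, 2) = alpha(t, 1) * A[1] * e0;
            xi(t, 3) = alpha(t, 1) * A[3] * e1;
        }
    }

    return List::create(_["gamma"] = gamma, _["xi"] = xi,
                        _["loglik"] = loglik);
}

// Simulate hidden states along the chain layout above, using R's RNG so that
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".sim_states_cpp")]]
IntegerVector sim_states_cpp(int T, NumericVector expd, IntegerVector tc,
                             NumericVector A0, NumericVector pi) {
    IntegerVector states(T);
    if (T == 0) return states;
    RNGScope rngScope;
    double A[4];
    states[0] = (unif_rand() < pi[0]) ? 1 : 2;
    for (int t = 1; t < T; ++t) {
        if (tc[t - 1] == 0) {
            states[t] = (unif_rand() < pi[0]) ? 1 : 2;
        } else {
            step_matrix(&A0[(tc[t - 1] - 1) * 4], expd[t - 1], A);
            int i = states[t - 1] - 1;
            // row i of A: P(U) = A[i + 0], P(M) = A[i + 2]
            states[t] = (unif_rand() < A[i]) ? 1 : 2;
        }
    }
    return states;
}
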