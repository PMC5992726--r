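# Two-state distance-dependent HMM: primitives and E/M steps ------------

#' Construct and validate HMM parameters
#'
#' The model has two states (U = unmethylated, M = methylated).  Emissions
#' are binomial with context-specific success probabilities `p[i, c]`;
#' transitions between adjacent cytosines at distance d follow
#' `A(d) = A0 * exp(-d/D) + (1/N) * (1 - exp(-d/D))`, with a zero-distance
#' matrix `A0` and decay length `D` per ordered pair of contexts (transition
#' context).
#'
#' @param p 2 x C matrix of binomial success probabilities, rows `U`, `M`,
#'   columns the context levels.
#' @param A0 2 x 2 x C^2 array of zero-distance transition matrices (rows =
#'   from-state, columns = to-state), one per transition context, or a single
#'   2 x 2 matrix recycled over all transition contexts.
#' @param D Decay lengths in bp: scalar or length-C^2 vector.
#' @param pi Initial state distribution, length 2.
#' @param levels Context levels (defaults to the six-context set).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(p, A0, D, pi = c(0.5, 0.5), levels = NULL) {
  if (is.null(levels)) levels <- colnames(p)
  if (is.null(levels)) levels <- CONTEXTS6[seq_len(ncol(p))]
  C <- length(levels)
  p <- matrix(as.numeric(p), nrow = 2, ncol = C,
              dimnames = list(STATES, levels))
  if (any(p < 0 | p > 1)) stop("emission probabilities must be in [0, 1]")
  if (is.matrix(A0)) A0 <- array(A0, dim = c(2, 2, C * C))
  if (!is.array(A0) || !all(dim(A0) == c(2, 2, C * C)))
    stop("A0 must be a 2 x 2 matrix or a 2 x 2 x C^2 array")
  dimnames(A0) <- list(STATES, STATES, tc_names(levels))
  rs <- apply(A0, 3, rowSums)
  if (any(abs(rs - 1) > 1e-12)) stop("A0 rows must sum to 1")
  if (length(D) == 1L) D <- rep(D, C * C)
  if (length(D) != C * C) stop("D must have length 1 or C^2")
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be positive and finite")
  names(D) <- tc_names(levels)
  pi <- as.numeric(pi)
  if (length(pi) != 2L || abs(sum(pi) - 1) > 1e-12)
    stop("pi must be a length-2 distribution")
  names(pi) <- STATES
  structure(list(p = p, A0 = A0, D = D, pi = pi, levels = levels),
            class = "hmm_params")
}

#' Default initial parameters for model fitting
#'
#' p_U = 0.05 and p_M = 0.80 in every context (breaking the label symmetry
#' toward the conventional U/M meaning), diagonally dominant transitions
#' (0.9 persistence) and a uniform initial distribution.
#'
#' @param levels Context levels.
#' @param D Decay lengths (scalar or per transition context); default 30 bp.
#' @return An `hmm_params` object.
#' @export
default_params <- function(levels = CONTEXTS6, D = 30) {
  C <- length(levels)
  p <- rbind(U = rep(0.05, C), M = rep(0.80, C))
  colnames(p) <- levels
  A0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  hmm_params(p, A0, D, pi = c(0.5, 0.5), levels = levels)
}

#' Binomial emission probability
#'
#' `B(m, r, p) = choose(r, m) p^m (1-p)^(r-m)`; by convention the emission
#' is exactly 1 when r = 0 (uncovered sites carry no information, so every
#' state emits them with probability 1), and 0^0 = 1.
#'
#' @param m Methylated count(s).
#' @param r Total count(s).
#' @param p Success probability(ies).
#' @return Numeric vector of probabilities.
#' @examples
#' emission_prob(2, 10, 0.1)
#' emission_prob(0, 0, 0.37)  # uncovered: 1
#' @export
emission_prob <- function(m, r, p) {
  if (any(m < 0 | r < 0 | m > r)) stop("require 0 <= m <= r")
  if (any(p < 0 | p > 1)) stop("require 0 <= p <= 1")
  dbinom(m, r, p)
}

#' Distance-dependent transition matrix
#'
#' `A(d) = A0 * exp(-d/D) + (1/N) * (1 - exp(-d/D))`: at d = 0 the matrix is
#' `A0` itself; as d grows all transitions converge to the uniform 1/N, so
#' cytosines far apart become independent a priori.
#'
#' @param A0 Row-stochastic N x N zero-distance matrix.
#' @param d Distance in bp (>= 0).
#' @param D Decay length in bp (> 0).
#' @return The N x N transition matrix at distance `d`.
#' @examples
#' A0 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' transition_matrix(A0, d = 0, D = 30)    # A0 exactly
#' transition_matrix(A0, d = 3e10, D = 30) # ~uniform 1/2
#' @export
transition_matrix <- function(A0, d, D) {
  if (D <= 0) stop("D must be > 0")
  if (d < 0) stop("d must be >= 0")
  N <- nrow(A0)
  e <- exp(-d / D)
  A0 * e + (1 / N) * (1 - e)
}

# internal: chain layout for a methylome restricted to valid contexts.
# Returns indices of valid rows plus per-step exp(-d/D) and transition
# context (0 at chromosome breaks).
chain_layout <- function(methylome, params) {
  valid <- which(methylome$context_valid)
  if (length(valid) == 0L)
    stop("no cytosines with a valid context: cannot build the model")
  v <- methylome[valid, , drop = FALSE]
  C <- length(params$levels)
  Tn <- nrow(v)
  ci <- as.integer(factor(as.character(v$context), levels = params$levels))
  if (anyNA(ci))
    stop("methylome contexts do not match the parameter context levels")
  if (Tn == 1L) {
    return(list(valid = valid, ci = ci, expd = numeric(0), tc = integer(0)))
  }
  brk <- v$chrom[-Tn] != v$chrom[-1]
  d <- as.numeric(v$position[-1] - v$position[-Tn])
  tc <- ifelse(brk, 0L, tc_index(ci[-Tn], ci[-1], C))
  expd <- ifelse(brk, 0, exp(-d / params$D[pmax(tc, 1L)]))
  list(valid = valid, ci = ci, expd = expd, tc = as.integer(tc))
}

# internal: T x 2 emission matrix for valid sites
emission_matrix <- function(m, r, ci, p) {
  cbind(U = dbinom(m, r, p[1L, ci]), M = dbinom(m, r, p[2L, ci]))
}

#' Forward-backward pass (E-step)
#'
#' Scaled forward-backward recursion over the methylome, treating each
#' chromosome as an independent chain started from `pi`.  Sites with
#' `context_valid = FALSE` are excluded.  Returns exact posteriors, pairwise
#' posteriors and the data log-likelihood.
#'
#' @param methylome Methylome `data.frame`.
#' @param params An `hmm_params` object.
#' @return List with `gamma` (T x 2, rows sum to 1), `xi` (T-1 x 4 with
#'   columns `U->U`, `U->M`, `M->U`, `M->M`; `NA` rows at chromosome
#'   breaks), `loglik`, and the `layout` used (internal bookkeeping).
#' @export
forward_backward <- function(methylome, params) {
  check_methylome(methylome)
  lay <- chain_layout(methylome, params)
  v <- methylome[lay$valid, , drop = FALSE]
  emis <- emission_matrix(v$methylated, v$total, lay$ci, params$p)
  res <- .fb_cpp(emis, lay$expd, lay$tc, as.numeric(params$A0), params$pi)
  colnames(res$gamma) <- STATES
  colnames(res$xi) <- c("U->U", "U->M", "M->U", "M->M")
  res$layout <- lay
  res
}

#' Transition M-step update (Lagrange-constrained)
#'
#' Updates each zero-distance matrix A0 from the pairwise posteriors.  Each
#' step contributes `xi_ij * (A0_ij / A_ij(d)) * exp(-d/D)` to its transition
#' context (the exp factor is the derivative of the distance kernel with
#' respect to A0), and rows are renormalized, which is the stationarity
#' condition of the expected complete-data log-likelihood under the
#' row-stochasticity constraint.  At d = 0 this reduces to the classical
#' Baum-Welch update.  Transition contexts with zero total weight keep their
#' previous matrix.
#'
#' @param xi Pairwise posteriors from [forward_backward()].
#' @param layout The `layout` element returned by [forward_backward()].
#' @param params Current `hmm_params`.
#' @return Updated 2 x 2 x C^2 array `A0`.
#' @export
update_transitions <- function(xi, layout, params) {
  C <- length(params$levels)
  K <- C * C
  A0 <- params$A0
  steps <- which(layout$tc > 0L)
  if (length(steps) == 0L) return(A0)
  tc <- layout$tc[steps]
  e <- layout$expd[steps]
  num <- matrix(0, nrow = K, ncol = 4)
  # xi columns U->U, U->M, M->U, M->M map to A0 entries [1,1],[1,2],[2,1],[2,2]
  a0flat <- matrix(as.numeric(A0), nrow = 4)        # rows: [1,1],[2,1],[1,2],[2,2]
  colmap <- c(1L, 3L, 2L, 4L)                       # xi col -> a0flat row
  for (j in 1:4) {
    a0_ij <- a0flat[colmap[j], tc]
    A_ij <- a0_ij * e + 0.5 * (1 - e)
    w <- xi[steps, j] * (a0_ij / A_ij) * e
    s <- rowsum(w, group = tc)            # rows sorted by transition context
    num[as.integer(rownames(s)), j] <- s[, 1]
  }
  new_A0 <- A0
  for (k in seq_len(K)) {
    rowU <- num[k, c(1, 2)]
    rowM <- num[k, c(3, 4)]
    if (sum(rowU) > 0) new_A0[1, , k] <- rowU / sum(rowU)
    if (sum(rowM) > 0) new_A0[2, , k] <- rowM / sum(rowM)
  }
  new_A0
}

#' Emission M-step update
#'
#' `p'_ic = sum_t [c_t = c] gamma_it m_t / sum_t [c_t = c] gamma_it r_t`:
#' the posterior-weighted pooled methylated fraction per state and context.
#' Zero-coverage sites contribute nothing; contexts with a zero denominator
#' keep their previous value.
#'
#' @param gamma Posteriors from [forward_backward()].
#' @param layout The `layout` element returned by [forward_backward()].
#' @param methylome Methylome `data.frame`.
#' @param params Current `hmm_params`.
#' @return Updated 2 x C matrix `p`.
#' @export
update_emissions <- function(gamma, layout, methylome, params) {
  v <- methylome[layout$valid, , drop = FALSE]
  C <- length(params$levels)
  p_new <- params$p
  ci <- layout$ci
  for (i in 1:2) {
    num <- rowsum(gamma[, i] * v$methylated, group = ci, reorder = FALSE)
    den <- rowsum(gamma[, i] * v$total, group = ci, reorder = FALSE)
    grp <- as.integer(rownames(num))
    ok <- den[, 1] > 0
    p_new[i, grp[ok]] <- num[ok, 1] / den[ok, 1]
  }
  # keep strictly inside (0,1) so emissions stay positive
  pmin(pmax(p_new, 1e-12), 1 - 1e-12)
}
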