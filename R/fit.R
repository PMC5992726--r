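# Model fitting: modified Baum-Welch ------------------------------------

#' Fit the distance-aware methylation HMM
#'
#' Fits the two-state (unmethylated/methylated) hidden Markov model with
#' context-specific binomial emissions and distance-dependent transitions to
#' a per-cytosine methylome by a modified Baum-Welch algorithm.  The decay
#' lengths D are estimated beforehand from the correlation between adjacent
#' cytosines (or supplied) and held fixed during EM; the zero-distance
#' transition matrices, emission probabilities and initial distribution are
#' re-estimated each iteration.  Every cytosine with a valid context --
#' including uncovered ones -- receives a posterior, a status call
#' (posterior argmax, ties resolved to U) and a recalibrated methylation
#' level `p_U[c] * gamma_U + p_M[c] * gamma_M`.
#'
#' After convergence the state labels are swapped if necessary so that the
#' low-emission state is U (`mean(p_U) <= mean(p_M)`), and the bisulfite
#' conversion rate is reported as `1 - p_U` in context CG (with `1 - p_M` as
#' an upward-biased bound on the methylated-cytosine conversion rate).
#'
#' @param methylome Methylome `data.frame` (see [merge_counts()] or
#'   [simulate_methylome()]).
#' @param decay A `decay_fit` object from [estimate_decay()], a numeric
#'   decay length (scalar or per transition context), or `NULL` to estimate
#'   from `methylome`.
#' @param init Initial `hmm_params`, or `NULL` for [default_params()].
#' @param tol Absolute log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param verbose Print per-iteration log-likelihoods.
#' @return An object of class `methylHMM` with elements `params`
#'   (`hmm_params`), `gamma` (T x 2 posteriors, `NA` rows for invalid
#'   contexts), `status` (factor U/M), `rc_level`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `conversion_rates`, `decay`, `data` and `call`.
#' @seealso [predict.methylHMM()], [summary.methylHMM()],
#'   [simulate.methylHMM()], [conversion_rates()]
#' @examples
#' sim <- simulate_methylome(n = 2000, lambda = 6, seed = 1)
#' fit <- methylHMM(sim$methylome, decay = 30, max_iter = 50)
#' fit
#' @export
methylHMM <- function(methylome, decay = NULL, init = NULL, tol = 1e-4,
                      max_iter = 500L, verbose = FALSE) {
  cl <- match.call()
  check_methylome(methylome)
  lv <- levels(methylome$context)
  if (is.null(lv)) stop("methylome$context must be a factor")

  if (is.null(init)) {
    if (is.null(decay)) decay <- estimate_decay(methylome)
    D <- if (inherits(decay, "decay_fit")) decay$D else decay
    params <- default_params(levels = lv, D = D)
  } else {
    if (!inherits(init, "hmm_params")) stop("init must be an hmm_params object")
    params <- init
    if (!is.null(decay)) {      # an explicit decay overrides the init's D
      D <- if (inherits(decay, "decay_fit")) decay$D else decay
      params <- hmm_params(params$p, params$A0, D, params$pi, levels = lv)
    }
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(methylome, params)
    ll <- fb$loglik
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", iter)
    trace <- c(trace, ll)
    if (verbose)
      message(sprintf("iter %3d  loglik %.6f", iter, ll))
    if (iter > 1L) {
      if (ll < ll_old - 1e-8)
        stop(sprintf(
          "log-likelihood decreased by %.3g at iteration %d (numerical failure)",
          ll_old - ll, iter))
      if (abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
    }
    ll_old <- ll
    # M-step
    lay <- fb$layout
    A0_new <- update_transitions(fb$xi, lay, params)
    p_new <- update_emissions(fb$gamma, lay, methylome, params)
    starts <- c(1L, which(lay$tc == 0L) + 1L)
    pi_new <- colSums(fb$gamma[starts, , drop = FALSE])
    pi_new <- pi_new / sum(pi_new)
    params <- hmm_params(p_new, A0_new, params$D, pi_new, levels = lv)
  }

  if (!converged) {
    # max_iter ended on an M-step: realign posteriors with the final params
    fb <- forward_backward(methylome, params)
    trace <- c(trace, fb$loglik)
  }

  # label convention: U is the low-emission state
  if (mean(params$p[1, ]) > mean(params$p[2, ])) {
    params <- hmm_params(params$p[2:1, , drop = FALSE],
                         params$A0[2:1, 2:1, , drop = FALSE],
                         params$D, params$pi[2:1], levels = lv)
    fb <- forward_backward(methylome, params)
  }

  Tn <- nrow(methylome)
  gamma <- matrix(NA_real_, Tn, 2, dimnames = list(NULL, STATES))
  gamma[fb$layout$valid, ] <- fb$gamma
  status <- factor(rep(NA_character_, Tn), levels = STATES)
  status[fb$layout$valid] <- STATES[(fb$gamma[, 2] > fb$gamma[, 1]) + 1L]
  rc <- rep(NA_real_, Tn)
  rc[fb$layout$valid] <-
    recalibrated_levels(fb$gamma, params,
                        methylome$context[fb$layout$valid])

  structure(list(
    params = params,
    gamma = gamma,
    status = status,
    rc_level = rc,
    loglik = trace[length(trace)],
    loglik_trace = trace,
    n_iter = length(trace),
    converged = converged,
    conversion_rates = conversion_rates(params),
    decay = if (inherits(decay, "decay_fit")) decay else NULL,
    data = methylome,
    call = cl
  ), class = "methylHMM")
}

#' Recalibrated methylation levels
#'
#' The posterior-weighted mixture of the two states' binomial success
#' probabilities, `m' = p_U[c] * gamma_U + p_M[c] * gamma_M`.  Defined for
#' every cytosine, including uncovered ones, and always bounded by
#' `[p_U[c], p_M[c]]`.
#'
#' @param gamma T x 2 posterior matrix (rows sum to 1).
#' @param params An `hmm_params` object.
#' @param contexts Per-site context factor (length T).
#' @return Numeric vector of recalibrated levels.
#' @export
recalibrated_levels <- function(gamma, params, contexts) {
  ci <- as.integer(factor(as.character(contexts), levels = params$levels))
  unname(params$p[1L, ci] * gamma[, 1L] + params$p[2L, ci] * gamma[, 2L])
}

#' Bisulfite conversion rates implied by the fitted emissions
#'
#' `1 - p_U` in context CG is the conversion rate: the probability that a
#' truly unmethylated cytosine is read as unmethylated.  `1 - p_M` in CG
#' bounds the inappropriate conversion rate of methylated cytosines from
#' above (it is confounded with cellular heterogeneity, hence biased
#' upward).  CG is used to avoid the fuzzier non-CG contexts.
#'
#' @param params A fitted `hmm_params` object.
#' @return Named numeric vector `c(unmethylated = 1 - p_U_CG,
#'   methylated_upper_bound = 1 - p_M_CG)`.
#' @export
conversion_rates <- function(params) {
  if (inherits(params, "methylHMM")) params <- params$params
  cg <- match("CG", params$levels)
  c(unmethylated = 1 - params$p[1L, cg],
    methylated_upper_bound = 1 - params$p[2L, cg])
}
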