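# Synthetic methylome generator -----------------------------------------
#
# Implements the model's own generative process: hidden U/M states from the
# distance-dependent Markov chain, binomial read counts with conversion-
# failure noise, and a coverage distribution with zero- and low-coverage
# mass, so that fitting, imputation and the evaluation suite are testable
# without external data.

#' Default ground-truth parameters for simulation
#'
#' Conversion failure of 1% (p_U = 0.01, i.e. a conversion rate of 0.99,
#' typical of published experiments), context-ordered p_M decreasing from
#' 0.80 (CG) to 0.30 (pooled CHH), persistent states (A0 diagonal 0.9) and a
#' 30 bp decay length.  These are synthetic defaults chosen to resemble a
#' plant methylome regime, not values fitted to any dataset.
#'
#' @param levels Context levels.
#' @param D Decay length(s) in bp; default 30.
#' @return An `hmm_params` object.
#' @export
truth_params <- function(levels = CONTEXTS6, D = 30) {
  p_M6 <- c(CG = 0.80, CCG = 0.60, CWG = 0.55, CAA = 0.45, CTA = 0.40,
            CHH_rest = 0.30)
  p_M3 <- c(CG = 0.80, CHG = 0.55, CHH = 0.30)
  p_M <- if (identical(levels, CONTEXTS3)) p_M3 else
    p_M6[seq_along(levels)]
  p <- rbind(U = rep(0.01, length(levels)), M = unname(p_M))
  colnames(p) <- levels
  A0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  hmm_params(p, A0, D, pi = c(0.5, 0.5), levels = levels)
}

#' Simulate cytosine sites
#'
#' Positions follow geometric inter-cytosine gaps (mean `mean_gap` bp, the
#' density of a cytosine-rich plant genome); contexts are drawn i.i.d. from
#' `context_weights`.  The default weights are the composition of a
#' uniform-random genome (e.g. a quarter of cytosines are CG).
#'
#' @param n Number of sites.
#' @param context_weights Probability weights over the context levels
#'   (named or in level order); must sum to 1.
#' @param mean_gap Mean inter-cytosine distance in bp (>= 1); default 5.
#' @param seed Optional seed passed to [set.seed()].
#' @param chrom Chromosome name.
#' @param levels Context levels.
#' @return A site `data.frame` (chrom, position, strand, context,
#'   context_valid).
#' @export
simulate_sites <- function(n, context_weights = NULL, mean_gap = 5,
                           seed = NULL, chrom = "chr1", levels = CONTEXTS6) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(context_weights)) {
    context_weights <- if (identical(levels, CONTEXTS6))
      c(CG = 4, CCG = 1, CWG = 2, CAA = 1, CTA = 1, CHH_rest = 7) / 16
    else c(CG = 4, CHG = 3, CHH = 9) / 16
  }
  if (abs(sum(context_weights) - 1) > 1e-8)
    stop("context_weights must sum to 1")
  if (n == 0L)
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(),
                      context = factor(character(), levels = levels),
                      context_valid = logical()))
  gaps <- 1L + rgeom(n, prob = 1 / mean_gap)   # mean 1 + (mean_gap - 1)
  position <- cumsum(gaps)
  context <- factor(sample(levels, n, replace = TRUE,
                           prob = context_weights), levels = levels)
  data.frame(chrom = chrom, position = position, strand = "+",
             context = context, context_valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate hidden methylation states
#'
#' The first site of each chromosome draws from `pi`; each subsequent state
#' draws from the row of the distance-dependent transition matrix
#' `A(d) = A0 exp(-d/D) + (1/N)(1 - exp(-d/D))` for its transition context.
#'
#' @param sites Site `data.frame` (from [simulate_sites()] or
#'   [extract_cytosines()]).
#' @param params Generating `hmm_params`.
#' @param seed Optional seed passed to [set.seed()].
#' @return Factor of states (U/M) per site.
#' @export
simulate_states <- function(sites, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- chain_layout(sites, params)
  st <- .sim_states_cpp(length(lay$valid), lay$expd, lay$tc,
                        as.numeric(params$A0), params$pi)
  out <- factor(rep(NA_character_, nrow(sites)), levels = STATES)
  out[lay$valid] <- STATES[st]
  out
}

#' Simulate read counts given hidden states
#'
#' Coverage is Poisson(`lambda`) per site (including zero-coverage mass)
#' unless an explicit per-site coverage vector or an empirical histogram
#' (table of probabilities named by coverage) is supplied; methylated counts
#' are `Binomial(r, p[state, context])`.
#'
#' @param sites Site `data.frame`.
#' @param states Factor of hidden states per site.
#' @param params Generating `hmm_params`.
#' @param coverage Either a single Poisson mean (default 6), a per-site
#'   integer vector, or a named numeric vector of coverage probabilities.
#' @param seed Optional seed passed to [set.seed()].
#' @return A methylome `data.frame`.
#' @export
simulate_counts <- function(sites, states, params, coverage = 6,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  r <- if (length(coverage) == 1L && is.null(names(coverage))) {
    rpois(n, coverage)
  } else if (!is.null(names(coverage))) {
    sample(as.integer(names(coverage)), n, replace = TRUE, prob = coverage)
  } else {
    as.integer(coverage)
  }
  ci <- as.integer(factor(as.character(sites$context),
                          levels = params$levels))
  si <- as.integer(states)
  p_site <- params$p[cbind(si, ci)]
  m <- integer(n)
  okk <- !is.na(p_site)
  m[okk] <- rbinom(sum(okk), r[okk], p_site[okk])
  out <- sites
  out$methylated <- m
  out$total <- r
  out
}

#' Simulate a complete methylome with known truth
#'
#' Convenience wrapper around [simulate_sites()], [simulate_states()] and
#' [simulate_counts()] drawing everything from one seed.
#'
#' @param n Number of cytosines.
#' @param params Generating `hmm_params`; default [truth_params()].
#' @param lambda Poisson coverage mean (or vector/histogram, see
#'   [simulate_counts()]).
#' @param mean_gap Mean inter-cytosine distance in bp.
#' @param seed Optional seed.
#' @param levels Context levels.
#' @return List of class `methylome_simulation`: `methylome`, `states`
#'   (the hidden truth), `params`, `seed`.
#' @export
simulate_methylome <- function(n = 200000, params = NULL, lambda = 6,
                               mean_gap = 5, seed = NULL,
                               levels = CONTEXTS6) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- truth_params(levels = levels)
  sites <- simulate_sites(n, mean_gap = mean_gap, levels = params$levels)
  states <- simulate_states(sites, params)
  methylome <- simulate_counts(sites, states, params, coverage = lambda)
  structure(list(methylome = methylome, states = states, params = params,
                 seed = seed), class = "methylome_simulation")
}
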