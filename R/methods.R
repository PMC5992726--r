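# S3 methods for fitted methylHMM objects --------------------------------

#' @export
print.methylHMM <- function(x, ...) {
  cat("Distance-aware two-state methylation HMM\n\n")
  cat("Call:  ", deparse(x$call), "\n", sep = "")
  Tn <- nrow(x$data)
  cov <- x$data$total
  cat(sprintf("Sites: %d (%.1f%% uncovered)  contexts: %s\n",
              Tn, 100 * mean(cov == 0),
              paste(x$params$levels, collapse = ", ")))
  cat(sprintf("Log-likelihood: %.3f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  cat("\nEmission probabilities p[state, context]:\n")
  print(round(x$params$p, 4))
  cr <- x$conversion_rates
  cat(sprintf("\nConversion rate (1 - p_U, CG): %.4f\n", cr["unmethylated"]))
  cat(sprintf("Methylated-conversion upper bound (1 - p_M, CG): %.4f\n",
              cr["methylated_upper_bound"]))
  invisible(x)
}

#' Summarize a fitted methylation HMM
#'
#' Reports the fitted parameters, conversion rates, status-call composition
#' and the fraction of high-confidence calls (max posterior above
#' `threshold`) per coverage category (imputed / uninformative /
#' informative).
#'
#' @param object A `methylHMM` fit.
#' @param threshold Posterior confidence threshold (default 0.9).
#' @param ... Unused.
#' @method summary methylHMM
#' @export
summary.methylHMM <- function(object, threshold = 0.9, ...) {
  conf <- confidence_summary(object, object$data, threshold = threshold)
  gml <- gml_from_calls(object$status, object$data$context)
  out <- list(fit = object, confidence = conf, threshold = threshold,
              gml = gml,
              category_counts = table(coverage_category(object$data$total)))
  class(out) <- "summary.methylHMM"
  out
}

#' @export
print.summary.methylHMM <- function(x, ...) {
  print(x$fit)
  cat("\nCoverage categories:\n")
  print(x$category_counts)
  cat(sprintf("\nFraction of calls with max posterior >= %.2f:\n",
              x$threshold))
  print(round(x$confidence$by_category, 4))
  cat("\nGenome-wide methylation level from status calls (per context):\n")
  print(round(x$gml$per_context, 4))
  invisible(x)
}

#' Extract fitted HMM parameters
#'
#' @param object A `methylHMM` fit.
#' @param which One of `"emission"` (the 2 x C matrix `p`), `"transition"`
#'   (the 2 x 2 x C^2 array `A0`), `"decay"` (`D`) or `"initial"` (`pi`).
#' @param ... Unused.
#' @method coef methylHMM
#' @export
coef.methylHMM <- function(object,
                           which = c("emission", "transition", "decay",
                                     "initial"), ...) {
  which <- match.arg(which)
  switch(which,
         emission = object$params$p,
         transition = object$params$A0,
         decay = object$params$D,
         initial = object$params$pi)
}

#' @method logLik methylHMM
#' @export
logLik.methylHMM <- function(object, ...) {
  C <- length(object$params$levels)
  # free parameters: 2C emissions + 2 per A0 row pair per transition context
  # + 1 for pi (D is pre-fitted, not an EM parameter)
  df <- 2 * C + 2 * C * C + 1
  structure(object$loglik, df = df,
            nobs = sum(object$data$context_valid), class = "logLik")
}

#' Posterior decoding for the fitted or new data
#'
#' @param object A `methylHMM` fit.
#' @param newdata Optional methylome to decode with the fitted parameters;
#'   default: the training methylome (fitted values).
#' @param type `"status"` (factor of U/M calls), `"posterior"` (T x 2
#'   matrix) or `"level"` (recalibrated methylation level).
#' @param ... Unused.
#' @method predict methylHMM
#' @export
predict.methylHMM <- function(object, newdata = NULL,
                              type = c("status", "posterior", "level"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type, status = object$status, posterior = object$gamma,
                  level = object$rc_level))
  }
  check_methylome(newdata)
  fb <- forward_backward(newdata, object$params)
  Tn <- nrow(newdata)
  gamma <- matrix(NA_real_, Tn, 2, dimnames = list(NULL, STATES))
  gamma[fb$layout$valid, ] <- fb$gamma
  switch(type,
         posterior = gamma,
         status = {
           st <- factor(rep(NA_character_, Tn), levels = STATES)
           st[fb$layout$valid] <- STATES[(fb$gamma[, 2] > fb$gamma[, 1]) + 1L]
           st
         },
         level = {
           rc <- rep(NA_real_, Tn)
           rc[fb$layout$valid] <- recalibrated_levels(
             fb$gamma, object$params, newdata$context[fb$layout$valid])
           rc
         })
}

#' Residuals of a fitted methylation HMM
#'
#' Response residuals: observed methylation level `m/r` minus the fitted
#' recalibrated level, for covered valid-context sites (`NA` elsewhere).
#'
#' @param object A `methylHMM` fit.
#' @param ... Unused.
#' @method residuals methylHMM
#' @export
residuals.methylHMM <- function(object, ...) {
  obs <- ifelse(object$data$total > 0,
                object$data$methylated / object$data$total, NA_real_)
  obs - object$rc_level
}

#' Simulate methylomes from a fitted model
#'
#' Parametric resampling: keeps the fitted sites (positions, contexts) and
#' observed coverage, redraws hidden states from the fitted distance-
#' dependent Markov chain and counts from the fitted binomial emissions.
#'
#' @param object A `methylHMM` fit.
#' @param nsim Number of methylomes to simulate.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Unused.
#' @return A list of `nsim` methylome `data.frame`s, each with a
#'   `true_state` attribute.
#' @method simulate methylHMM
#' @export
simulate.methylHMM <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sites <- object$data[, c("chrom", "position", "strand", "context",
                           "context_valid")]
  lapply(seq_len(nsim), function(k) {
    states <- simulate_states(sites, object$params)
    sim <- simulate_counts(sites, states, object$params,
                           coverage = object$data$total)
    attr(sim, "true_state") <- states
    sim
  })
}

#' Diagnostic plots for a fitted methylation HMM
#'
#' @param x A `methylHMM` fit.
#' @param type `"trace"` (EM log-likelihood trace), `"emissions"` (fitted
#'   p_U/p_M per context) or `"posterior"` (histogram of max posteriors).
#' @param ... Passed to the underlying plotting functions.
#' @method plot methylHMM
#' @export
plot.methylHMM <- function(x, type = c("trace", "emissions", "posterior"),
                           ...) {
  type <- match.arg(type)
  if (type == "trace") {
    plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
         xlab = "EM iteration", ylab = "log-likelihood", ...)
  } else if (type == "emissions") {
    barplot(x$params$p, beside = TRUE, ylim = c(0, 1),
            legend.text = rownames(x$params$p),
            xlab = "context", ylab = "binomial success probability p", ...)
  } else {
    mp <- apply(x$gamma, 1, max)
    hist(mp[!is.na(mp)], breaks = 40, main = "",
         xlab = "max posterior probability", ...)
  }
  invisible(x)
}
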