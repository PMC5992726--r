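# Correlation decay between adjacent cytosines --------------------------
#
# The distance dependence of the transition probabilities is governed by a
# per-transition-context decay length D (bp), estimated before the EM from
# the correlation of raw methylation levels between adjacent covered
# cytosines, via the exponential model y(d) = a0 * exp(-d / D).

#' Correlation between adjacent cytosines, by transition context and distance
#'
#' Only genuinely adjacent cytosines (no other cytosine in between, within
#' one chromosome) form pairs, matching the transition structure of the HMM.
#' The correlation is the Pearson correlation of the raw methylation levels
#' m/r of pairs whose both members are covered (r >= 1).
#'
#' @param methylome Methylome `data.frame`.
#' @param max_distance Largest pair distance (bp) retained; default 100.
#' @param min_pairs Minimum number of pairs for a (context, distance) row to
#'   be kept; default 100.
#' @return A `data.frame` with columns `from`, `to` (the transition
#'   context), `distance`, `correlation`, `n_pairs`.
#' @export
adjacent_correlations <- function(methylome, max_distance = 100L,
                                  min_pairs = 100L) {
  check_methylome(methylome)
  v <- methylome[methylome$context_valid, , drop = FALSE]
  lv <- levels(v$context)
  n <- nrow(v)
  if (n < 2L)
    return(data.frame(from = character(), to = character(),
                      distance = integer(), correlation = numeric(),
                      n_pairs = integer()))
  same_chrom <- v$chrom[-n] == v$chrom[-1]
  d <- v$position[-1] - v$position[-n]
  lev <- ifelse(v$total > 0, v$methylated / v$total, NA_real_)
  keep <- same_chrom & d >= 1L & d <= max_distance &
    !is.na(lev[-n]) & !is.na(lev[-1])
  i <- which(keep)
  tc <- tc_index(v$context[i], v$context[i + 1L], length(lv))
  grp <- interaction(tc, d[i], drop = TRUE)
  rows <- lapply(split(seq_along(i), grp), function(ix) {
    if (length(ix) < min_pairs) return(NULL)
    x <- lev[i[ix]]
    y <- lev[i[ix] + 1L]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    data.frame(tc = tc[ix[1]], distance = d[i[ix[1]]],
               correlation = cor(x, y), n_pairs = length(ix))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(from = character(), to = character(),
                      distance = integer(), correlation = numeric(),
                      n_pairs = integer()))
  from_i <- (rows$tc - 1L) %/% length(lv) + 1L
  to_i <- (rows$tc - 1L) %% length(lv) + 1L
  out <- data.frame(from = lv[from_i], to = lv[to_i],
                    distance = rows$distance,
                    correlation = rows$correlation, n_pairs = rows$n_pairs,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$from, lv), match(out$to, lv), out$distance), ]
  rownames(out) <- NULL
  out
}

# one nls fit of y = a0 * exp(-d/D); multi-start on D, keep best; returns
# c(a0, D) or NULL on failure
fit_decay_one <- function(d, y, starts = c(5, 30, 100)) {
  best <- NULL
  best_rss <- Inf
  a0_start <- y[which.min(d)]
  for (D0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a0 * exp(-d / D),
                        start = list(a0 = a0_start, D = D0),
                        lower = c(a0 = -1, D = 1), upper = c(a0 = 1, D = 1000),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- coef(fit)
      }
    }
  }
  best
}

#' Fit exponential decay constants to a correlation table
#'
#' Fits `y(d) = a0 * exp(-d/D)` per transition context by nonlinear least
#' squares (Levenberg-Marquardt), with D constrained to \[1, 1000\] bp.
#' Contexts with fewer than 3 distances, or where the optimizer fails,
#' inherit the pooled fit over all contexts (and failing that, the defaults
#' a0 = 0.5, D = 30), with a warning.
#'
#' @param table Correlation table from [adjacent_correlations()].
#' @param levels Context levels; default taken from the table, falling back
#'   to the six-context set.
#' @return An object of class `decay_fit`: list with `a0` and `D` (named
#'   vectors over the C^2 transition contexts) and the input `table`.
#' @export
fit_decay <- function(table, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (nrow(table) > 0 && all(table$from %in% CONTEXTS3))
      CONTEXTS3 else CONTEXTS6
    if (nrow(table) > 0 && !all(table$from %in% levels)) levels <- CONTEXTS6
  }
  C <- length(levels)
  nm <- tc_names(levels)
  a0 <- setNames(rep(NA_real_, C * C), nm)
  D <- setNames(rep(NA_real_, C * C), nm)

  pooled <- NULL
  if (nrow(table) >= 3L) {
    agg <- stats::aggregate(cbind(correlation * n_pairs, n_pairs) ~ distance,
                            data = table, FUN = sum)
    names(agg) <- c("distance", "wsum", "n")
    if (nrow(agg) >= 3L)
      pooled <- fit_decay_one(agg$distance, agg$wsum / agg$n)
  }
  if (is.null(pooled)) pooled <- c(a0 = 0.5, D = 30)

  fallback <- character()
  for (k in seq_len(C * C)) {
    from <- levels[(k - 1L) %/% C + 1L]
    to <- levels[(k - 1L) %% C + 1L]
    sub <- table[table$from == from & table$to == to, , drop = FALSE]
    est <- NULL
    if (nrow(sub) >= 3L)
      est <- fit_decay_one(sub$distance, sub$correlation)
    if (is.null(est)) {
      est <- pooled
      fallback <- c(fallback, nm[k])
    }
    a0[k] <- est[["a0"]]
    D[k] <- min(max(est[["D"]], 1), 1000)
  }
  if (length(fallback) && length(fallback) < C * C)
    warning("decay fit fell back to the pooled estimate for ",
            length(fallback), " transition context(s)")
  structure(list(a0 = a0, D = D, table = table, levels = levels),
            class = "decay_fit")
}

#' Estimate decay constants from a methylome
#'
#' Convenience wrapper: [adjacent_correlations()] followed by [fit_decay()].
#'
#' @inheritParams adjacent_correlations
#' @return A `decay_fit` object.
#' @export
estimate_decay <- function(methylome, max_distance = 100L, min_pairs = 100L) {
  tab <- adjacent_correlations(methylome, max_distance = max_distance,
                               min_pairs = min_pairs)
  fit_decay(tab, levels = levels(methylome$context))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential correlation-decay fit (y = a0 * exp(-d/D))\n")
  cat(sprintf("  %d transition contexts; D range %.1f-%.1f bp (median %.1f)\n",
              length(x$D), min(x$D), max(x$D), stats::median(x$D)))
  invisible(x)
}
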