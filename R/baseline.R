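# Binomial-test baseline caller with neighbourhood imputation -----------

#' Binomial-test methylation calls for informative sites
#'
#' One-sided exact binomial test of H0: the methylated fraction equals the
#' sequencing/conversion error rate, against greater.  Sites are called M
#' when the (optionally Benjamini-Hochberg-adjusted) p-value falls below
#' `alpha`, U otherwise.  Only informative sites (r >= 3) may be tested;
#' lower-coverage sites must be routed to [neighborhood_impute()].
#'
#' @param m,r Methylated and total counts (r >= 3 for every element).
#' @param error_rate Null methylated fraction; default 0.01 (1 minus a
#'   typical conversion rate of 0.99).
#' @param alpha Significance level; default 0.05.
#' @param fdr Apply Benjamini-Hochberg correction across the supplied sites
#'   (default `TRUE`).
#' @return List with `status` (factor U/M) and `p_value` (the unadjusted
#'   exact tail probability `P(X >= m)` under `Binomial(r, error_rate)`).
#' @export
binomial_test_call <- function(m, r, error_rate = 0.01, alpha = 0.05,
                               fdr = TRUE) {
  if (any(r < 3L)) stop("binomial test requires r >= 3 (informative sites)")
  if (error_rate <= 0 || error_rate >= 1) stop("error_rate must be in (0, 1)")
  pval <- pbinom(m - 1L, r, error_rate, lower.tail = FALSE)
  padj <- if (fdr) p.adjust(pval, method = "BH") else pval
  status <- factor(ifelse(padj < alpha, "M", "U"), levels = STATES)
  list(status = status, p_value = pval)
}

#' Majority-vote imputation of low-coverage sites
#'
#' Each site with fewer than 3 reads receives the majority methylation
#' status of the directly-called sites of the same sequence context within a
#' `window` bp neighbourhood centred on it (i.e. within +/- `window`/2 bp).
#' Sites with no qualifying neighbour, or with a tied vote, stay
#' `undefined`.
#'
#' @param methylome Methylome `data.frame`.
#' @param direct_status Factor of U/M calls, `NA` for untested sites,
#'   aligned with `methylome` (from [binomial_test_call()] on the r >= 3
#'   subset).
#' @param window Neighbourhood width in bp (default 200).
#' @return Factor with levels U/M/undefined for every site.
#' @export
neighborhood_impute <- function(methylome, direct_status, window = 200) {
  half <- window / 2
  Tn <- nrow(methylome)
  status <- factor(rep("undefined", Tn), levels = c(STATES, "undefined"))
  called <- !is.na(direct_status)
  status[called] <- as.character(direct_status[called])
  todo <- which(!called)
  if (length(todo) == 0L) return(status)
  for (ch in unique(methylome$chrom[todo])) {
    in_ch <- methylome$chrom == ch
    for (ctx in unique(as.character(methylome$context[todo[
      methylome$chrom[todo] == ch]]))) {
      if (is.na(ctx)) next
      ref <- which(in_ch & called &
                     as.character(methylome$context) %in% ctx)
      tgt <- todo[methylome$chrom[todo] == ch &
                    as.character(methylome$context[todo]) %in% ctx]
      if (length(tgt) == 0L) next
      if (length(ref) == 0L) next
      rp <- methylome$position[ref]
      cumM <- cumsum(direct_status[ref] == "M")
      tp <- methylome$position[tgt]
      lo <- findInterval(tp - half - 0.5, rp)   # count of ref < tp - half
      hi <- findInterval(tp + half + 0.5, rp)   # count of ref <= tp + half
      nM <- ifelse(hi >= 1L, cumM[pmax(hi, 1L)], 0L) -
        ifelse(lo >= 1L, cumM[pmax(lo, 1L)], 0L)
      nTot <- hi - lo
      call <- ifelse(nTot == 0L, "undefined",
                     ifelse(nM > nTot - nM, "M",
                            ifelse(nM < nTot - nM, "U", "undefined")))
      status[tgt] <- call
    }
  }
  status
}

#' Baseline methylation calls: binomial test plus neighbourhood vote
#'
#' The comparison method used in the saturation analysis: informative sites
#' (r >= 3) are called by an exact binomial test against the error rate;
#' uninformative and uncovered sites get the majority status of same-context
#' informative neighbours within the window, or `undefined`.
#'
#' @inheritParams binomial_test_call
#' @inheritParams neighborhood_impute
#' @return List with `status` (factor U/M/undefined per site), `p_value`
#'   (`NA` for untested sites) and `direct` (logical: directly tested).
#' @export
baseline_calls <- function(methylome, error_rate = 0.01, alpha = 0.05,
                           fdr = TRUE, window = 200) {
  check_methylome(methylome)
  Tn <- nrow(methylome)
  direct <- methylome$total >= 3L & methylome$context_valid
  pval <- rep(NA_real_, Tn)
  direct_status <- factor(rep(NA_character_, Tn), levels = STATES)
  if (any(direct)) {
    bt <- binomial_test_call(methylome$methylated[direct],
                             methylome$total[direct],
                             error_rate = error_rate, alpha = alpha,
                             fdr = fdr)
    pval[direct] <- bt$p_value
    direct_status[direct] <- bt$status
  }
  status <- neighborhood_impute(methylome, direct_status, window = window)
  list(status = status, p_value = pval, direct = direct)
}
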