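# Saturation analysis, genome-wide summaries, enrichment profiles -------

#' Coverage categories
#'
#' Imputed (r = 0), uninformative (r = 1 or 2) and informative (r >= 3)
#' cytosines.
#'
#' @param total Total read counts.
#' @return Factor with levels `imputed`, `uninformative`, `informative`.
#' @export
coverage_category <- function(total) {
  cut(total, breaks = c(-Inf, 0.5, 2.5, Inf),
      labels = c("imputed", "uninformative", "informative"))
}

#' Downsample a methylome by read-level thinning
#'
#' Each site's methylated and unmethylated reads are independently thinned
#' with `Binomial(., fraction)`, which matches Bernoulli sampling of
#' individual reads in distribution.  Positions and contexts are unchanged.
#'
#' @param methylome Methylome `data.frame`.
#' @param fraction Retention fraction in \[0, 1\].
#' @param seed Optional seed passed to [set.seed()].
#' @return The thinned methylome.
#' @export
downsample <- function(methylome, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- methylome
  m <- rbinom(nrow(methylome), methylome$methylated, fraction)
  u <- rbinom(nrow(methylome), methylome$total - methylome$methylated,
              fraction)
  out$methylated <- m
  out$total <- m + u
  out
}

#' Precision, recall and F1 against ground-truth calls
#'
#' Per-state precision, recall and F1, plus an overall F1 weighted by the
#' truth-state frequencies.  `undefined` (or `NA`) predictions count as
#' false negatives for the truth state, never as positives.
#'
#' @param calls Factor of predicted statuses (levels may include
#'   `undefined`).
#' @param truth Factor of ground-truth statuses (U/M, no undefined).
#' @return List with `per_state` (data.frame: state, precision, recall, F1,
#'   n_truth, degenerate flag) and `overall` (weighted mean F1).
#' @export
f1_scores <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth must have equal length")
  calls <- as.character(calls)
  truth <- as.character(truth)
  keep <- !is.na(truth)
  calls <- calls[keep]
  truth <- truth[keep]
  rows <- lapply(STATES, function(s) {
    tp <- sum(calls == s & truth == s, na.rm = TRUE)
    fp <- sum(calls == s & truth != s, na.rm = TRUE)
    fn <- sum(truth == s) - tp
    degenerate <- (tp + fp) == 0 || (tp + fn) == 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(state = s, precision = prec, recall = rec, F1 = f1,
               n_truth = sum(truth == s), degenerate = degenerate)
  })
  per_state <- do.call(rbind, rows)
  w <- per_state$n_truth / sum(per_state$n_truth)
  list(per_state = per_state, overall = sum(w * per_state$F1))
}

#' Genome-wide methylation level from status calls
#'
#' The fraction of cytosines called methylated (#mC / all C), per context
#' and overall.  Sites with undefined or missing status are excluded from
#' both numerator and denominator; their count is reported.
#'
#' @param status Factor of status calls.
#' @param contexts Context factor aligned with `status`.
#' @return List with `per_context`, `overall` and `n_undefined`.
#' @export
gml_from_calls <- function(status, contexts) {
  st <- as.character(status)
  def <- !is.na(st) & st %in% STATES
  isM <- st == "M" & def
  per <- tapply(isM[def], droplevels(factor(contexts[def])), mean)
  list(per_context = per, overall = mean(isM[def]),
       n_undefined = sum(!def))
}

#' Weighted genome-wide methylation level
#'
#' Total methylated reads over total reads (per context and overall);
#' uncovered sites contribute nothing.  Contexts without any reads get `NA`
#' and are flagged.
#'
#' @param methylome Methylome `data.frame`.
#' @return List with `per_context`, `overall` and `undefined_contexts`.
#' @export
weighted_gml <- function(methylome) {
  ctx <- methylome$context
  if (!is.factor(ctx)) ctx <- factor(ctx)
  msum <- tapply(methylome$methylated, ctx, sum)
  rsum <- tapply(methylome$total, ctx, sum)
  per <- ifelse(rsum > 0, msum / rsum, NA_real_)
  names(per) <- names(rsum)
  overall <- if (sum(methylome$total) > 0)
    sum(methylome$methylated) / sum(methylome$total) else NA_real_
  list(per_context = per, overall = overall,
       undefined_contexts = names(per)[is.na(per)])
}

#' Coverage-weighted recalibrated genome-wide methylation level
#'
#' Sum of per-cytosine recalibrated levels weighted by coverage,
#' `sum(m' * r) / sum(r)`, per context and overall.
#'
#' @param fit A `methylHMM` fit.
#' @param methylome Methylome the fit is aligned with (default: the
#'   training data).
#' @return List with `per_context`, `overall` and `undefined_contexts`.
#' @export
recalibrated_wgml <- function(fit, methylome = fit$data) {
  if (length(fit$rc_level) != nrow(methylome))
    stop("fit and methylome are not aligned")
  ok <- !is.na(fit$rc_level)
  ctx <- factor(methylome$context[ok])
  num <- tapply(fit$rc_level[ok] * methylome$total[ok], ctx, sum)
  den <- tapply(methylome$total[ok], ctx, sum)
  per <- ifelse(den > 0, num / den, NA_real_)
  names(per) <- names(den)
  overall <- if (sum(den) > 0) sum(num) / sum(den) else NA_real_
  list(per_context = per, overall = overall,
       undefined_contexts = names(per)[is.na(per)])
}

#' High-confidence call fractions by coverage category
#'
#' Fraction of sites whose maximum posterior reaches `threshold`, split by
#' coverage category (imputed / uninformative / informative) and, in
#' `by_category_context`, additionally by sequence context.
#'
#' @param fit A `methylHMM` fit.
#' @param methylome Methylome the fit is aligned with.
#' @param threshold Posterior threshold in (0.5, 1\]; default 0.9.
#' @return List with `by_category` and `by_category_context`.
#' @export
confidence_summary <- function(fit, methylome = fit$data, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  mp <- pmax(fit$gamma[, 1], fit$gamma[, 2])
  ok <- !is.na(mp)
  cat_ <- coverage_category(methylome$total)
  hi <- mp >= threshold
  by_cat <- c(tapply(hi[ok], cat_[ok], mean))
  by_cc <- tapply(hi[ok],
                  list(cat_[ok], droplevels(factor(methylome$context[ok]))),
                  mean)
  list(by_category = by_cat, by_category_context = by_cc)
}

#' Meta-feature enrichment profile of recalibrated levels
#'
#' Average recalibrated methylation level across scaled feature bodies and
#' fixed-width flanks, per sequence context and coverage category.  Feature
#' bodies are divided into `body_bins` equal fractions; each flank into
#' `flank_bins` bins of `flank_bp / flank_bins` bp.  Minus-strand features
#' are flipped so the profile always runs 5' to 3'.  Sites inside
#' overlapping features are counted once per feature occurrence; empty bins
#' are absent from the output.
#'
#' @param fit A `methylHMM` fit.
#' @param methylome Methylome the fit is aligned with.
#' @param features Annotation `data.frame` from [read_annotation()].
#' @param body_bins Number of body bins (default 20).
#' @param flank_bp Flank width in bp (default 1000).
#' @param flank_bins Number of bins per flank (default 10).
#' @return A `data.frame`: `context`, `category`, `bin` (1-based, upstream
#'   flank first), `region`, `mean_rc_level`, `n_sites`.
#' @export
enrichment_profile <- function(fit, methylome = fit$data, features,
                               body_bins = 20L, flank_bp = 1000L,
                               flank_bins = 10L) {
  ok <- !is.na(fit$rc_level)
  pos <- methylome$position
  cat_ <- coverage_category(methylome$total)
  ctx <- as.character(methylome$context)
  acc <- list()
  for (f in seq_len(nrow(features))) {
    fs <- features$start[f]
    fe <- features$end[f]
    fchrom <- features$chrom[f]
    minus <- identical(features$strand[f], "-")
    in_ch <- which(methylome$chrom == fchrom & ok &
                     pos >= fs - flank_bp & pos <= fe + flank_bp)
    if (length(in_ch) == 0L) next
    p <- pos[in_ch]
    bin <- integer(length(p))
    width <- fe - fs + 1
    up <- p < fs       # 5' flank on + orientation
    dn <- p > fe
    body <- !up & !dn
    bin[up] <- pmin(flank_bins,
                    flank_bins - floor((fs - p[up] - 1) / (flank_bp / flank_bins)))
    bin[body] <- flank_bins +
      pmin(body_bins, floor((p[body] - fs) / width * body_bins) + 1L)
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins, floor((p[dn] - fe - 1) / (flank_bp / flank_bins)) + 1L)
    if (minus) bin <- 2L * flank_bins + body_bins + 1L - bin
    acc[[length(acc) + 1L]] <- data.frame(
      context = ctx[in_ch], category = as.character(cat_[in_ch]), bin = bin,
      rc = fit$rc_level[in_ch], stringsAsFactors = FALSE)
  }
  if (length(acc) == 0L)
    return(data.frame(context = character(), category = character(),
                      bin = integer(), region = character(),
                      mean_rc_level = numeric(), n_sites = integer()))
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(rc ~ context + category + bin, data = all,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(context = agg$context, category = agg$category,
                    bin = agg$bin,
                    region = ifelse(agg$bin <= flank_bins, "upstream",
                                    ifelse(agg$bin <= flank_bins + body_bins,
                                           "body", "downstream")),
                    mean_rc_level = agg$rc[, 1], n_sites = agg$rc[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$context, out$category, out$bin), ]
  rownames(out) <- NULL
  out
}

#' Saturation analysis: downsampling and F1 against full-data calls
#'
#' Thins the methylome to each retention fraction, refits the HMM (reusing
#' the full-data decay constants) and recomputes the baseline calls, then
#' scores both against the full-data calls of the same method (taken as
#' ground truth, as in a saturation experiment).  Undefined baseline calls
#' count as false negatives.
#'
#' @param methylome Deeply covered methylome `data.frame`.
#' @param fractions Retention fractions; default `c(0.9, 0.5, 0.25, 0.1)`.
#' @param seed Optional seed for the thinning.
#' @param error_rate,alpha,fdr,window Baseline parameters, see
#'   [baseline_calls()].
#' @param ... Passed to [methylHMM()] (e.g. `tol`, `max_iter`).
#' @return List with `table` (data.frame: fraction, method, F1_U, F1_M,
#'   overall_F1), `full_fit` and `full_baseline`.
#' @export
saturation_analysis <- function(methylome, fractions = c(0.9, 0.5, 0.25, 0.1),
                                seed = NULL, error_rate = 0.01, alpha = 0.05,
                                fdr = TRUE, window = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  decay <- estimate_decay(methylome)
  full_fit <- methylHMM(methylome, decay = decay, ...)
  truth_hmm <- full_fit$status
  full_base <- baseline_calls(methylome, error_rate = error_rate,
                              alpha = alpha, fdr = fdr, window = window)
  truth_base <- full_base$status
  truth_base[truth_base == "undefined"] <- NA
  rows <- list()
  for (fr in fractions) {
    ds <- downsample(methylome, fr)
    fit <- methylHMM(ds, decay = decay, ...)
    f_hmm <- f1_scores(fit$status, truth_hmm)
    base <- baseline_calls(ds, error_rate = error_rate, alpha = alpha,
                           fdr = fdr, window = window)
    f_base <- f1_scores(base$status, truth_base)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = fr, method = c("hmm", "baseline"),
      F1_U = c(f_hmm$per_state$F1[1], f_base$per_state$F1[1]),
      F1_M = c(f_hmm$per_state$F1[2], f_base$per_state$F1[2]),
      overall_F1 = c(f_hmm$overall, f_base$overall))
  }
  list(table = do.call(rbind, rows), full_fit = full_fit,
       full_baseline = full_base)
}
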