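# Downsampling, F1 scoring, methylation summaries, enrichment profiles

test_that("downsampling thins counts binomially and respects the bounds", {
  sim <- simulate_methylome(n = 2000, lambda = 10, seed = 21)
  expect_identical(downsample(sim$methylome, 1),
                   sim$methylome)
  ds0 <- downsample(sim$methylome, 0)
  expect_true(all(ds0$total == 0) && all(ds0$methylated == 0))
  expect_error(downsample(sim$methylome, 1.2), "fraction")

  # heavy methylome: kept total within 3 sigma of fraction * reads
  set.seed(22)
  big <- sim$methylome
  big$total <- big$total + 500L   # ~10^6 reads overall
  big$methylated <- pmin(big$methylated, big$total)
  ds <- downsample(big, 0.5, seed = 23)
  n_reads <- sum(big$total)
  expect_lt(abs(sum(ds$total) - 0.5 * n_reads),
            3 * sqrt(n_reads * 0.25))
  expect_true(all(ds$methylated <= ds$total))
  expect_identical(ds$position, big$position)
})

test_that("F1 arithmetic follows the definitions", {
  truth <- factor(rep(c("M", "U"), each = 10), levels = c("U", "M"))
  calls <- truth
  f <- f1_scores(calls, truth)
  expect_equal(f$per_state$F1, c(1, 1))
  expect_equal(f$overall, 1)

  # constructed confusion: for M, TP=8 FP=2 FN=2
  calls2 <- as.character(truth)
  calls2[1:2] <- "U"          # two true M miscalled
  calls2[11:12] <- "M"        # two true U miscalled
  f2 <- f1_scores(factor(calls2, levels = c("U", "M")), truth)
  m_row <- f2$per_state[f2$per_state$state == "M", ]
  expect_equal(m_row$precision, 0.8)
  expect_equal(m_row$recall, 0.8)
  expect_equal(m_row$F1, 0.8)

  # all-undefined predictions: recall and F1 collapse to 0
  undef <- factor(rep("undefined", 20), levels = c("U", "M", "undefined"))
  f3 <- f1_scores(undef, truth)
  expect_equal(f3$per_state$recall, c(0, 0))
  expect_equal(f3$per_state$F1, c(0, 0))
  expect_true(all(f3$per_state$degenerate))
  expect_equal(f3$overall, 0)

  # undefined counts as a false negative for the truth state
  calls4 <- as.character(truth)
  calls4[1] <- "undefined"
  f4 <- f1_scores(factor(calls4, levels = c("U", "M", "undefined")), truth)
  m4 <- f4$per_state[f4$per_state$state == "M", ]
  expect_equal(m4$recall, 9 / 10)
  expect_equal(m4$precision, 1)
})

test_that("GML and weighted GML follow their definitions", {
  ctx <- factor(c("CG", "CG", "CHH"), levels = c("CG", "CHG", "CHH"))
  st <- factor(c("M", "U", "M"), levels = c("U", "M"))
  g <- gml_from_calls(st, ctx)
  expect_equal(unname(g$per_context[["CG"]]), 0.5)
  expect_equal(g$overall, 2 / 3)

  st10 <- factor(c(rep("M", 3), rep("U", 7)), levels = c("U", "M"))
  expect_equal(gml_from_calls(st10, factor(rep("CG", 10)))$overall, 0.3)

  meth <- data.frame(chrom = "chr1", position = c(1L, 5L), strand = "+",
                     context = factor(c("CG", "CG"),
                                      levels = c("CG", "CHG", "CHH")),
                     context_valid = TRUE,
                     methylated = c(1L, 9L), total = c(10L, 10L))
  w <- weighted_gml(meth)
  expect_equal(unname(w$per_context[["CG"]]), 0.5)
  expect_equal(w$overall, 0.5)
  expect_true("CHH" %in% w$undefined_contexts)

  one <- meth[1, ]
  one$methylated <- 3L; one$total <- 4L
  expect_equal(weighted_gml(one)$overall, 0.75)
})

test_that("recalibrated wGML reduces to call-based GML under hard posteriors", {
  meth <- data.frame(chrom = "chr1", position = c(1L, 5L, 9L, 13L),
                     strand = "+",
                     context = factor("CG", levels = "CG"),
                     context_valid = TRUE,
                     methylated = c(0L, 5L, 0L, 0L),
                     total = c(5L, 5L, 5L, 0L))
  # hard posteriors with p_U = 0, p_M = 1: rc_level is the 0/1 call
  fit <- list(rc_level = c(0, 1, 0, 1), data = meth)
  rw <- recalibrated_wgml(fit, meth)
  covered <- meth$total > 0
  expect_equal(rw$overall,
               sum((fit$rc_level * meth$total)[covered]) /
                 sum(meth$total[covered]))
  expect_equal(rw$overall, 1 / 3)   # 5 methylated-called reads of 15

  # two-site arithmetic with soft posteriors
  par <- hmm_params(p = cbind(CG = c(0.1, 0.9)), A0 = diag(2), D = 30,
                    levels = "CG")
  gamma <- rbind(c(0.75, 0.25), c(0.2, 0.8))
  rc <- recalibrated_levels(gamma, par, factor(c("CG", "CG"), levels = "CG"))
  meth2 <- meth[1:2, ]
  fit2 <- list(rc_level = rc, data = meth2)
  expect_equal(recalibrated_wgml(fit2, meth2)$overall,
               sum(rc * 5) / 10, tolerance = 1e-15)

  # all-uncovered: flagged undefined
  meth3 <- meth[4, , drop = FALSE]
  fit3 <- list(rc_level = 0.5, data = meth3)
  expect_true(is.na(recalibrated_wgml(fit3, meth3)$overall))
})

test_that("confidence summary counts high-posterior calls per coverage class", {
  meth <- data.frame(chrom = "chr1", position = seq(1, 24, 4), strand = "+",
                     context = factor("CG", levels = "CG"),
                     context_valid = TRUE,
                     methylated = 0L,
                     total = c(0L, 0L, 1L, 2L, 3L, 9L))
  expect_equal(as.character(coverage_category(meth$total)),
               c("imputed", "imputed", "uninformative", "uninformative",
                 "informative", "informative"))
  g <- rbind(c(0.5, 0.5), c(0.05, 0.95), c(0.3, 0.7), c(0.95, 0.05),
             c(0.2, 0.8), c(0.99, 0.01))
  colnames(g) <- c("U", "M")
  fit <- list(gamma = g, data = meth)
  cs <- confidence_summary(fit, meth, threshold = 0.9)
  expect_equal(unname(cs$by_category["imputed"]), 0.5)
  expect_equal(unname(cs$by_category["uninformative"]), 0.5)
  expect_equal(unname(cs$by_category["informative"]), 0.5)
  fit2 <- list(gamma = matrix(c(0, 1), 6, 2, byrow = TRUE,
                              dimnames = list(NULL, c("U", "M"))),
               data = meth)
  expect_equal(unname(confidence_summary(fit2, meth)$by_category),
               rep(1, 3))
  expect_error(confidence_summary(fit, meth, threshold = 0.4), "threshold")
})

test_that("enrichment profiles recover flat and step patterns and mirror strands", {
  # cytosines every 2 bp across a 100 bp feature plus 40 bp flanks
  pos <- seq(1L, 200L, 2L)
  meth <- data.frame(chrom = "chr1", position = pos, strand = "+",
                     context = factor("CG", levels = "CG"),
                     context_valid = TRUE, methylated = 1L, total = 2L)
  feature <- data.frame(chrom = "chr1", start = 51L, end = 150L,
                        strand = "+", type = "gene")
  flat <- list(rc_level = rep(0.3, length(pos)), data = meth)
  prof <- enrichment_profile(flat, meth, feature, body_bins = 10,
                             flank_bp = 40, flank_bins = 4)
  expect_true(all(abs(prof$mean_rc_level - 0.3) < 1e-12))
  expect_setequal(unique(prof$region), c("upstream", "body", "downstream"))

  # step at the feature midpoint (position 100)
  step_fit <- list(rc_level = ifelse(pos <= 100, 0.1, 0.9), data = meth)
  prof2 <- enrichment_profile(step_fit, meth, feature, body_bins = 10,
                              flank_bp = 40, flank_bins = 4)
  body <- prof2[prof2$region == "body", ]
  expect_equal(body$mean_rc_level[body$bin <= 4 + 5], rep(0.1, 5))
  expect_equal(body$mean_rc_level[body$bin > 4 + 5], rep(0.9, 5))

  # a minus-strand feature mirrors the profile
  feature_m <- feature
  feature_m$strand <- "-"
  prof3 <- enrichment_profile(step_fit, meth, feature_m, body_bins = 10,
                              flank_bp = 40, flank_bins = 4)
  total_bins <- 2 * 4 + 10
  mirrored <- prof3$mean_rc_level[match(total_bins + 1 - prof2$bin,
                                        prof3$bin)]
  expect_equal(prof2$mean_rc_level, mirrored)

  # features with no overlapping cytosines contribute nothing
  far <- data.frame(chrom = "chr9", start = 1L, end = 100L, strand = "+",
                    type = "gene")
  expect_equal(nrow(enrichment_profile(flat, meth, far)), 0L)
})

test_that("coverage categories partition all sites", {
  sim <- simulate_methylome(n = 3000, lambda = 3, seed = 24)
  cats <- table(coverage_category(sim$methylome$total))
  expect_equal(sum(cats), 3000)
  expect_true(all(cats > 0))
})
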