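# HMM primitives: emissions, distance kernel, forward-backward, M-step

test_that("binomial emissions match direct evaluation and handle r = 0", {
  expect_equal(emission_prob(0, 0, 0.37), 1)     # uncovered site
  expect_equal(emission_prob(3, 3, 1.0), 1)      # certain success, 0^0 = 1
  expect_equal(emission_prob(2, 10, 0.1),
               choose(10, 2) * 0.1^2 * 0.9^8, tolerance = 1e-15)
  expect_error(emission_prob(3, 2, 0.5), "m <= r")
})

test_that("distance kernel interpolates between A0 and the uniform matrix", {
  A0 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(transition_matrix(A0, d = 0, D = 30), A0)
  far <- transition_matrix(A0, d = 1e9 * 30, D = 30)
  expect_equal(as.vector(far), rep(0.5, 4), tolerance = 1e-6)
  atD <- transition_matrix(A0, d = 30, D = 30)
  expect_equal(atD[1, 1], 0.8 * exp(-1) + 0.5 * (1 - exp(-1)),
               tolerance = 1e-15)
  expect_error(transition_matrix(A0, d = 1, D = 0), "D must be > 0")
  expect_error(transition_matrix(A0, d = -1, D = 10), "d must be >= 0")
})

test_that("degenerate emissions force the posterior", {
  meth <- data.frame(chrom = "chr1", position = 1L, strand = "+",
                     context = factor("CG", levels = c("CG", "CHG", "CHH")),
                     context_valid = TRUE, methylated = 1L, total = 1L)
  par <- hmm_params(p = cbind(CG = c(0, 1), CHG = c(0, 1), CHH = c(0, 1)),
                    A0 = diag(2) * 0.8 + 0.1, D = 30,
                    levels = c("CG", "CHG", "CHH"))
  fb <- forward_backward(meth, par)
  expect_equal(as.vector(fb$gamma), c(0, 1))
})

test_that("all-uncovered symmetric chains give uniform posteriors", {
  set.seed(8)
  meth <- random_methylome(50)
  meth$methylated <- 0L
  meth$total <- 0L
  par <- random_params()
  par$p[] <- c(0.1, 0.8)   # any p: emissions are 1 at r = 0
  sym <- hmm_params(par$p, matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE),
                    D = 30, pi = c(0.5, 0.5), levels = par$levels)
  fb <- forward_backward(meth, sym)
  expect_equal(as.vector(fb$gamma), rep(0.5, 100), tolerance = 1e-12)
})

test_that("scaled recursion equals exhaustive path enumeration", {
  set.seed(9)
  for (rep in 1:20) {
    Tn <- sample(2:8, 1)
    meth <- random_methylome(Tn, n_chrom = sample(1:2, 1))
    par <- random_params()
    fb <- forward_backward(meth, par)
    en <- fb_enumerate(meth, par)
    expect_equal(fb$loglik, en$loglik, tolerance = 1e-9)
    expect_equal(unname(fb$gamma), en$gamma, tolerance = 1e-9)
    expect_equal(unname(fb$xi), en$xi, tolerance = 1e-9)
    # contracts: rows of gamma and full xi sum to 1
    expect_equal(rowSums(fb$gamma), rep(1, nrow(meth)), tolerance = 1e-12)
    ok <- !is.na(fb$xi[, 1])
    if (any(ok))
      expect_equal(unname(rowSums(fb$xi[ok, , drop = FALSE])),
                   rep(1, sum(ok)), tolerance = 1e-12)
  }
})

test_that("transition update reduces to classical Baum-Welch at d = 0-like steps", {
  # all steps at tiny d/D (expd ~ 1): A = A0, correction factors 1
  set.seed(10)
  meth <- random_methylome(40, levels = "CG")
  meth$position <- seq_len(40)          # d = 1
  meth$context <- factor("CG", levels = "CG")
  par <- random_params(C = 1, levels = "CG")
  par <- hmm_params(par$p, par$A0, D = 1e9, pi = par$pi, levels = "CG")
  fb <- forward_backward(meth, par)
  upd <- update_transitions(fb$xi, fb$layout, par)
  classical <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    classical[i, j] <- sum(fb$xi[, (i - 1) * 2 + j])
  classical <- classical / rowSums(classical)
  expect_equal(unname(upd[, , 1]), classical, tolerance = 1e-7)
})

test_that("M-step updates match the term-by-term oracle transcription", {
  set.seed(12)
  meth <- fixture_methylome6()
  par <- random_params()
  fb <- forward_backward(meth, par)
  A0_pkg <- update_transitions(fb$xi, fb$layout, par)
  A0_orc <- transition_update_oracle(fb$xi, meth, par)
  expect_equal(A0_pkg, A0_orc, tolerance = 1e-12)
  expect_equal(as.vector(apply(A0_pkg, 3, rowSums)),
               rep(1, 2 * dim(A0_pkg)[3]), tolerance = 1e-12)

  p_pkg <- update_emissions(fb$gamma, fb$layout, meth, par)
  p_orc <- emission_update_oracle(fb$gamma, meth, par)
  expect_equal(p_pkg, pmin(pmax(p_orc, 1e-12), 1 - 1e-12),
               tolerance = 1e-14)
})

test_that("emission update pools counts weighted by the posterior", {
  meth <- data.frame(chrom = "chr1", position = c(1L, 5L), strand = "+",
                     context = factor(c("CG", "CG"), levels = "CG"),
                     context_valid = TRUE, methylated = c(1L, 3L),
                     total = c(2L, 4L))
  par <- random_params(C = 1, levels = "CG")
  gamma <- cbind(U = c(0, 0), M = c(1, 1))
  lay <- list(valid = 1:2, ci = c(1L, 1L))
  p <- update_emissions(gamma, lay, meth, par)
  expect_equal(unname(p[2, 1]), 4 / 6, tolerance = 1e-15)
  expect_equal(unname(p[1, 1]), unname(par$p[1, 1]))  # zero denominator kept

  # zero-coverage sites contribute nothing
  meth2 <- rbind(meth, data.frame(chrom = "chr1", position = 9L,
                                  strand = "+",
                                  context = factor("CG", levels = "CG"),
                                  context_valid = TRUE, methylated = 0L,
                                  total = 0L))
  gamma2 <- cbind(U = c(0, 0, 0.3), M = c(1, 1, 0.7))
  lay2 <- list(valid = 1:3, ci = c(1L, 1L, 1L))
  expect_equal(update_emissions(gamma2, lay2, meth2, par)[2, 1], 4 / 6,
               tolerance = 1e-15)
})

test_that("recalibrated levels interpolate the state emission probabilities", {
  par <- hmm_params(p = cbind(CG = c(0.01, 0.81)), A0 = diag(2), D = 30,
                    levels = "CG")
  ctx <- factor(c("CG", "CG", "CG"), levels = "CG")
  gamma <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  m <- recalibrated_levels(gamma, par, ctx)
  expect_equal(m, c(0.01, 0.81, 0.5 * 0.01 + 0.5 * 0.81), tolerance = 1e-15)
})

test_that("posterior confidence decays toward 1/2 inside long uncovered gaps", {
  # covered flanks, one uncovered site far (>> D) from both neighbours
  meth <- data.frame(chrom = "chr1",
                     position = c(1L, 3L, 5000L, 9997L, 9999L),
                     strand = "+",
                     context = factor("CG", levels = "CG"),
                     context_valid = TRUE,
                     methylated = c(5L, 5L, 0L, 5L, 5L),
                     total = c(5L, 5L, 0L, 5L, 5L))
  par <- hmm_params(p = cbind(CG = c(0.05, 0.9)),
                    A0 = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                    D = 30, pi = c(0.5, 0.5), levels = "CG")
  fb <- forward_backward(meth, par)
  expect_gt(fb$gamma[2, 2], 0.99)                 # covered: confident M
  expect_lt(max(fb$gamma[3, ]), 0.51)             # gap >> D: near stationary
})
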