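# Independent oracles: brute-force path enumeration for the HMM E-step and
# literal term-by-term transcriptions of the M-step update formulas.  These
# deliberately share no code with the package internals (plain loops, no
# scaling tricks).

# exhaustive enumeration of all 2^T hidden-state paths
fb_enumerate <- function(methylome, params) {
  v <- methylome[methylome$context_valid, , drop = FALSE]
  Tn <- nrow(v)
  C <- length(params$levels)
  ci <- as.integer(factor(as.character(v$context), levels = params$levels))
  E <- cbind(dbinom(v$methylated, v$total, params$p[1, ci]),
             dbinom(v$methylated, v$total, params$p[2, ci]))
  is_break <- logical(max(Tn - 1, 0))
  A <- vector("list", max(Tn - 1, 0))
  if (Tn > 1) {
    for (t in 1:(Tn - 1)) {
      if (v$chrom[t + 1] != v$chrom[t]) {
        is_break[t] <- TRUE
      } else {
        d <- v$position[t + 1] - v$position[t]
        k <- (ci[t] - 1) * C + ci[t + 1]
        e <- exp(-d / params$D[k])
        A[[t]] <- params$A0[, , k] * e + 0.5 * (1 - e)
      }
    }
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  probs <- apply(paths, 1, function(s) {
    p <- params$pi[s[1]] * E[1, s[1]]
    if (Tn > 1) {
      for (t in 1:(Tn - 1)) {
        p <- p * (if (is_break[t]) params$pi[s[t + 1]]
                  else A[[t]][s[t], s[t + 1]]) * E[t + 1, s[t + 1]]
      }
    }
    p
  })
  Z <- sum(probs)
  gamma <- matrix(0, Tn, 2)
  for (t in 1:Tn) for (i in 1:2)
    gamma[t, i] <- sum(probs[paths[, t] == i]) / Z
  xi <- if (Tn > 1) matrix(NA_real_, Tn - 1, 4) else
    matrix(numeric(0), 0, 4)
  if (Tn > 1) {
    for (t in 1:(Tn - 1)) {
      if (is_break[t]) next
      for (i in 1:2) for (j in 1:2)
        xi[t, (i - 1) * 2 + j] <-
          sum(probs[paths[, t] == i & paths[, t + 1] == j]) / Z
    }
  }
  list(gamma = gamma, xi = xi, loglik = log(Z))
}

# literal transcription of the Lagrange-constrained transition update:
# A'_ijc = (sum_t delta_{c,c_t,t+1} xi_ijt (A0_ijc / A_ij(d_t)) dA/dA0)
#        / (sum_{t,j} same), with dA/dA0 = exp(-d/D_c)
transition_update_oracle <- function(xi, methylome, params) {
  v <- methylome[methylome$context_valid, , drop = FALSE]
  Tn <- nrow(v)
  C <- length(params$levels)
  ci <- as.integer(factor(as.character(v$context), levels = params$levels))
  A0new <- params$A0
  for (cc in seq_len(C * C)) {
    for (i in 1:2) {
      num <- c(0, 0)
      den <- 0
      for (t in seq_len(Tn - 1)) {
        if (v$chrom[t + 1] != v$chrom[t]) next
        k <- (ci[t] - 1) * C + ci[t + 1]
        if (k != cc) next
        d <- v$position[t + 1] - v$position[t]
        e <- exp(-d / params$D[cc])
        for (j in 1:2) {
          A_ij <- params$A0[i, j, cc] * e + 0.5 * (1 - e)
          term <- xi[t, (i - 1) * 2 + j] * (params$A0[i, j, cc] / A_ij) * e
          num[j] <- num[j] + term
          den <- den + term
        }
      }
      if (den > 0) A0new[i, , cc] <- num / den
    }
  }
  A0new
}

# literal transcription of the emission update:
# p'_ic = sum_t delta_{c,c_t} gamma_it m_t / sum_t delta_{c,c_t} gamma_it r_t
emission_update_oracle <- function(gamma, methylome, params) {
  v <- methylome[methylome$context_valid, , drop = FALSE]
  C <- length(params$levels)
  ci <- as.integer(factor(as.character(v$context), levels = params$levels))
  pnew <- params$p
  for (cc in seq_len(C)) {
    for (i in 1:2) {
      num <- 0
      den <- 0
      for (t in seq_len(nrow(v))) {
        if (ci[t] != cc) next
        num <- num + gamma[t, i] * v$methylated[t]
        den <- den + gamma[t, i] * v$total[t]
      }
      if (den > 0) pnew[i, cc] <- num / den
    }
  }
  pnew
}

# random valid parameters and a random small methylome for property tests
random_params <- function(C = 3, levels = c("CG", "CHG", "CHH")[seq_len(C)]) {
  p <- rbind(runif(C, 0, 0.4), runif(C, 0.5, 1))
  colnames(p) <- levels
  A0 <- array(0, c(2, 2, C * C))
  for (k in seq_len(C * C)) {
    a <- runif(2, 0.05, 0.95)
    A0[, , k] <- rbind(c(a[1], 1 - a[1]), c(1 - a[2], a[2]))
  }
  pi1 <- runif(1, 0.05, 0.95)
  hmm_params(p, A0, D = runif(C * C, 5, 100), pi = c(pi1, 1 - pi1),
             levels = levels)
}

random_methylome <- function(Tn, levels = c("CG", "CHG", "CHH"),
                             n_chrom = 1, lambda = 4) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), Tn, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(Tn), chrom), function(ix)
    cumsum(1L + rgeom(length(ix), 0.2))), use.names = FALSE)
  r <- rpois(Tn, lambda)
  m <- rbinom(Tn, r, runif(Tn))
  data.frame(chrom = chrom, position = pos, strand = "+",
             context = factor(sample(levels, Tn, replace = TRUE),
                              levels = levels),
             context_valid = TRUE, methylated = m, total = r,
             stringsAsFactors = FALSE)
}

# small deterministic methylome fixture used by several M-step tests
fixture_methylome6 <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    position = c(1L, 4L, 10L, 40L, 3L, 5L),
    strand = "+",
    context = factor(c("CG", "CHH", "CG", "CHG", "CHG", "CG"),
                     levels = c("CG", "CHG", "CHH")),
    context_valid = TRUE,
    methylated = c(3L, 0L, 1L, 2L, 0L, 5L),
    total = c(4L, 2L, 1L, 6L, 0L, 5L),
    stringsAsFactors = FALSE
  )
}
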