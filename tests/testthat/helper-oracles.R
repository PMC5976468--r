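# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the implementation it checks.

# least-squares slope/t/p via the generic linear-model fitter
ols_oracle <- function(g, y) {
  fit <- lm(y ~ g)
  s <- summary(fit)$coefficients["g", ]
  list(beta = unname(s["Estimate"]), t_stat = unname(s["t value"]),
       p_value = unname(s["Pr(>|t|)"]))
}

# one-way ANOVA by explicit between/within sum-of-squares decomposition
anova_ss_oracle <- function(g, y) {
  g <- factor(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tapply(y, g, length)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((y - means[as.character(g)])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  list(F_stat = f, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

# BH step-up computed literally from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive best PWM placement: per-position probability products, both
# strands, scored from first principles
scan_oracle <- function(sequence, pwm) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    tot <- 0
    for (j in seq_along(b)) {
      i <- match(b[j], c("A", "C", "G", "T"))
      tot <- tot + log2(pwm$probs[i, j]) - log2(pwm$background[i])
    }
    tot
  }
  w <- pwm$width
  best <- -Inf
  for (st in seq_len(nchar(sequence) - w + 1L)) {
    win <- substr(sequence, st, st + w - 1L)
    best <- max(best, score1(win), score1(rc(win)))
  }
  best
}

# random PWM with a fixed generator state managed by the caller
random_pwm <- function(width) {
  counts <- matrix(sample(1:50, 4 * width, replace = TRUE), nrow = 4)
  pwm_matrix(counts)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small cohort reused by several files
small_sim <- function(seed = 11) {
  simulate_cohort(sim_config(n_patients = 120, n_snps = 12, n_genes = 6,
                             seed = seed))
}
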