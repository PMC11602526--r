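# Independent oracles used across tests; deliberately naive implementations.

# exhaustive double-loop ROC scan over all midpoints between sorted unique
# values (plus open extremes), maximizing Youden's J, ties toward the more
# specific cutoff
brute_force_cutoff <- function(x, y, direction = "high_abnormal") {
  s <- if (direction == "high_abnormal") 1 else -1
  xs <- s * x
  u <- sort(unique(xs))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (cc in cand) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(xs)) {
      pos <- xs[i] >= cc
      if (y[i] && pos) tp <- tp + 1
      if (!y[i] && pos) fp <- fp + 1
      if (y[i] && !pos) fn <- fn + 1
      if (!y[i] && !pos) tn <- tn + 1
    }
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12))
      best <- list(cutoff = s * cc, j = j, sens = sens, spec = spec)
  }
  best
}

# Mann-Whitney AUC with half credit for ties (pairwise enumeration)
brute_force_auc <- function(x, y) {
  pos <- x[y]; neg <- x[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ICC(2,1) via aov() mean squares (independent of the closed-form path)
aov_icc21 <- function(rep1, rep2) {
  n <- length(rep1)
  d <- data.frame(y = c(rep1, rep2),
                  subj = factor(rep(seq_len(n), 2)),
                  scan = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + scan, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# random square contingency table with at least one count
random_table <- function(k, rng_max = 6) {
  m <- matrix(sample(0:rng_max, k * k, replace = TRUE), k, k)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

figure6_tte_panel <- function()
  list(E = 80, A = 40, e_average = 9, tr_velocity = 300)

figure6_cmr_panel <- function()
  list(E = 55, A = 37, e_average = 8, tr_velocity = 300)
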