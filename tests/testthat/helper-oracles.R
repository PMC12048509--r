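# Independent oracles used to cross-check the analytic implementations.

# stationary distribution as the null space of the generator matrix,
# built here directly from the master equation (independent of the
# package's closed form)
oracle_steady_state <- function(kc, ko, ki, kt) {
  A <- matrix(c(-ko,        kc,   0,
                ko, -(kc + ki), kt,
                0,         ki, -kt), nrow = 3, byrow = TRUE)
  v <- svd(A)$v[, 3]
  p <- v / sum(v)
  stats::setNames(p, c("p_nuc", "p_open", "p_pol2"))
}

# brute-force grid search over (A, kt) for the Poisson decay likelihood
oracle_grid_fit_decay <- function(y, t, kt_max = 2, rounds = 4) {
  ll <- function(A, k) sum(y * log(A * exp(-k * t)) - A * exp(-k * t))
  k_lo <- 1e-6; k_hi <- kt_max
  A_lo <- max(y) * 0.25; A_hi <- max(y) * 4
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    ks <- seq(k_lo, k_hi, length.out = 201)
    As <- seq(A_lo, A_hi, length.out = 201)
    vals <- outer(As, ks, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(As[idx[1]], ks[idx[2]])
    dk <- ks[2] - ks[1]; dA <- As[2] - As[1]
    k_lo <- max(1e-9, best[2] - 2 * dk); k_hi <- best[2] + 2 * dk
    A_lo <- max(1e-9, best[1] - 2 * dA); A_hi <- best[1] + 2 * dA
  }
  list(A = best[1], kt = best[2])
}

# Pearson chi-square membership test for the multinomial confidence region
in_multinomial_region <- function(counts, probs, level = 0.99) {
  n <- sum(counts)
  expct <- n * probs
  keep <- probs > 0
  stat <- sum((counts[keep] - expct[keep])^2 / expct[keep])
  stat <= stats::qchisq(level, df = sum(keep) - 1)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), alpha)
  x / sum(x)
}

all_patterns <- function() {
  apply(expand.grid(0:1, 0:1, 0:1, 0:1)[, 4:1], 1, paste, collapse = "")
}
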