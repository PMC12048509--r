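mk_tc <- function(counts, timepoints, replicates = 1,
                  spikein = NULL) {
  samples <- expand.grid(replicate_id = paste0("rep", seq_len(replicates)),
                         timepoint_min = timepoints,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("t%g_%s", samples$timepoint_min,
                               samples$replicate_id)
  samples$spikein_total <- if (is.null(spikein)) 1e6 else spikein
  colnames(counts) <- samples$sample_id
  time_course(counts, samples)
}

test_that("spike-in normalisation divides by the sample total", {
  tc <- mk_tc(matrix(c(100, 100), 1, dimnames = list("g1", NULL)),
              timepoints = c(0, 5), spikein = c(1e4, 2e4))
  ntc <- spikein_normalize(tc, scale = 1)
  expect_equal(unname(ntc$norm["g1", ]), c(0.01, 0.005))
})

test_that("normalisation is scale-equivariant within a sample", {
  counts <- matrix(c(100, 80, 60, 40), 1, dimnames = list("g1", NULL))
  tc1 <- mk_tc(counts, c(0, 2.5, 5, 10), spikein = c(1e6, 9e5, 8e5, 7e5))
  tc2 <- mk_tc(counts * 3, c(0, 2.5, 5, 10),
               spikein = 3 * c(1e6, 9e5, 8e5, 7e5))
  expect_equal(spikein_normalize(tc1, scale = 1)$norm,
               spikein_normalize(tc2, scale = 1)$norm)
})

test_that("replicates average; single-replicate timepoints pass through", {
  counts <- matrix(c(100, 120, 50, 70), 1,
                   dimnames = list("g1", NULL))
  samples <- data.frame(
    sample_id = c("t0_rep1", "t0_rep2", "t5_rep1", "t5_rep2"),
    timepoint_min = c(0, 0, 5, 5), replicate_id = c("rep1", "rep2") ,
    spikein_total = 1e6)
  colnames(counts) <- samples$sample_id
  ntc <- spikein_normalize(time_course(counts, samples), scale = 1e6)
  expect_equal(unname(ntc$norm["g1", ]), c(110, 60))
  # one replicate at a timepoint (the 2.5-min QC dropout scenario)
  counts2 <- counts[, -4, drop = FALSE]
  ntc2 <- spikein_normalize(time_course(counts2, samples[-4, ]),
                            scale = 1e6)
  expect_equal(unname(ntc2$norm["g1", "5"]), 50)
  # identical replicates: averaging is the identity
  counts3 <- counts; counts3[1, 2] <- 100; counts3[1, 4] <- 50
  ntc3 <- spikein_normalize(time_course(counts3, samples), scale = 1e6)
  expect_equal(unname(ntc3$norm["g1", ]), c(100, 50))
})

test_that("time_course validates its inputs", {
  counts <- matrix(1, 1, 1, dimnames = list("g", "s1"))
  s <- data.frame(sample_id = "s1", timepoint_min = 5, replicate_id = "r1",
                  spikein_total = 10)
  expect_error(time_course(counts, s), "timepoint 0")
  s$timepoint_min <- 0; s$spikein_total <- 0
  expect_error(time_course(counts, s), "spikein_total")
})

test_that("fold changes are anchored at 1 and drop zero baselines", {
  tc <- mk_tc(matrix(c(10, 5, 2.5, 0, 3, 6), 2, byrow = TRUE,
                     dimnames = list(c("g1", "g2"), NULL)),
              timepoints = c(0, 5, 10))
  ntc <- spikein_normalize(tc, scale = 1e6)
  expect_message(fc <- fold_changes(ntc), "zero baseline")
  expect_equal(unname(fc["g1", ]), c(1, 0.5, 0.25))
  expect_equal(attr(fc, "dropped"), "g2")
  # constant series -> all 1
  tcc <- mk_tc(matrix(7, 1, 3, dimnames = list("g1", NULL)), c(0, 5, 10))
  fcc <- fold_changes(spikein_normalize(tcc))
  expect_equal(unname(fcc["g1", ]), c(1, 1, 1))
})

test_that("the Poisson decay MLE matches a brute-force grid oracle", {
  t <- c(0, 2.5, 5, 10, 20)
  # noiseless curve: exact recovery
  fit <- fit_decay(1000 * exp(-0.2 * t), t)
  expect_equal(fit$kt_hat, 0.2, tolerance = 1e-6)
  expect_equal(fit$half_life, log(2) / fit$kt_hat)
  expect_equal(fit$half_life, 3.4657, tolerance = 1e-4)
  oracle <- oracle_grid_fit_decay(1000 * exp(-0.2 * t), t)
  expect_equal(fit$kt_hat, oracle$kt, tolerance = 1e-4)

  # random instances vs the oracle, 3 significant figures
  set.seed(17)
  for (i in 1:20) {
    kt <- runif(1, 0.05, 0.8)
    A <- runif(1, 500, 5000)
    y <- rpois(length(t), A * exp(-kt * t))
    if (sum(y) == 0) next
    fit <- fit_decay(y, t)
    if (fit$boundary) next
    oracle <- oracle_grid_fit_decay(y, t)
    expect_equal(fit$kt_hat, oracle$kt, tolerance = 5e-3)
    expect_equal(fit$amplitude_hat, oracle$A, tolerance = 5e-3)
  }
})

test_that("non-decaying data lands on the kt = 0 boundary", {
  t <- c(0, 2.5, 5, 10, 20)
  fit <- fit_decay(rep(100, 5), t)
  expect_true(fit$boundary)
  expect_equal(fit$kt_hat, 0)
  expect_identical(fit$half_life, Inf)
  # increasing counts likewise
  expect_true(fit_decay(c(10, 20, 30, 40, 50), t)$boundary)
  expect_error(fit_decay(c(0, 0, 0, 0, 0), t), "zero")
  expect_error(fit_decay(c(5, 4), c(0, 5)), "3 distinct")
})

test_that("half-life is a strictly decreasing function of the rate", {
  t <- c(0, 2.5, 5, 10, 20)
  kts <- c(0.05, 0.14, 0.3, 0.7)
  hl <- vapply(kts, function(k) fit_decay(5000 * exp(-k * t), t)$half_life,
               numeric(1))
  expect_true(all(diff(hl) < 0))
  expect_equal(fit_decay(1000 * exp(-log(2) * t), t)$half_life, 1,
               tolerance = 1e-6)
})

test_that("k-means separates slow from fast decay families", {
  set.seed(4)
  kt_true <- rep(c(0.05, 0.7), each = 200)
  sim <- simulate_timecourse(kt_true, A = 5000, seed = 19)
  ntc <- spikein_normalize(sim$tc)
  fc <- fold_changes(ntc)
  cl <- cluster_decay(fc, k = 2, seed = 1)
  truth_lab <- rep(1:2, each = 200)[match(names(cl$assignment),
                                          sim$truth$tss_id)]
  acc <- mean(cl$assignment == truth_lab)
  expect_gte(acc, 0.95)
  # cluster 1 is the slower-decaying group by construction
  expect_lt(cl$centroid_kt[1], cl$centroid_kt[2])
  # determinism
  cl2 <- cluster_decay(fc, k = 2, seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("degenerate clustering inputs behave", {
  fc <- matrix(rep(c(1, 0.5, 0.25), each = 3), 3,
               dimnames = list(paste0("g", 1:3), c("0", "5", "10")))
  attr(fc, "timepoints") <- c(0, 5, 10)
  cl <- cluster_decay(fc, k = 1, seed = 1)
  expect_equal(unname(cl$assignment), rep(1L, 3))
  expect_equal(unname(cl$centroids["1", ]), c(1, 0.5, 0.25))
  expect_error(cluster_decay(fc, k = 5, seed = 1), "fewer")
})

test_that("per-cluster fits recover the generating half-lives", {
  set.seed(6)
  kt_true <- rep(c(0.05, 0.14, 0.3, 0.7), each = 100)
  sim <- simulate_timecourse(kt_true, A = 3000, seed = 23)
  ntc <- spikein_normalize(sim$tc)
  fc <- fold_changes(ntc)
  cl <- cluster_decay(fc, k = 4, seed = 2)
  fits <- fit_cluster_decay(ntc, cl)
  expect_equal(fits$kt, c(0.05, 0.14, 0.3, 0.7), tolerance = 0.1)
  expect_equal(fits$half_life_min, log(2) / c(0.05, 0.14, 0.3, 0.7),
               tolerance = 0.1)
  expect_true(all(fits$ci_lo <= fits$kt & fits$kt <= fits$ci_hi))
})

test_that("pausing index applies the printed exclusion rules", {
  out <- pausing_index(c(90, 10, 50), c(30, 0, 20), c(5000, 5000, 500))
  expect_equal(out$pausing_index[1], 3)
  expect_true(is.na(out$pausing_index[2]))
  expect_equal(out$exclude_reason[2], "non-finite")
  expect_equal(out$exclude_reason[3], "length")
  expect_error(pausing_index(-1, 1, 1000), "non-negative")
})

test_that("time-course TSVs round-trip", {
  sim <- simulate_timecourse(c(g1 = 0.2, g2 = 0.05), A = 1000, seed = 3)
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_time_course(sim$tc, cp, sp)
  back <- read_time_course(cp, sp)
  expect_equal(back$counts, sim$tc$counts)
  expect_equal(back$samples, sim$tc$samples)
})
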