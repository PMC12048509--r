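#' Canonical bin accessibility pattern per promoter state
#'
#' The pattern a noiseless molecule of each state produces in the four bins
#' (order upstream, TATA, Pol II, downstream; 1 = accessible).  These are
#' the patterns that map uniquely back to their state under
#' [default_state_mapping()]: unbound 1111, PIC 1011, PolII 1101, PIC+PolII
#' 1001, nucleosome 0000, unassigned 0101 (a representative non-contiguous
#' pattern).
#'
#' @return Named list of 4-bit integer vectors.
#' @export
state_patterns <- function() {
  list("unbound"    = c(1L, 1L, 1L, 1L),
       "PIC"        = c(1L, 0L, 1L, 1L),
       "PolII"      = c(1L, 1L, 0L, 1L),
       "PIC+PolII"  = c(1L, 0L, 0L, 1L),
       "nucleosome" = c(0L, 0L, 0L, 0L),
       "unassigned" = c(0L, 1L, 0L, 1L))
}

template_positions <- function(layout, cytosines_per_bin, flank_spacing,
                               flank_range) {
  bin_pos <- unlist(lapply(seq_along(layout), function(i) {
    w <- layout[[i]]
    unique(round(seq(w[1], w[2], length.out = cytosines_per_bin)))
  }))
  bins <- rep(seq_along(layout),
              vapply(seq_along(layout), function(i) {
                w <- layout[[i]]
                length(unique(round(seq(w[1], w[2],
                                        length.out = cytosines_per_bin))))
              }, integer(1)))
  flank <- seq(flank_range[1], flank_range[2], by = flank_spacing)
  flank <- flank[is.na(assign_bin(flank, layout))]
  data.frame(rel_pos = c(bin_pos, flank),
             bin = c(bins, rep(NA_integer_, length(flank))))
}

#' Simulate single-molecule footprinting reads with known state truth
#'
#' Draws each molecule's promoter state from the supplied six-state
#' frequencies, writes per-cytosine methylation calls consistent with that
#' state's accessibility pattern (protected bins unmethylated, accessible
#' bins methylated; flanking cytosines accessible except in the nucleosome
#' state), and flips every call independently with probability
#' `call_noise`.  Deterministic for a fixed seed.
#'
#' @param state_freqs Matrix (promoters x 6, columns named as
#'   [promoter_states()]) of state frequencies, or a single named vector.
#'   Rownames (or `tss_ids`) name the promoters.
#' @param n_reads Molecules per promoter.
#' @param seed Integer seed.
#' @param layout A [bin_layout()].
#' @param cytosines_per_bin Informative cytosines per bin (>= 1).
#' @param flank_spacing Spacing of flanking cytosines outside the bins (bp).
#' @param flank_range Relative range covered by flanking cytosines.
#' @param call_noise Probability a call flips (must be < 0.5).
#' @param replicate_id Replicate label stamped on the reads.
#' @param tss_ids Optional promoter names (default from rownames).
#' @param out_dir If non-NULL, the calls and truth tables are also written
#'   as `reads.tsv` and `truth_states.tsv` in this directory.
#' @return List with `reads` (long call table: `read_id`, `tss_id`,
#'   `replicate_id`, `rel_pos`, `methylated`) and `truth` (per-promoter true
#'   frequencies and realised state counts).
#' @export
simulate_reads <- function(state_freqs, n_reads = 1000, seed = 1,
                           layout = bin_layout("mouse"),
                           cytosines_per_bin = 2, flank_spacing = 25,
                           flank_range = c(-250L, 250L), call_noise = 0,
                           replicate_id = "rep1", tss_ids = NULL,
                           out_dir = NULL) {
  if (is.null(dim(state_freqs)))
    state_freqs <- matrix(state_freqs, nrow = 1,
                          dimnames = list("tss_1", names(state_freqs)))
  if (!setequal(colnames(state_freqs), promoter_states()))
    stop("state_freqs columns must be the six promoter states", call. = FALSE)
  state_freqs <- state_freqs[, promoter_states(), drop = FALSE]
  if (any(state_freqs < 0) ||
      any(abs(rowSums(state_freqs) - 1) > 1e-8))
    stop("each row of state_freqs must be a probability vector", call. = FALSE)
  if (call_noise < 0 || call_noise >= 0.5)
    stop("call_noise must lie in [0, 0.5)", call. = FALSE)
  stopifnot(cytosines_per_bin >= 1, n_reads >= 1)
  if (is.null(tss_ids)) tss_ids <- rownames(state_freqs)
  if (is.null(tss_ids)) tss_ids <- paste0("tss_", seq_len(nrow(state_freqs)))

  set.seed(as.integer(seed))
  tmpl <- template_positions(layout, cytosines_per_bin, flank_spacing,
                             flank_range)
  pat <- state_patterns()
  # per-state accessibility over the template (flank accessible unless
  # nucleosome)
  access <- vapply(promoter_states(), function(s) {
    bits <- pat[[s]]
    ifelse(is.na(tmpl$bin), as.integer(s != "nucleosome"), bits[tmpl$bin])
  }, integer(nrow(tmpl)))

  P <- nrow(tmpl)
  reads_list <- vector("list", nrow(state_freqs))
  truth_list <- vector("list", nrow(state_freqs))
  for (g in seq_len(nrow(state_freqs))) {
    states <- sample(promoter_states(), n_reads, replace = TRUE,
                     prob = state_freqs[g, ])
    meth <- t(access[, states, drop = FALSE])        # n_reads x P
    if (call_noise > 0) {
      flips <- matrix(stats::runif(n_reads * P) < call_noise, n_reads, P)
      meth <- abs(meth - flips)
    }
    reads_list[[g]] <- data.frame(
      read_id = rep(sprintf("%s_r%06d", tss_ids[g], seq_len(n_reads)),
                    each = P),
      tss_id = tss_ids[g], replicate_id = replicate_id,
      rel_pos = rep(tmpl$rel_pos, times = n_reads),
      methylated = as.integer(t(meth)), stringsAsFactors = FALSE)
    cnt <- table(factor(states, promoter_states()))
    truth_list[[g]] <- data.frame(
      tss_id = tss_ids[g], state = promoter_states(),
      true_freq = as.numeric(state_freqs[g, ]),
      n_drawn = as.integer(cnt), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads_list)
  truth <- do.call(rbind, truth_list)
  rownames(reads) <- rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_methylation_tsv(reads, file.path(out_dir, "reads.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth_states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Simulate a spike-in-scaled decay time course with known turnover rates
#'
#' Per promoter `g` and sample at time `t`, counts are drawn
#' `Poisson(s_sample * A_g * exp(-kt_g * t))`, where
#' `s_sample = spikein_total / mean(spikein_total)` models the inter-sample
#' scale the spike-in normalisation removes.  Deterministic for a fixed
#' seed.
#'
#' @param kt True turnover rates (min^-1), one per promoter; names (or
#'   `tss_ids`) name the promoters.
#' @param A True t = 0 expected counts (recycled).
#' @param timepoints Minutes (must include 0).
#' @param replicates Replicates per timepoint.
#' @param spikein_totals One total per sample
#'   (`length(timepoints) * replicates`); by default drawn uniformly in
#'   `[8e5, 1.2e6]` to exercise the normalisation.
#' @param seed Integer seed.
#' @param tss_ids Optional promoter names.
#' @param out_dir If non-NULL, writes `timecourse.tsv`, `samples.tsv` and
#'   `truth_kt.tsv` there.
#' @return List with `tc` (a [time_course()]) and `truth` (per-promoter
#'   `tss_id`, `kt`, `A`, `half_life_min`).
#' @export
simulate_timecourse <- function(kt, A = 5000,
                                timepoints = c(0, 2.5, 5, 10, 20),
                                replicates = 2, spikein_totals = NULL,
                                seed = 1, tss_ids = NULL, out_dir = NULL) {
  if (!0 %in% timepoints) stop("timepoints must include 0", call. = FALSE)
  if (any(kt < 0)) stop("kt must be non-negative", call. = FALSE)
  n_g <- length(kt)
  A <- rep_len(A, n_g)
  if (is.null(tss_ids)) tss_ids <- names(kt)
  if (is.null(tss_ids)) tss_ids <- paste0("tss_", seq_len(n_g))
  set.seed(as.integer(seed))
  samples <- expand.grid(replicate_id = paste0("rep", seq_len(replicates)),
                         timepoint_min = timepoints,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("t%g_%s", samples$timepoint_min,
                               samples$replicate_id)
  if (is.null(spikein_totals))
    spikein_totals <- round(stats::runif(nrow(samples), 8e5, 1.2e6))
  samples$spikein_total <- spikein_totals
  s_fac <- samples$spikein_total / mean(samples$spikein_total)
  mu <- outer(A, rep(1, nrow(samples))) *
    exp(-outer(kt, samples$timepoint_min)) *
    matrix(s_fac, n_g, nrow(samples), byrow = TRUE)
  counts <- matrix(stats::rpois(length(mu), mu), n_g,
                   dimnames = list(tss_ids, samples$sample_id))
  tc <- time_course(counts, samples[, c("sample_id", "timepoint_min",
                                        "replicate_id", "spikein_total")])
  truth <- data.frame(tss_id = tss_ids, kt = as.numeric(kt), A = A,
                      half_life_min = log(2) / as.numeric(kt),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_time_course(tc, file.path(out_dir, "timecourse.tsv"),
                      file.path(out_dir, "samples.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth_kt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tc = tc, truth = truth)
}

#' Six-state frequencies induced by model rates
#'
#' Maps the three-state steady state onto the six observable states: the
#' open probability is split equally between `unbound` and `PIC`, the
#' Pol II probability equally between `PolII` and `PIC+PolII`, and
#' `unassigned` gets zero mass.
#'
#' @param rates A [kinetic_rates()] object.
#' @return Named frequency vector over [promoter_states()].
#' @export
state_freqs_from_rates <- function(rates) {
  p <- steady_state(rates)
  stats::setNames(
    c(p[["p_pol2"]] / 2, p[["p_pol2"]] / 2, p[["p_open"]] / 2,
      p[["p_open"]] / 2, p[["p_nuc"]], 0),
    promoter_states())
}

#' Simulate a consistent reads + time-course dataset from known kinetics
#'
#' For each promoter, single-molecule reads are generated from the
#' steady-state state frequencies of its rates, and a decay time course is
#' generated from the same turnover rate, so that running the classifier
#' (for `q`), the turnover fit (for `kt`) and [infer_initiation_rate()]
#' must recover the generating `ki`.
#'
#' @param rates_list List of [kinetic_rates()] (one per promoter), or a
#'   single `kinetic_rates` object.
#' @param n_reads Molecules per promoter.
#' @param A Expected t = 0 time-course counts per promoter (recycled).
#' @param timepoints Time-course design (minutes, must include 0).
#' @param call_noise Per-call flip probability for the reads.
#' @param seed Integer seed (split internally between the two generators).
#' @param tss_ids Optional promoter names.
#' @param out_dir If non-NULL, all tables are written there.
#' @return List with `reads`, `tc`, and `truth` (per-promoter `tss_id`,
#'   `kc`, `ko`, `ki`, `kt`, `q`, plus the six true state frequencies).
#' @export
simulate_end_to_end <- function(rates_list, n_reads = 20000, A = 5000,
                                timepoints = c(0, 2.5, 5, 10, 20),
                                call_noise = 0, seed = 1, tss_ids = NULL,
                                out_dir = NULL) {
  if (inherits(rates_list, "kinetic_rates")) rates_list <- list(rates_list)
  n_g <- length(rates_list)
  if (is.null(tss_ids)) tss_ids <- paste0("tss_", seq_len(n_g))
  freqs <- t(vapply(rates_list, state_freqs_from_rates, numeric(6)))
  rownames(freqs) <- tss_ids
  q_true <- vapply(rates_list, function(r)
    relative_occupancy(steady_state(r))$q, numeric(1))
  kt_true <- vapply(rates_list, `[[`, numeric(1), "kt")
  sim_r <- simulate_reads(freqs, n_reads = n_reads, seed = seed,
                          call_noise = call_noise, tss_ids = tss_ids,
                          out_dir = out_dir)
  sim_t <- simulate_timecourse(stats::setNames(kt_true, tss_ids), A = A,
                               timepoints = timepoints,
                               seed = as.integer(seed) + 1L,
                               tss_ids = tss_ids, out_dir = out_dir)
  truth <- data.frame(
    tss_id = tss_ids,
    kc = vapply(rates_list, `[[`, numeric(1), "kc"),
    ko = vapply(rates_list, `[[`, numeric(1), "ko"),
    ki = vapply(rates_list, `[[`, numeric(1), "ki"),
    kt = kt_true, q = q_true, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(freqs))
  rownames(truth) <- NULL
  if (!is.null(out_dir))
    utils::write.table(truth, file.path(out_dir, "truth_kinetics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads = sim_r$reads, tc = sim_t$tc, truth = truth)
}
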