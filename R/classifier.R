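#' Promoter state labels
#'
#' The six single-molecule promoter states, in the column order used by all
#' state tables: Pol II, PIC + Pol II, PIC, unbound, nucleosome, unassigned.
#' @return Character vector of length 6.
#' @export
promoter_states <- function() {
  c("PolII", "PIC+PolII", "PIC", "unbound", "nucleosome", "unassigned")
}

state_freq_cols <- c(
  "PolII" = "f_pol2", "PIC+PolII" = "f_pic_pol2", "PIC" = "f_pic",
  "unbound" = "f_unbound", "nucleosome" = "f_nucleosome",
  "unassigned" = "f_unassigned")

#' Four-bin layout around the TSS
#'
#' The classifier reads the methylation pattern in four bins on the
#' TSS-relative axis (upstream flank, TATA region, Pol II pausing site,
#' downstream flank).  Coordinates are closed intervals with the TSS base at
#' 0 and upstream negative.  The `"mouse"` preset is
#' upstream `[-58,-43]`, TATA `[-36,-22]`, Pol II `[28,47]`,
#' downstream `[54,69]`.
#'
#' @param preset Either `"mouse"` or `NULL` when giving explicit windows.
#' @param upstream,tata,pol2,downstream Length-2 integer vectors `c(start,
#'   end)` on the TSS-relative axis; required when `preset` is `NULL`.
#' @return An object of class `bin_layout`: a named list of windows.
#' @export
#' @examples
#' bin_layout("mouse")
bin_layout <- function(preset = "mouse", upstream = NULL, tata = NULL,
                       pol2 = NULL, downstream = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "mouse")
    wins <- list(upstream = c(-58L, -43L), tata = c(-36L, -22L),
                 pol2 = c(28L, 47L), downstream = c(54L, 69L))
  } else {
    wins <- list(upstream = upstream, tata = tata, pol2 = pol2,
                 downstream = downstream)
  }
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (is.null(w) || length(w) != 2L || !is.numeric(w) || w[1] > w[2])
      stop("bin '", nm, "' must be c(start, end) with start <= end",
           call. = FALSE)
  }
  ends <- vapply(wins, `[`, numeric(1), 2)
  starts <- vapply(wins, `[`, numeric(1), 1)
  if (any(starts[-1] <= ends[-4]))
    stop("the four bins must be disjoint and ordered ",
         "upstream < tata < pol2 < downstream", call. = FALSE)
  structure(wins, class = "bin_layout")
}

#' @export
print.bin_layout <- function(x, ...) {
  cat("bin layout (TSS-relative, closed intervals):\n")
  for (nm in names(x))
    cat(sprintf("  %-10s [%d, %d]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Default mapping of the 16 bin patterns to six promoter states
#'
#' Each molecule is summarised as a 4-bit accessibility vector over the bins
#' (order upstream, TATA, Pol II, downstream; 1 = accessible/methylated,
#' 0 = protected).  The default mapping reads the patterns biochemically:
#' fully accessible is `unbound`; protection confined to the TATA bin is
#' `PIC`; to the Pol II bin, `PolII`; to both, `PIC+PolII`; a contiguous
#' protected run touching an edge bin is a broad `nucleosome` footprint; the
#' remaining (non-contiguous or interior-only) patterns are `unassigned`.
#' The mapping is an input: supply any complete 16-row table to
#' [classify_molecules()] to override it.
#'
#' @return Data frame with columns `pattern` (e.g. `"1011"`) and `state`.
#' @export
default_state_mapping <- function() {
  m <- c(
    "1111" = "unbound", "1011" = "PIC", "1101" = "PolII",
    "1001" = "PIC+PolII",
    "0000" = "nucleosome", "0001" = "nucleosome", "1000" = "nucleosome",
    "0011" = "nucleosome", "1100" = "nucleosome", "0111" = "nucleosome",
    "1110" = "nucleosome",
    "0101" = "unassigned", "1010" = "unassigned", "0110" = "unassigned",
    "0010" = "unassigned", "0100" = "unassigned")
  data.frame(pattern = names(m), state = unname(m), stringsAsFactors = FALSE)
}

validate_state_mapping <- function(mapping) {
  if (!is.data.frame(mapping) || !all(c("pattern", "state") %in% names(mapping)))
    stop("mapping must be a data frame with columns pattern, state",
         call. = FALSE)
  all16 <- apply(expand.grid(0:1, 0:1, 0:1, 0:1)[, 4:1], 1, paste, collapse = "")
  if (!setequal(mapping$pattern, all16) || anyDuplicated(mapping$pattern))
    stop("mapping must cover each of the 16 four-bit patterns exactly once",
         call. = FALSE)
  if (!setequal(unique(mapping$state), promoter_states()))
    stop("mapping must use exactly the six promoter states", call. = FALSE)
  mapping
}

#' Read / write a state mapping TSV
#'
#' Two-column TSV with header `pattern<TAB>state`; patterns are four
#' characters of 0/1 in bin order upstream, TATA, Pol II, downstream.
#' @param path File path.
#' @return For the reader, a validated mapping data frame.
#' @export
read_state_mapping <- function(path) {
  m <- utils::read.delim(path, colClasses = "character")
  validate_state_mapping(m)
}

#' @rdname read_state_mapping
#' @param mapping Mapping data frame.
#' @export
write_state_mapping <- function(mapping, path) {
  utils::write.table(validate_state_mapping(mapping), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

assign_bin <- function(rel_pos, layout) {
  bin <- rep(NA_integer_, length(rel_pos))
  for (i in seq_along(layout)) {
    w <- layout[[i]]
    bin[rel_pos >= w[1] & rel_pos <= w[2]] <- i
  }
  bin
}

#' Summarise one molecule as a four-bit accessibility vector
#'
#' The mean methylation over the calls in each bin is rounded to 0 or 1
#' (a mean of exactly 0.5 rounds up, to accessible).  A read lacking calls in
#' any of the four bins cannot be classified and returns `NULL` (rejected).
#'
#' @param calls Data frame with columns `rel_pos` (TSS-relative position on
#'   the gene strand) and `methylated` (0/1; 1 = accessible).
#' @param layout A [bin_layout()].
#' @return Integer vector of 4 bits (upstream, TATA, Pol II, downstream), or
#'   `NULL` if any bin has no call.
#' @export
vectorize_read <- function(calls, layout = bin_layout("mouse")) {
  stopifnot(inherits(layout, "bin_layout"),
            all(c("rel_pos", "methylated") %in% names(calls)))
  if (!all(calls$methylated %in% c(0, 1)))
    stop("methylated must be 0/1", call. = FALSE)
  bin <- assign_bin(calls$rel_pos, layout)
  keep <- !is.na(bin)
  if (length(unique(bin[keep])) < 4L) return(NULL)
  means <- tapply(calls$methylated[keep], bin[keep], mean)
  as.integer(means[as.character(1:4)] >= 0.5)
}

#' Map a bin vector to its promoter state
#'
#' @param bits Integer vector of 4 bits, or a 4-character pattern string.
#' @param mapping A complete 16-pattern state mapping
#'   (default [default_state_mapping()]).
#' @return The state label.
#' @export
classify_read <- function(bits, mapping = default_state_mapping()) {
  mapping <- validate_state_mapping(mapping)
  pattern <- if (is.character(bits)) bits else paste(as.integer(bits),
                                                     collapse = "")
  if (!grepl("^[01]{4}$", pattern))
    stop("bits must encode a 4-bit 0/1 pattern", call. = FALSE)
  mapping$state[match(pattern, mapping$pattern)]
}

#' Classify every molecule in a methylation-call table
#'
#' Vectorised classification of a long per-call table (one row per read and
#' cytosine).  Reads covering at least one call in each of the four bins are
#' summarised with [vectorize_read()] semantics and mapped to states; the
#' rest are rejected.
#'
#' @param reads Data frame with columns `read_id`, `tss_id`, `replicate_id`,
#'   `rel_pos`, `methylated`.
#' @param layout A [bin_layout()].
#' @param mapping A state mapping (validated against all 16 patterns).
#' @return Data frame with one row per classified read: `read_id`, `tss_id`,
#'   `replicate_id`, `pattern`, `state`; the number of rejected reads is
#'   attached as `attr(, "n_rejected")`.
#' @export
classify_molecules <- function(reads, layout = bin_layout("mouse"),
                               mapping = default_state_mapping()) {
  mapping <- validate_state_mapping(mapping)
  req <- c("read_id", "tss_id", "replicate_id", "rel_pos", "methylated")
  if (!all(req %in% names(reads)))
    stop("reads must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (!all(reads$methylated %in% c(0, 1)))
    stop("methylated must be 0/1", call. = FALSE)
  dt <- data.table::as.data.table(reads[req])
  dt[, bin := assign_bin(rel_pos, layout)]
  n_reads_total <- data.table::uniqueN(dt, by = c("tss_id", "read_id",
                                                  "replicate_id"))
  dt <- dt[!is.na(bin)]
  bm <- dt[, list(m = mean(methylated)),
           by = c("tss_id", "read_id", "replicate_id", "bin")]
  wide <- data.table::dcast(bm, tss_id + read_id + replicate_id ~ bin,
                            value.var = "m")
  for (b in as.character(1:4)) if (!b %in% names(wide)) wide[, (b) := NA_real_]
  cc <- stats::complete.cases(wide[, as.character(1:4), with = FALSE])
  wide <- wide[cc]
  bits <- lapply(as.character(1:4), function(b)
    as.integer(wide[[b]] >= 0.5))
  wide[, pattern := paste0(bits[[1]], bits[[2]], bits[[3]], bits[[4]])]
  wide[, state := mapping$state[match(pattern, mapping$pattern)]]
  out <- as.data.frame(wide[, c("read_id", "tss_id", "replicate_id",
                                "pattern", "state"), with = FALSE])
  attr(out, "n_rejected") <- n_reads_total - nrow(out)
  out
}

state_table_from_counts <- function(tss_id, counts, replicate_id = NA_character_) {
  n <- sum(counts)
  freqs <- counts / n
  tab <- data.frame(tss_id = tss_id, replicate_id = replicate_id,
                    n_reads = n, stringsAsFactors = FALSE)
  for (s in promoter_states()) tab[[state_freq_cols[[s]]]] <- freqs[[s]]
  tab$pol2_binding <- tab$f_pol2 + tab$f_pic_pol2
  tab$pic_binding <- tab$f_pic + tab$f_pic_pol2
  tab
}

#' Per-promoter state frequencies
#'
#' Counts classified molecules per state for each promoter (and replicate)
#' and converts them to frequencies.  Promoters with fewer than `min_reads`
#' classified molecules in a replicate are dropped (the whole-genome /
#' bait-capture analyses use 20; targeted amplicon data uses 100).  Derived
#' binding frequencies combine Pol II-bearing states
#' (`pol2_binding = f(PolII) + f(PIC+PolII)`) and PIC-bearing states
#' (`pic_binding = f(PIC) + f(PIC+PolII)`).
#'
#' @param classified Output of [classify_molecules()] (or a data frame with
#'   `tss_id`, `replicate_id`, `state`).
#' @param min_reads Minimum number of classified reads per promoter and
#'   replicate.
#' @return Data frame with one row per retained promoter x replicate:
#'   `tss_id`, `replicate_id`, `n_reads`, the six frequency columns
#'   (`f_pol2`, `f_pic_pol2`, `f_pic`, `f_unbound`, `f_nucleosome`,
#'   `f_unassigned`), `pol2_binding`, `pic_binding`.  Rejected promoters are
#'   listed in `attr(, "rejected")`.
#' @export
state_frequencies <- function(classified, min_reads = 20) {
  stopifnot(min_reads >= 1)
  req <- c("tss_id", "replicate_id", "state")
  if (!all(req %in% names(classified)))
    stop("classified must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(classified[req])
  grp <- dt[, list(n = .N), by = c("tss_id", "replicate_id", "state")]
  totals <- grp[, list(n_reads = sum(n)), by = c("tss_id", "replicate_id")]
  keep <- totals[n_reads >= min_reads]
  rejected <- totals[n_reads < min_reads]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    g <- grp[tss_id == keep$tss_id[i] & replicate_id == keep$replicate_id[i]]
    counts <- stats::setNames(rep(0, 6), promoter_states())
    counts[g$state] <- g$n
    state_table_from_counts(keep$tss_id[i], counts, keep$replicate_id[i])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    state_table_from_counts("x", stats::setNames(rep(1, 6),
                                                 promoter_states()))[0, ]
  rownames(out) <- NULL
  attr(out, "rejected") <- as.data.frame(rejected)
  out
}

#' Average promoter state frequencies across replicates
#'
#' Unweighted mean of the per-replicate state frequencies for each promoter;
#' `n_reads` is summed and the derived binding frequencies are recomputed
#' from the averaged frequencies.
#'
#' @param tables A state-frequency table (rows spanning replicates), as from
#'   [state_frequencies()].
#' @return One row per `tss_id`, with `replicate_id` dropped.
#' @export
average_replicates <- function(tables) {
  fcols <- unname(state_freq_cols)
  if (!all(c("tss_id", "n_reads", fcols) %in% names(tables)))
    stop("tables must be a promoter state table", call. = FALSE)
  dt <- data.table::as.data.table(tables)
  out <- dt[, c(list(n_reads = sum(n_reads)),
                lapply(.SD, mean)), by = "tss_id", .SDcols = fcols]
  out <- as.data.frame(out)
  out$pol2_binding <- out$f_pol2 + out$f_pic_pol2
  out$pic_binding <- out$f_pic + out$f_pic_pol2
  out
}

#' Per-cytosine footprint profile from single-molecule reads
#'
#' The footprint frequency at a cytosine is `1 - mean(methylated)` over the
#' reads covering it (protection = unmethylated).  A centred running mean
#' over `smooth_bp` base pairs (computed across the observed cytosines,
#' truncated at the edges) is returned alongside.
#'
#' @param reads Long per-call data frame (`rel_pos`, `methylated`).
#' @param range Closed TSS-relative window to profile.
#' @param smooth_bp Width of the running-mean window in bp.
#' @return Data frame `rel_pos`, `n`, `footprint`, `smoothed`.
#' @export
smf_profile <- function(reads, range = c(-250L, 250L), smooth_bp = 20L) {
  stopifnot(all(c("rel_pos", "methylated") %in% names(reads)))
  dt <- data.table::as.data.table(reads[, c("rel_pos", "methylated")])
  dt <- dt[rel_pos >= range[1] & rel_pos <= range[2]]
  prof <- dt[, list(n = .N, footprint = 1 - mean(methylated)), by = "rel_pos"]
  data.table::setorder(prof, rel_pos)
  prof <- as.data.frame(prof)
  half_lo <- floor((smooth_bp - 1) / 2)
  half_hi <- ceiling((smooth_bp - 1) / 2)
  prof$smoothed <- vapply(seq_len(nrow(prof)), function(i) {
    w <- prof$rel_pos >= prof$rel_pos[i] - half_lo &
      prof$rel_pos <= prof$rel_pos[i] + half_hi
    mean(prof$footprint[w])
  }, numeric(1))
  prof
}

#' Read / write the long methylation-call TSV
#'
#' Columns `read_id`, `tss_id`, `replicate_id`, `rel_pos`, `methylated`
#' (plus an optional `conversion_rate`).  When `min_conversion` is given and
#' the column is present, reads below the threshold are dropped (bisulfite
#' conversion QC; the upstream caller normally enforces this).
#'
#' @param path File path.
#' @param min_conversion Optional minimum per-read conversion rate.
#' @return Data frame of calls.
#' @export
read_methylation_tsv <- function(path, min_conversion = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("read_id", "tss_id", "replicate_id", "rel_pos", "methylated")
  if (!all(req %in% names(x)))
    stop("methylation TSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!is.null(min_conversion) && "conversion_rate" %in% names(x))
    x <- x[x$conversion_rate >= min_conversion, ]
  x
}

#' @rdname read_methylation_tsv
#' @param reads Call table to write.
#' @export
write_methylation_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
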