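#' Read TSSs or CAGE peaks from a BED6 file
#'
#' BED is 0-based half-open; the imported single-base anchor is the 5' end
#' of the feature on its own strand (start for `+`, end for `-`), reported
#' in 1-based coordinates.
#'
#' @param path BED6 file.
#' @return For TSSs: data frame `chrom`, `pos`, `strand`, `tss_id`,
#'   `gene_id` (gene id duplicates the name column); for CAGE peaks:
#'   `chrom`, `pos`, `strand`, `score`.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("invalid strand in ", path, ": must be + or -", call. = FALSE)
  pos <- ifelse(strand == "+", GenomicRanges::start(gr),
                GenomicRanges::end(gr))
  nm <- if (!is.null(gr$name)) gr$name else paste0("tss_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)), pos = pos,
             strand = strand, tss_id = nm, gene_id = nm,
             stringsAsFactors = FALSE)
}

#' @rdname read_tss_bed
#' @export
read_cage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("invalid strand in ", path, ": must be + or -", call. = FALSE)
  pos <- ifelse(strand == "+", GenomicRanges::start(gr),
                GenomicRanges::end(gr))
  score <- if (!is.null(gr$score)) as.numeric(gr$score) else
    rep(0, length(gr))
  if (any(score < 0)) stop("CAGE scores must be non-negative", call. = FALSE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)), pos = pos,
             strand = strand, score = score, stringsAsFactors = FALSE)
}

validate_tss <- function(tss) {
  req <- c("chrom", "pos", "strand", "tss_id")
  if (!all(req %in% names(tss)))
    stop("TSS table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(!tss$strand %in% c("+", "-")))
    stop("invalid strand value: must be + or -", call. = FALSE)
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0", call. = FALSE)
  tss
}

#' Refine TSS positions against CAGE peaks
#'
#' Each TSS is shifted to the position of the strongest same-strand CAGE
#' peak within `max_dist` bp; TSSs with no eligible peak keep their original
#' position.  Score ties are broken by distance to the original TSS, then by
#' the most 5' position on the gene strand.  Exact duplicate
#' `(chrom, pos, strand)` records after refinement are removed, keeping the
#' first in input order.
#'
#' @param tss Data frame of TSS records (see [read_tss_bed()]).
#' @param cage Data frame of CAGE peaks (`chrom`, `pos`, `strand`, `score`).
#' @param max_dist Maximum shift in bp (default 50).
#' @return The refined, de-duplicated TSS data frame.
#' @export
refine_tss <- function(tss, cage, max_dist = 50) {
  tss <- validate_tss(tss)
  stopifnot(max_dist >= 0)
  if (nrow(cage) > 0 && any(!cage$strand %in% c("+", "-")))
    stop("invalid strand value: must be + or -", call. = FALSE)
  if (nrow(cage) > 0 && any(cage$score < 0))
    stop("CAGE scores must be non-negative", call. = FALSE)
  new_pos <- tss$pos
  if (nrow(cage) > 0 && nrow(tss) > 0) {
    tss_gr <- GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(tss$pos - max_dist, tss$pos + max_dist),
      strand = tss$strand)
    cage_gr <- GenomicRanges::GRanges(
      cage$chrom, IRanges::IRanges(cage$pos, cage$pos),
      strand = cage$strand)
    ov <- GenomicRanges::findOverlaps(tss_gr, cage_gr, ignore.strand = FALSE)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (i in unique(qh)) {
        cand <- sh[qh == i]
        sc <- cage$score[cand]
        cand <- cand[sc == max(sc)]
        if (length(cand) > 1) {                      # tie: closest
          d <- abs(cage$pos[cand] - tss$pos[i])
          cand <- cand[d == min(d)]
        }
        if (length(cand) > 1) {                      # tie: most 5'
          cand <- if (tss$strand[i] == "+") cand[which.min(cage$pos[cand])]
          else cand[which.max(cage$pos[cand])]
        }
        new_pos[i] <- cage$pos[cand]
      }
    }
  }
  tss$pos <- new_pos
  dup <- duplicated(tss[, c("chrom", "pos", "strand")])
  tss[!dup, , drop = FALSE]
}

#' TATA-box detection in the core promoter
#'
#' Scans a gene-strand promoter sequence for the TATA-box consensus
#' `TATAWAWR` (IUPAC: W = A/T, R = A/G) starting at a TSS-relative position
#' within `window` (default `[-37, -18]`, the canonical TATA location +/- 5
#' bp).
#'
#' @param promoter_seq Character string or [Biostrings::DNAString] oriented
#'   5'->3' on the gene strand (alphabet ACGTN).
#' @param tss_offset 1-based index of the TSS base within `promoter_seq`.
#' @param window Closed TSS-relative interval of allowed motif start
#'   positions.
#' @return `TRUE` if a TATAWAWR match starts within the window.
#' @export
#' @examples
#' s <- paste0(strrep("C", 30), "TATAAAAG", strrep("C", 62))
#' detect_tata(s, tss_offset = 61)   # motif starts at relative -30
detect_tata <- function(promoter_seq, tss_offset, window = c(-37L, -18L)) {
  s <- toupper(as.character(promoter_seq))
  if (grepl("[^ACGTN]", s))
    stop("promoter sequence must use the ACGTN alphabet", call. = FALSE)
  lo <- tss_offset + window[1]
  hi <- tss_offset + window[2] + 7L    # last base of an 8-mer at window end
  if (lo < 1 || hi > nchar(s))
    stop("promoter sequence too short to cover the TATA search window ",
         "[", window[1], ", ", window[2] + 7L, "] around the TSS",
         call. = FALSE)
  sub <- substr(s, lo, hi)
  grepl("TATA[AT]A[AT][AG]", sub)
}

#' TATA annotation for a set of promoter sequences
#'
#' @param seqs A named [Biostrings::DNAStringSet] (names = `tss_id`) or a
#'   named character vector of gene-strand promoter sequences.
#' @param tss_offset 1-based TSS index, a single value or one per sequence.
#' @param window As in [detect_tata()].
#' @return Named logical vector.
#' @export
detect_tata_set <- function(seqs, tss_offset, window = c(-37L, -18L)) {
  ss <- as.character(seqs)
  off <- rep_len(tss_offset, length(ss))
  out <- vapply(seq_along(ss), function(i)
    detect_tata(ss[i], off[i], window), logical(1))
  names(out) <- names(ss)
  out
}

#' Read promoter sequences with TSS offsets from FASTA
#'
#' Sequence IDs must equal the `tss_id`; an `offset=<int>` token in the
#' header declares the 1-based TSS position within the sequence (default
#' applies when absent).
#'
#' @param path FASTA file.
#' @param default_offset Offset used when the header carries none.
#' @return List with `seqs` (a [Biostrings::DNAStringSet] named by tss_id)
#'   and `offsets` (named integer vector).
#' @export
read_promoter_fasta <- function(path, default_offset = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  off <- suppressWarnings(as.integer(sub(".*offset=(\\d+).*", "\\1",
                                         headers)))
  off[grepl("offset=", headers) == FALSE] <- NA_integer_
  if (anyNA(off)) {
    if (is.null(default_offset))
      stop("FASTA headers lack offset= and no default_offset given",
           call. = FALSE)
    off[is.na(off)] <- as.integer(default_offset)
  }
  names(ss) <- ids
  names(off) <- ids
  list(seqs = ss, offsets = off)
}

#' Strand-aware window counting around a TSS
#'
#' Positions are first shifted `shift` bp downstream along each read's own
#' strand (`+ shift` on `+`, `- shift` on `-`), then mapped to the
#' TSS-relative axis of the gene (mirrored for minus-strand genes) and
#' summed over the closed `window`.  `strand_mode` selects reads on the gene
#' strand (`"same"`), the opposite strand (`"opposite"`, the PRO-seq
#' convention since the nascent RNA is sequenced from the 3' end) or both.
#'
#' @param signal Data frame `pos`, `strand`, and optional `weight`
#'   (default 1 per row).
#' @param tss A single TSS record (1-row data frame or list with `pos`,
#'   `strand`).
#' @param window Closed TSS-relative interval `c(start, end)`.
#' @param shift Downstream shift in bp applied along each read's strand.
#' @param strand_mode `"same"`, `"opposite"` or `"both"`.
#' @return Summed weight of shifted positions inside the window.
#' @export
count_in_window <- function(signal, tss, window, shift = 0,
                            strand_mode = c("same", "opposite", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (nrow(signal) == 0) return(0)
  if (!all(signal$strand %in% c("+", "-")))
    stop("invalid strand value: must be + or -", call. = FALSE)
  w <- if ("weight" %in% names(signal)) signal$weight else
    rep(1, nrow(signal))
  keep <- switch(strand_mode,
                 same = signal$strand == tss$strand,
                 opposite = signal$strand != tss$strand,
                 both = rep(TRUE, nrow(signal)))
  if (!any(keep)) return(0)
  pos <- signal$pos[keep] +
    ifelse(signal$strand[keep] == "+", shift, -shift)
  rel <- if (tss$strand == "+") pos - tss$pos else tss$pos - pos
  sum(w[keep][rel >= window[1] & rel <= window[2]])
}

#' Per-TSS window counts for a cohort
#'
#' @inheritParams count_in_window
#' @param tss_table Data frame of TSS records.
#' @return Data frame `tss_id`, `count`.
#' @export
count_table <- function(signal, tss_table, window, shift = 0,
                        strand_mode = "same") {
  tss_table <- validate_tss(tss_table)
  counts <- vapply(seq_len(nrow(tss_table)), function(i) {
    sig <- signal[signal$chrom == tss_table$chrom[i], , drop = FALSE]
    count_in_window(sig, tss_table[i, ], window, shift, strand_mode)
  }, numeric(1))
  data.frame(tss_id = tss_table$tss_id, count = counts,
             stringsAsFactors = FALSE)
}

#' Promoter activity rank from a per-TSS count table
#'
#' Percentile rank (average ties, scaled to `[0, 1]`) of e.g. Pol II ChIP
#' counts in a promoter window; 1 = most active, so the "top 5%" are
#' `activity_rank >= 0.95`.
#'
#' @param counts Numeric vector of per-TSS counts.
#' @return Ranks in `[0, 1]`.
#' @export
activity_rank <- function(counts) {
  n <- length(counts)
  if (n == 1L) return(1)
  (rank(counts, ties.method = "average") - 1) / (n - 1)
}

#' Composite signal profile across promoters
#'
#' Mean across promoters per relative position, then a centred running mean
#' of width `smooth_bp` (truncated at the edges), optionally standardised to
#' a Z-score across positions (mean 0, sd 1) so profiles from different
#' assays or species can share an axis.
#'
#' @param values Promoters x positions matrix of per-position signal; all
#'   rows share the same relative coordinate columns.
#' @param smooth_bp Running-mean width in positions.
#' @param zscore Standardise the smoothed profile?
#' @return Numeric vector, one value per position (names preserved).
#' @export
composite_profile <- function(values, smooth_bp = 20L, zscore = FALSE) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  prof <- colMeans(values)
  n <- length(prof)
  half_lo <- floor((smooth_bp - 1) / 2)
  half_hi <- ceiling((smooth_bp - 1) / 2)
  cs <- cumsum(c(0, prof))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  names(sm) <- colnames(values)
  if (zscore) {
    s <- stats::sd(sm)
    if (!is.finite(s) || s <= 1e-12 * max(1, abs(mean(sm))))
      stop("constant profile: Z-score undefined (zero variance)",
           call. = FALSE)
    sm <- (sm - mean(sm)) / s
  }
  sm
}

#' Expand bedGraph intervals to per-base signal positions
#'
#' bedGraph is 0-based half-open; each interval is expanded to 1-based
#' per-base positions with the interval's value as weight, tagged with the
#' given strand (the format is unstranded, so one file per strand is
#' expected).
#'
#' @param path bedGraph file.
#' @param strand `"+"` or `"-"` for all records in the file.
#' @return Data frame `chrom`, `pos`, `strand`, `weight`.
#' @export
read_bedgraph_signal <- function(path, strand) {
  stopifnot(strand %in% c("+", "-"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  pos <- unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
  reps <- GenomicRanges::width(gr)
  data.frame(chrom = rep(as.character(GenomicRanges::seqnames(gr)), reps),
             pos = pos, strand = strand,
             weight = rep(gr$score, reps), stringsAsFactors = FALSE)
}
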