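tss1 <- data.frame(chrom = "chr1", pos = 1000L, strand = "+",
                   tss_id = "t1", gene_id = "g1")

test_that("TSSs move to the strongest same-strand CAGE peak within range", {
  cage <- data.frame(chrom = "chr1", pos = c(1040L, 990L),
                     strand = "+", score = c(5, 9))
  out <- refine_tss(tss1, cage)
  expect_equal(out$pos, 990L)
  # nothing eligible -> original position retained
  out <- refine_tss(tss1, cage[cage$score > 100, ])
  expect_equal(out$pos, 1000L)
  # opposite-strand peak is ignored
  cage_minus <- data.frame(chrom = "chr1", pos = 995L, strand = "-",
                           score = 50)
  expect_equal(refine_tss(tss1, cage_minus)$pos, 1000L)
  # out-of-range strong peak is ignored
  cage_far <- data.frame(chrom = "chr1", pos = 1060L, strand = "+",
                         score = 50)
  expect_equal(refine_tss(tss1, cage_far)$pos, 1000L)
})

test_that("CAGE score ties break by distance then 5' position", {
  cage <- data.frame(chrom = "chr1", pos = c(960L, 1010L), strand = "+",
                     score = c(7, 7))
  expect_equal(refine_tss(tss1, cage)$pos, 1010L)   # closer wins
  cage_eq <- data.frame(chrom = "chr1", pos = c(990L, 1010L), strand = "+",
                        score = c(7, 7))
  expect_equal(refine_tss(tss1, cage_eq)$pos, 990L) # equidistant: most 5'
  tss_m <- transform(tss1, strand = "-")
  cage_m <- data.frame(chrom = "chr1", pos = c(990L, 1010L), strand = "-",
                       score = c(7, 7))
  expect_equal(refine_tss(tss_m, cage_m)$pos, 1010L) # most 5' on minus
})

test_that("refinement removes duplicates and is idempotent", {
  tss2 <- rbind(tss1, transform(tss1, pos = 1020L, tss_id = "t2"))
  cage <- data.frame(chrom = "chr1", pos = 1010L, strand = "+", score = 3)
  out <- refine_tss(tss2, cage)
  expect_equal(nrow(out), 1L)
  expect_equal(out$tss_id, "t1")     # first record in input order kept
  expect_equal(refine_tss(out, cage), out)
  expect_error(refine_tss(transform(tss1, strand = "*"), cage), "strand")
})

test_that("TATA detection enforces the motif and its positional window", {
  mk <- function(motif_at) {
    # TSS at index 61; motif_at is the TSS-relative start of TATAAAAG
    s <- strsplit(strrep("C", 120), "")[[1]]
    idx <- 61 + motif_at
    s[idx:(idx + 7)] <- strsplit("TATAAAAG", "")[[1]]
    paste(s, collapse = "")
  }
  expect_true(detect_tata(mk(-30), tss_offset = 61))
  expect_false(detect_tata(mk(-40), tss_offset = 61))
  expect_false(detect_tata(mk(-10), tss_offset = 61))
  expect_false(detect_tata(strrep("C", 120), tss_offset = 61))
  # W and R degeneracy: TATATATA fits TATAWAWR
  s <- mk(-30); substr(s, 31, 38) <- "TATATATA"
  expect_true(detect_tata(s, tss_offset = 61))
  # non-degenerate violation: TATACAAG has C at the W slot
  s2 <- mk(-30); substr(s2, 31, 38) <- "TATACAAG"
  expect_false(detect_tata(s2, tss_offset = 61))
  expect_error(detect_tata("TATAAAAG", tss_offset = 4), "too short")
})

test_that("TATA call ignores sequence content outside the search region", {
  set.seed(8)
  base <- strsplit(strrep("C", 150), "")[[1]]
  base[41:48] <- strsplit("TATAAAAG", "")[[1]]   # starts at -30 for TSS at 71
  s1 <- paste(base, collapse = "")
  scr <- base
  outside <- c(1:33, 61:150)                      # outside [-37, -11] + TSS 71
  scr[outside] <- sample(c("A", "C", "G", "T"), length(outside),
                         replace = TRUE)
  s2 <- paste(scr, collapse = "")
  expect_equal(detect_tata(s1, 71), detect_tata(s2, 71))
  expect_true(detect_tata(s2, 71))
})

test_that("window counting shifts along the read strand and mirrors minus genes", {
  tss <- list(pos = 1000L, strand = "+")
  sig <- data.frame(pos = 925L, strand = "+")
  expect_equal(count_in_window(sig, tss, c(-200, 100), shift = 75), 1)
  expect_equal(count_in_window(sig, tss, c(1, 100), shift = 75), 0)
  # PRO-seq convention: gene-strand reads contribute nothing
  expect_equal(count_in_window(sig, tss, c(-200, 100), shift = 75,
                               strand_mode = "opposite"), 0)
  sig_m <- data.frame(pos = 1010L, strand = "-")
  tss_m <- list(pos = 1000L, strand = "-")
  expect_equal(count_in_window(sig_m, tss_m, c(-100, 200)), 1)  # rel -10
  expect_equal(count_in_window(sig_m, tss_m, c(-5, 200)), 0)
  # minus-strand shift moves the position to lower coordinates
  expect_equal(count_in_window(sig_m, tss_m, c(-5, 200), shift = 20), 1)
  expect_equal(count_in_window(sig[0, ], tss, c(-100, 100)), 0)
})

test_that("window counts are additive over disjoint windows", {
  set.seed(3)
  sig <- data.frame(pos = sample(900:1100, 200, replace = TRUE),
                    strand = sample(c("+", "-"), 200, replace = TRUE))
  tss <- list(pos = 1000L, strand = "+")
  whole <- count_in_window(sig, tss, c(-150, 150), strand_mode = "both")
  left <- count_in_window(sig, tss, c(-150, 0), strand_mode = "both")
  right <- count_in_window(sig, tss, c(1, 150), strand_mode = "both")
  expect_equal(left + right, whole)
  expect_equal(count_in_window(sig, tss, c(-1e6, 1e6), strand_mode = "both"),
               nrow(sig))
})

test_that("activity rank puts the top 5% at >= 0.95", {
  counts <- seq_len(100)
  rk <- activity_rank(counts)
  expect_equal(sum(rk >= 0.95), 5L)
  expect_equal(rk[100], 1)
})

test_that("composite profile preserves constants and standardises", {
  m <- matrix(4.2, nrow = 3, ncol = 21)
  expect_equal(unname(composite_profile(m, smooth_bp = 20)), rep(4.2, 21))
  v <- c(0, 0, 10, 0, 0)
  expect_equal(unname(composite_profile(v, smooth_bp = 1)), v)
  set.seed(2)
  prof <- composite_profile(matrix(rnorm(500), 5, 100), smooth_bp = 20,
                            zscore = TRUE)
  expect_lt(abs(mean(prof)), 1e-12)
  expect_lt(abs(sd(prof) - 1), 1e-12)
  expect_error(composite_profile(m, zscore = TRUE), "constant")
})

test_that("BED6 import anchors the 5' end per strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1000\ttA\t0\t+",
               "chr1\t2000\t2050\ttB\t0\t-"), bed)
  tss <- read_tss_bed(bed)
  expect_equal(tss$pos, c(1000L, 2050L))
  expect_equal(tss$tss_id, c("tA", "tB"))
  cage <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t989\t990\tp1\t9\t+",
               "chr1\t1039\t1040\tp2\t5\t+"), cage)
  peaks <- read_cage_bed(cage)
  expect_equal(peaks$pos, c(990L, 1040L))
  expect_equal(peaks$score, c(9, 5))
  out <- refine_tss(tss, peaks)
  expect_equal(out$pos[out$tss_id == "tA"], 990L)
})

test_that("bedGraph intervals expand to per-base weighted positions", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t3\t2.5", "chr1\t10\t11\t7"), bg)
  sig <- read_bedgraph_signal(bg, strand = "+")
  expect_equal(sig$pos, c(1L, 2L, 3L, 11L))
  expect_equal(sig$weight, c(2.5, 2.5, 2.5, 7))
  tss <- list(pos = 1L, strand = "+")
  expect_equal(count_in_window(sig, tss, c(0, 2)), 7.5)
})

test_that("promoter FASTA reader extracts ids and offsets", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 offset=61", paste0(strrep("C", 30), "TATAAAAG",
                                       strrep("C", 82)),
               ">p2 offset=61", strrep("G", 120)), fa)
  pf <- read_promoter_fasta(fa)
  expect_equal(names(pf$seqs), c("p1", "p2"))
  expect_equal(unname(pf$offsets), c(61L, 61L))
  tata <- detect_tata_set(pf$seqs, pf$offsets)
  expect_equal(unname(tata), c(TRUE, FALSE))
})
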