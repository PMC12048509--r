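#' Assemble a nascent-transcription time course
#'
#' Per-TSS counts (e.g. PRO-seq reads in a `[-100, 200]` promoter window)
#' for a set of samples taken at several times after blocking transcription
#' initiation, together with the per-sample spike-in totals used for
#' inter-sample normalisation.
#'
#' @param counts Numeric matrix, rows = `tss_id`, columns = `sample_id`.
#' @param samples Data frame with columns `sample_id`, `timepoint_min`,
#'   `replicate_id`, `spikein_total`.
#' @return An object of class `time_course`.
#' @export
time_course <- function(counts, samples) {
  req <- c("sample_id", "timepoint_min", "replicate_id", "spikein_total")
  if (!all(req %in% names(samples)))
    stop("samples must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have tss_id rownames and sample_id colnames",
         call. = FALSE)
  if (!setequal(colnames(counts), samples$sample_id))
    stop("counts columns and sample sheet do not match", call. = FALSE)
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (any(is.na(samples$spikein_total)) || any(samples$spikein_total <= 0))
    stop("every sample needs a positive spikein_total", call. = FALSE)
  if (!0 %in% samples$timepoint_min)
    stop("timepoint 0 (the untreated reference) must be present",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, samples = samples), class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time course: %d TSSs x %d samples; timepoints {%s} min\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$timepoint_min)), collapse = ", ")))
  invisible(x)
}

#' Spike-in normalisation and replicate averaging
#'
#' Each sample's counts are divided by its spike-in total (times a global
#' scale, by default the mean spike-in total, which keeps values on a
#' count-like scale without affecting any downstream ratio).  Replicates at
#' the same timepoint are then averaged; timepoints with a single surviving
#' replicate pass through unchanged.
#'
#' @param tc A [time_course()].
#' @param scale Global scale factor (default `mean(spikein_total)`).
#' @return List of class `norm_time_course` with `norm` (tss x timepoint
#'   matrix, columns ordered by time) and `timepoints` (minutes).
#' @export
spikein_normalize <- function(tc, scale = NULL) {
  stopifnot(inherits(tc, "time_course"))
  s <- tc$samples
  if (is.null(scale)) scale <- mean(s$spikein_total)
  normed <- sweep(tc$counts, 2, s$spikein_total / scale, "/")
  tps <- sort(unique(s$timepoint_min))
  norm <- matrix(0, nrow(normed), length(tps),
                 dimnames = list(rownames(normed), as.character(tps)))
  for (j in seq_along(tps)) {
    cols <- s$sample_id[s$timepoint_min == tps[j]]
    norm[, j] <- rowMeans(normed[, cols, drop = FALSE])
  }
  structure(list(norm = norm, timepoints = tps), class = "norm_time_course")
}

#' Fold changes relative to the untreated reference
#'
#' `FC(g, t) = norm(g, t) / norm(g, 0)`; the reference column is identically
#' 1.  Promoters with a zero baseline have no defined fold change and are
#' dropped (their ids are kept in `attr(, "dropped")`).
#'
#' @param ntc A `norm_time_course` from [spikein_normalize()].
#' @return tss x timepoint matrix of fold changes.
#' @export
fold_changes <- function(ntc) {
  stopifnot(inherits(ntc, "norm_time_course"))
  base <- ntc$norm[, "0"]
  drop <- base <= 0
  if (any(drop))
    message(sum(drop), " promoter(s) dropped: zero baseline at t = 0")
  fc <- sweep(ntc$norm[!drop, , drop = FALSE], 1, base[!drop], "/")
  attr(fc, "timepoints") <- ntc$timepoints
  attr(fc, "dropped") <- rownames(ntc$norm)[drop]
  fc
}

#' Cluster promoters by their decay fold-change profiles
#'
#' k-means (squared Euclidean, Lloyd's algorithm with 25 restarts under a
#' fixed seed) on the linear fold-change vectors over the post-treatment
#' timepoints.  Cluster labels are renumbered in order of increasing fitted
#' turnover rate (an exponential fit to each centroid, anchored at
#' `FC(0) = 1`), so cluster 1 is always the slowest-decaying group.
#'
#' @param fc Fold-change matrix from [fold_changes()].
#' @param k Number of clusters (default 4).
#' @param seed Integer seed for the restarts.
#' @return List of class `cluster_result`: `k`, `assignment` (named integer
#'   vector by tss_id), `centroids` (k x timepoint matrix including t = 0),
#'   `centroid_kt` (fitted rate per cluster, min^-1).
#' @export
cluster_decay <- function(fc, k = 4, seed = 1) {
  tps <- attr(fc, "timepoints")
  if (is.null(tps)) tps <- as.numeric(colnames(fc))
  if (nrow(fc) < k)
    stop("fewer promoters (", nrow(fc), ") than clusters (", k, ")",
         call. = FALSE)
  post <- fc[, tps > 0, drop = FALSE]
  set.seed(as.integer(seed))
  km <- stats::kmeans(post, centers = k, nstart = 25, iter.max = 100)
  # order clusters by the decay rate of their centroid (FC starts at 1)
  cent_kt <- vapply(seq_len(k), function(j) {
    fit_decay(c(1, km$centers[j, ]), c(0, tps[tps > 0]))$kt_hat
  }, numeric(1))
  ord <- order(cent_kt)
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[km$cluster]
  names(assignment) <- rownames(fc)
  centroids <- cbind(`0` = 1, km$centers)[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  colnames(centroids) <- as.character(c(0, tps[tps > 0]))
  structure(list(k = k, assignment = assignment, centroids = centroids,
                 centroid_kt = cent_kt[ord]), class = "cluster_result")
}

decay_profile_loglik <- function(kt, y, t) {
  # profile log-likelihood in kt; A has closed form sum(y)/sum(exp(-kt t))
  S <- sum(exp(-kt * t))
  Y <- sum(y)
  Y * log(Y / S) - kt * sum(y * t) - Y
}

decay_full_negloglik <- function(par, y, t) {
  mu <- exp(par[1]) * exp(-exp(par[2]) * t)   # par = (log A, log kt)
  -sum(y * log(mu) - mu)
}

#' Fit an exponential decay by Poisson maximum likelihood
#'
#' Fits `mu_t = A exp(-kt t)` to per-timepoint counts by maximising the
#' Poisson-type log-likelihood `sum(y_t log mu_t - mu_t)` (valid for the
#' non-integer spike-in-normalised counts as a quasi-likelihood; for integer
#' counts the maximiser coincides with the full Poisson MLE since the `y!`
#' term is parameter-free).  The amplitude has a closed form given `kt`, so
#' the rate is found on its one-dimensional profile likelihood; the score at
#' `kt = 0` detects boundary (non-decaying) data analytically.  The 95%
#' Wald interval for `kt` comes from the numerical observed information in
#' `(log A, log kt)`, mapped back with the delta method.
#'
#' @param counts Non-negative counts, one per timepoint (a cluster aggregate
#'   or a single promoter).
#' @param timepoints Times in minutes (>= 3 distinct values).
#' @return Object of class `decay_fit`: `kt_hat` (min^-1), `amplitude_hat`,
#'   `ci95` (`c(lo, hi)`), `half_life` (`log(2)/kt_hat`, minutes),
#'   `loglik`, `boundary` (TRUE when the MLE sits at `kt = 0`).
#' @export
#' @examples
#' t <- c(0, 2.5, 5, 10, 20)
#' fit_decay(1000 * exp(-0.2 * t), t)
fit_decay <- function(counts, timepoints) {
  y <- as.numeric(counts); t <- as.numeric(timepoints)
  if (length(y) != length(t))
    stop("counts and timepoints must have equal length", call. = FALSE)
  if (length(unique(t)) < 3)
    stop("need at least 3 distinct timepoints", call. = FALSE)
  if (any(y < 0) || anyNA(y)) stop("counts must be non-negative", call. = FALSE)
  if (sum(y) == 0)
    stop("all counts are zero: decay rate unidentifiable", call. = FALSE)

  Y <- sum(y)
  # score at kt = 0: Y * mean(t) - sum(y t); <= 0 means no evidence of decay
  boundary <- (Y * mean(t) - sum(y * t)) <= 0
  if (boundary) {
    kt_hat <- 0
    A_hat <- Y / length(t)
    ll <- sum(y * log(A_hat)) - length(t) * A_hat
    fit <- list(kt_hat = 0, amplitude_hat = A_hat, ci95 = c(0, Inf),
                se = NA_real_, half_life = Inf, loglik = ll,
                boundary = TRUE)
    class(fit) <- "decay_fit"
    return(fit)
  }
  score <- function(k) {
    w <- exp(-k * t)
    Y * sum(t * w) / sum(w) - sum(y * t)
  }
  upper <- 1
  while (score(upper) > 0 && upper < 1e6) upper <- upper * 2
  if (score(upper) > 0)
    stop("decay-rate optimisation did not converge: score positive at kt = ",
         upper, call. = FALSE)
  kt_hat <- stats::uniroot(score, c(0, upper), tol = 1e-12)$root
  A_hat <- Y / sum(exp(-kt_hat * t))
  ll <- decay_profile_loglik(kt_hat, y, t)

  H <- stats::optimHess(c(log(A_hat), log(kt_hat)), decay_full_negloglik,
                        y = y, t = t)
  se <- tryCatch({
    V <- solve(H)
    sqrt(V[2, 2]) * kt_hat            # delta method from log kt to kt
  }, error = function(e) NA_real_)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    c(max(0, kt_hat - 1.96 * se), kt_hat + 1.96 * se)
  fit <- list(kt_hat = kt_hat, amplitude_hat = A_hat, ci95 = ci, se = se,
              half_life = log(2) / kt_hat, loglik = ll, boundary = FALSE)
  class(fit) <- "decay_fit"
  fit
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit: kt = %.4g min^-1 [%.4g, %.4g], t1/2 = %.3g min%s\n",
    x$kt_hat, x$ci95[1], x$ci95[2], x$half_life,
    if (x$boundary) " (boundary: no decay detected)" else ""))
  invisible(x)
}

#' Per-cluster turnover fits
#'
#' Aggregates the spike-in-normalised counts of each cluster's promoters by
#' summing per timepoint (which preserves the Poisson character of the
#' counts), then fits one exponential decay per cluster.  Per-gene fitting
#' is available via `per_gene = TRUE`.
#'
#' @param ntc A `norm_time_course` from [spikein_normalize()].
#' @param clusters A `cluster_result` from [cluster_decay()].
#' @param per_gene Fit each promoter separately instead of aggregating.
#' @return Data frame with one row per cluster (or promoter): `cluster`
#'   (or `tss_id`), `n_genes`, `kt`, `ci_lo`, `ci_hi`, `half_life_min`,
#'   `boundary`.
#' @export
fit_cluster_decay <- function(ntc, clusters, per_gene = FALSE) {
  stopifnot(inherits(ntc, "norm_time_course"),
            inherits(clusters, "cluster_result"))
  ids <- names(clusters$assignment)
  mat <- ntc$norm[ids, , drop = FALSE]
  if (per_gene) {
    fits <- lapply(ids, function(g) fit_decay(mat[g, ], ntc$timepoints))
    out <- data.frame(tss_id = ids,
                      cluster = unname(clusters$assignment[ids]))
  } else {
    fits <- lapply(seq_len(clusters$k), function(j) {
      members <- ids[clusters$assignment == j]
      fit_decay(colSums(mat[members, , drop = FALSE]), ntc$timepoints)
    })
    out <- data.frame(cluster = seq_len(clusters$k),
                      n_genes = as.vector(table(factor(clusters$assignment,
                                                       seq_len(clusters$k)))))
  }
  out$kt <- vapply(fits, `[[`, numeric(1), "kt_hat")
  out$ci_lo <- vapply(fits, function(f) f$ci95[1], numeric(1))
  out$ci_hi <- vapply(fits, function(f) f$ci95[2], numeric(1))
  out$half_life_min <- vapply(fits, `[[`, numeric(1), "half_life")
  out$boundary <- vapply(fits, `[[`, logical(1), "boundary")
  out
}

#' Pausing index
#'
#' Ratio of Pol II signal at the TSS (window `[-150, 150]`) to the gene body
#' (window `[+300, +600]`).  Genes shorter than `min_length` bp (600 by
#' default, so the body window exists) are excluded, as are genes with a
#' zero body count (non-finite index).  Vectorised.
#'
#' @param tss_count Counts in the TSS window.
#' @param body_count Counts in the gene-body window.
#' @param gene_length Gene length in bp.
#' @param min_length Minimum gene length (bp).
#' @return Data frame `pausing_index` (`NA` where excluded) and
#'   `exclude_reason` (`NA`, `"length"` or `"non-finite"`).
#' @export
pausing_index <- function(tss_count, body_count, gene_length,
                          min_length = 600) {
  n <- length(tss_count)
  stopifnot(length(body_count) == n, length(gene_length) == n)
  if (any(tss_count < 0) || any(body_count < 0))
    stop("counts must be non-negative", call. = FALSE)
  reason <- rep(NA_character_, n)
  reason[gene_length < min_length] <- "length"
  reason[is.na(reason) & body_count == 0] <- "non-finite"
  pi <- ifelse(is.na(reason), tss_count / body_count, NA_real_)
  data.frame(pausing_index = pi, exclude_reason = reason,
             stringsAsFactors = FALSE)
}

#' Read / write time-course tables
#'
#' The count TSV has a `tss_id` column plus one column per `sample_id`; the
#' sample sheet TSV has columns `sample_id`, `timepoint_min`,
#' `replicate_id`, `spikein_total`.
#'
#' @param counts_path,samples_path File paths.
#' @return A [time_course()].
#' @export
read_time_course <- function(counts_path, samples_path) {
  ct <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  m <- as.matrix(ct[, setdiff(names(ct), "tss_id"), drop = FALSE])
  rownames(m) <- ct$tss_id
  time_course(m, samples)
}

#' @rdname read_time_course
#' @param tc A [time_course()] to write.
#' @export
write_time_course <- function(tc, counts_path, samples_path) {
  df <- data.frame(tss_id = rownames(tc$counts), tc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tc$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
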