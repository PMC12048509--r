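#' Effective promoter kinetic rates
#'
#' Bundle the four effective rates of the three-state promoter model:
#' nucleosome binding (`kc`) and unbinding (`ko`), transcription initiation
#' (`ki`, loading of Pol II onto an open promoter) and Pol II turnover (`kt`,
#' loss of promoter-proximal Pol II to either productive elongation or early
#' termination). All rates are in events per minute.
#'
#' @param kc Nucleosome binding rate (min^-1).
#' @param ko Nucleosome unbinding rate (min^-1).
#' @param ki Transcription initiation rate (min^-1).
#' @param kt Pol II turnover rate (min^-1).
#' @return An object of class `kinetic_rates` (a named list).
#' @export
#' @examples
#' kinetic_rates(kc = 1, ko = 1, ki = 0.05, kt = 0.2)
kinetic_rates <- function(kc, ko, ki, kt) {
  r <- c(kc = kc, ko = ko, ki = ki, kt = kt)
  if (length(r) != 4L || !is.numeric(r) || anyNA(r) || any(!is.finite(r)))
    stop("rates must be four finite numbers", call. = FALSE)
  if (any(r < 0))
    stop("rates must be non-negative; got negative ",
         paste(names(r)[r < 0], collapse = ", "), call. = FALSE)
  structure(as.list(r), class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("kinetic rates (min^-1): kc = %g, ko = %g, ki = %g, kt = %g\n",
              x$kc, x$ko, x$ki, x$kt))
  invisible(x)
}

state_prob_names <- c("p_nuc", "p_open", "p_pol2")

as_state_probabilities <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 3L)
  names(p) <- state_prob_names
  p
}

#' Stationary distribution of the three-state promoter model
#'
#' The promoter cycles between a nucleosome-occluded state, an open
#' (nucleosome- and Pol II-free) state, and a Pol II-bound state.  At steady
#' state the chain satisfies detailed balance, giving the closed form
#' `p_open = 1 / (1 + kc/ko + ki/kt)`, `p_nuc = (kc/ko) p_open`,
#' `p_pol2 = (ki/kt) p_open`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return Named numeric vector `(p_nuc, p_open, p_pol2)` summing to 1.
#' @export
#' @examples
#' steady_state(kinetic_rates(1, 1, 1, 3))  # (3/7, 3/7, 1/7)
steady_state <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  kc <- rates$kc; ko <- rates$ko; ki <- rates$ki; kt <- rates$kt
  if (kc == 0 && ko == 0 && ki == 0 && kt == 0)
    stop("degenerate rates: all four rates are zero", call. = FALSE)
  if (ki > 0 && kt == 0)
    stop("degenerate rate kt = 0 with ki > 0: Pol II state is absorbing",
         call. = FALSE)
  if (kc > 0 && ko == 0)
    stop("degenerate rate ko = 0 with kc > 0: nucleosome state is absorbing",
         call. = FALSE)
  rn <- if (kc == 0) 0 else kc / ko   # kc/ko, zero when nucleosome unreachable
  rp <- if (ki == 0) 0 else ki / kt   # ki/kt, zero when Pol II unreachable
  p_open <- 1 / (1 + rn + rp)
  as_state_probabilities(c(rn * p_open, p_open, rp * p_open))
}

#' Relative Pol II occupancy and rate ratio from state probabilities
#'
#' The relative Pol II occupancy `q` is the fraction of nucleosome-free
#' promoter molecules that carry a Pol II footprint,
#' `q = p_pol2 / (p_open + p_pol2)`.  At steady state it obeys the sigmoid
#' `q = 1 / (1 + kt/ki)`, and the rate ratio satisfies
#' `kt/ki = p_open/p_pol2`.
#'
#' @param p Named numeric vector `(p_nuc, p_open, p_pol2)` (as from
#'   [steady_state()]), or any non-negative triple in that order.
#' @return A list with `q`, `r` (`Inf` when `p_pol2` is zero) and
#'   `p_free = p_open + p_pol2`.
#' @export
relative_occupancy <- function(p) {
  p <- as_state_probabilities(p)
  if (any(p < 0)) stop("state probabilities must be non-negative", call. = FALSE)
  p_free <- p[["p_open"]] + p[["p_pol2"]]
  if (p_free <= 0)
    stop("undefined occupancy: p_free = p_open + p_pol2 is zero", call. = FALSE)
  q <- p[["p_pol2"]] / p_free
  r <- if (p[["p_pol2"]] == 0) Inf else p[["p_open"]] / p[["p_pol2"]]
  list(q = q, r = r, p_free = p_free)
}

#' Infer the transcription initiation rate from occupancy and turnover
#'
#' Inverts the steady-state sigmoid `q = 1/(1 + kt/ki)`:
#' `ki = kt * q / (1 - q)`.  Vectorised over `q` and `kt`.
#'
#' @param q Relative Pol II occupancy in `[0, 1)`.
#' @param kt Pol II turnover rate (min^-1), strictly positive.
#' @return Initiation rate(s) `ki` in min^-1.
#' @export
#' @examples
#' infer_initiation_rate(q = 0.2, kt = 0.2)   # 0.05 -> one event per 20 min
infer_initiation_rate <- function(q, kt) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 1))
    stop("q must lie in [0, 1]", call. = FALSE)
  if (any(q == 1))
    stop("q = 1 implies an infinite initiation rate", call. = FALSE)
  if (!is.numeric(kt) || anyNA(kt) || any(kt <= 0))
    stop("kt must be strictly positive", call. = FALSE)
  kt * q / (1 - q)
}

promoter_generator <- function(rates) {
  # column j holds the rates out of state j; order (nuc, open, pol2)
  with(rates, matrix(c(
    -ko,            kc,  0,
     ko, -(kc + ki),     kt,
      0,            ki, -kt), nrow = 3, byrow = TRUE))
}

#' Time-dependent solution of the promoter master equation
#'
#' Propagates an initial state distribution `p0` for `t` minutes under the
#' linear master equation of the three-state model, via the matrix
#' exponential of the generator (exact, no ODE stepping).  As `t` grows the
#' solution converges to [steady_state()].
#'
#' @param rates A [kinetic_rates()] object.
#' @param p0 Initial probabilities `(p_nuc, p_open, p_pol2)` summing to 1.
#' @param t Time in minutes (non-negative).
#' @return Named probability vector at time `t`.
#' @export
propagate <- function(rates, p0, t) {
  stopifnot(inherits(rates, "kinetic_rates"))
  p0 <- as_state_probabilities(p0)
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability vector over the three states", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative time in minutes", call. = FALSE)
  if (t == 0) return(p0)
  A <- promoter_generator(rates)
  pt <- as.numeric(Matrix::expm(A * t) %*% p0)
  as_state_probabilities(pt)
}

#' Exact stochastic simulation of the three-state promoter chain
#'
#' Gillespie simulation of the nucleosome/open/Pol II promoter chain.  Both
#' the nucleosome and the Pol II state exit only towards the open state, so
#' the trajectory is a renewal sequence of open-state sojourns alternating
#' with excursions; dwell times and branch choices are drawn in vectorised
#' blocks, which makes long runs cheap.
#'
#' @param rates A [kinetic_rates()] object.
#' @param t_max Total simulated time in minutes.
#' @param seed Integer seed; a fixed seed reproduces the trajectory exactly.
#' @param init Starting state, one of `"open"`, `"nuc"`, `"pol2"`.
#' @return A list with `times` (entry time of each visited state), `states`
#'   (factor-like character vector `"nuc"/"open"/"pol2"`), `time_fractions`
#'   (named vector of occupancy fractions over `[0, t_max]`),
#'   `n_initiations` (count of open -> Pol II transitions) and `t_max`.
#' @export
#' @examples
#' sim <- gillespie_simulate(kinetic_rates(1, 1, 1, 1), t_max = 1000, seed = 1)
#' sim$time_fractions  # close to (1/3, 1/3, 1/3)
gillespie_simulate <- function(rates, t_max, seed,
                               init = c("open", "nuc", "pol2")) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0)
    stop("t_max must be a positive duration in minutes", call. = FALSE)
  init <- match.arg(init)
  kc <- rates$kc; ko <- rates$ko; ki <- rates$ki; kt <- rates$kt
  if (init == "nuc" && ko == 0)
    stop("nucleosome state is absorbing (ko = 0)", call. = FALSE)
  if (init == "pol2" && kt == 0)
    stop("Pol II state is absorbing (kt = 0)", call. = FALSE)
  set.seed(as.integer(seed))

  times <- numeric(0); states <- character(0)
  t_now <- 0; n_init <- 0L
  dwell <- c(nuc = 0, open = 0, pol2 = 0)

  # optional leading excursion when not starting in the open state
  if (init != "open") {
    rate_out <- if (init == "nuc") ko else kt
    d <- stats::rexp(1, rate_out)
    times <- 0; states <- init
    dwell[init] <- min(d, t_max)
    t_now <- d
  } else {
    times <- 0; states <- "open"
  }

  k_out <- kc + ki
  if (k_out == 0) {                      # open state absorbing
    if (t_now < t_max) {
      dwell["open"] <- dwell["open"] + (t_max - t_now)
      if (init != "open") { times <- c(times, t_now); states <- c(states, "open") }
    }
    tf <- dwell / t_max
    return(list(times = times, states = states, time_fractions = tf,
                n_initiations = 0L, t_max = t_max))
  }

  p_pol2_branch <- if (k_out > 0) ki / k_out else 0
  block <- max(1024L, ceiling(t_max * k_out / 2) + 64L)
  while (t_now < t_max) {
    open_d <- stats::rexp(block, k_out)
    to_pol2 <- stats::runif(block) < p_pol2_branch
    exc_rate <- ifelse(to_pol2, kt, ko)
    # absorbing excursion (rate 0) ends the walk; cap with +Inf dwell
    exc_d <- ifelse(exc_rate > 0, stats::rexp(block, pmax(exc_rate, 1e-300)),
                    Inf)
    entry_open <- t_now + c(0, cumsum(open_d + exc_d))[seq_len(block)]
    entry_exc <- entry_open + open_d
    keep <- entry_open < t_max
    if (!any(keep)) break
    eo <- entry_open[keep]; ee <- entry_exc[keep]
    tp <- to_pol2[keep]; od <- open_d[keep]; ed <- exc_d[keep]
    dwell["open"] <- dwell["open"] + sum(pmin(ee, t_max) - eo)
    in_exc <- ee < t_max
    exc_time <- pmin(ee + ed, t_max) - ee
    dwell["pol2"] <- dwell["pol2"] + sum(exc_time[in_exc & tp])
    dwell["nuc"] <- dwell["nuc"] + sum(exc_time[in_exc & !tp])
    n_init <- n_init + sum(in_exc & tp)
    # record trajectory (interleave open and excursion entries)
    n <- length(eo)
    tt <- as.vector(rbind(eo, ee))
    ss <- as.vector(rbind(rep("open", n), ifelse(tp, "pol2", "nuc")))
    sel <- tt < t_max
    times <- c(times, tt[sel]); states <- c(states, ss[sel])
    t_now <- eo[n] + od[n] + ed[n]
    if (!all(keep)) break
    if (!is.finite(t_now)) break         # entered an absorbing excursion
  }
  # drop the duplicated initial "open" entry if present
  if (length(times) >= 2 && times[1] == 0 && times[2] == 0) {
    times <- times[-1]; states <- states[-1]
  }
  tf <- dwell / t_max
  names(tf) <- c("nuc", "open", "pol2")
  list(times = times, states = states, time_fractions = tf,
       n_initiations = as.integer(n_init), t_max = t_max)
}

#' Empirical relative Pol II occupancy from a promoter state table
#'
#' Maps the six observed single-molecule states onto the three model states:
#' the nucleosome state is `nucleosome`, the open state pools `unbound` and
#' `PIC`, and the Pol II state pools `PolII` and `PIC+PolII`.  By default
#' `unassigned` molecules are excluded from the nucleosome-free denominator
#' (they are not interpretable as open or bound); set
#' `include_unassigned = TRUE` to count them as free.
#'
#' @param states A promoter state table as returned by [state_frequencies()]
#'   or [average_replicates()].
#' @param include_unassigned Count unassigned molecules in the free pool?
#' @return `states` with columns `q` and `r` appended.
#' @export
occupancy_from_states <- function(states, include_unassigned = FALSE) {
  req <- c("f_pol2", "f_pic_pol2", "f_nucleosome", "f_unassigned")
  if (!all(req %in% names(states)))
    stop("states must carry the six state-frequency columns", call. = FALSE)
  pol2 <- states$f_pol2 + states$f_pic_pol2
  free <- 1 - states$f_nucleosome -
    if (include_unassigned) 0 else states$f_unassigned
  q <- ifelse(free > 0, pol2 / free, NA_real_)
  states$q <- q
  states$r <- ifelse(q > 0, (1 - q) / q, Inf)
  states
}

#' Initiation rates for a cohort of promoters
#'
#' Combines per-promoter relative Pol II occupancy with per-promoter (or
#' cluster-broadcast) turnover rates to predict initiation rates
#' `ki = kt q/(1-q)` and mean inter-initiation intervals `1/ki`.
#'
#' @param occupancy Data frame with columns `tss_id` and `q`.
#' @param kt Either a single turnover rate (min^-1) applied to all promoters
#'   or a data frame with columns `tss_id` and `kt` (e.g. the cluster fit
#'   broadcast to members, optionally overridden per gene).
#' @return Data frame `tss_id, q, kt, r, ki, interval_min` (interval in
#'   minutes, `Inf` where `ki = 0`; rows with `q = 1` or missing `q` get
#'   `NA` rates).
#' @export
initiation_rate_table <- function(occupancy, kt) {
  stopifnot(all(c("tss_id", "q") %in% names(occupancy)))
  out <- occupancy[, c("tss_id", "q")]
  if (is.data.frame(kt)) {
    stopifnot(all(c("tss_id", "kt") %in% names(kt)))
    out$kt <- kt$kt[match(out$tss_id, kt$tss_id)]
  } else {
    out$kt <- as.numeric(kt)
  }
  ok <- !is.na(out$q) & out$q < 1 & !is.na(out$kt) & out$kt > 0
  out$r <- ifelse(ok & out$q > 0, (1 - out$q) / out$q,
                  ifelse(ok, Inf, NA_real_))
  out$ki <- NA_real_
  out$ki[ok] <- infer_initiation_rate(out$q[ok], out$kt[ok])
  out$interval_min <- ifelse(out$ki > 0, 1 / out$ki, Inf)
  out
}
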