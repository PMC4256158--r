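#' Synthetic survival cohorts and reproductive schedules
#'
#' Seeded generators that emulate the structure of a worm lifespan assay:
#' continuous Gompertz-Makeham lifetimes observed on a daily scoring grid,
#' independent per-day censoring (worms lost at transfer), and daily progeny
#' schedules that stop at a per-individual cessation day. A single integer
#' seed expands deterministically into independent substreams so lifetimes,
#' censoring and progeny can be regenerated in isolation.
#'
#' @name synthetic-cohorts
NULL

# Deterministic substream seed derivation (kept below 2^31).
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 9973) %% 2147483629)
}

#' Sample continuous Gompertz-Makeham lifetimes
#'
#' Draws i.i.d. death times by inverse-transform sampling from the GM hazard
#' \eqn{M(x) = M_0 e^{G x} + M_\infty}: for each uniform draw \eqn{U} the
#' cumulative hazard \eqn{H(t) = (M_0/G)(e^{G t} - 1) + M_\infty t} is solved
#' for \eqn{H(t) = -\log U}, in closed form when \code{Minf = 0}
#' (\eqn{t = (1/G)\log(1 - (G/M_0)\log U)}) and by bracketed root-finding
#' otherwise.
#'
#' @param params a \code{\link{gm_params}} object.
#' @param n number of lifetimes to draw (>= 1).
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return Numeric vector of \code{n} continuous death times in days.
#' @examples
#' t <- sample_gm_lifetimes(gm_params(0.002, 0.25), n = 1000, seed = 1)
#' median(t)
#' @export
sample_gm_lifetimes <- function(params, n, seed) {
  params <- as_gm_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("sample_gm_lifetimes: n must be a positive integer", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  u <- stats::runif(n)
  target <- -log(u)
  if (params$Minf == 0 && params$G > 0) {
    log1p((params$G / params$M0) * target) / params$G
  } else if (params$G == 0) {
    target / (params$M0 + params$Minf)
  } else {
    vapply(target, function(h) gm_invert_cumhaz(params, h), numeric(1))
  }
}

local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite integer seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Discretise continuous lifetimes to the daily grid with censoring
#'
#' Worms are scored once per day, so a death at continuous time \code{t} is
#' observed on day \code{ceiling(t)} (with deaths in (0, 1] recorded on day
#' 1). Independently of death, each individual may be lost on any day with
#' probability \code{censor_prob_per_day}; a loss strictly before the death
#' day produces a censored record on the loss day. Individuals still alive
#' and under observation at \code{max_day} are censored there.
#'
#' @param times positive continuous death times in days.
#' @param censor_prob_per_day per-day loss probability in [0, 1).
#' @param max_day last scored day; use \code{Inf} for no horizon.
#' @param seed integer seed for the censoring process.
#' @param group,replicate labels attached to every record.
#' @param id_prefix prefix for generated individual ids.
#' @return An \code{\link{event_table}}.
#' @export
discretize_and_censor <- function(times, censor_prob_per_day = 0,
                                  max_day = Inf, seed = 1,
                                  group = "cohort", replicate = "1",
                                  id_prefix = "w") {
  if (any(!is.finite(times)) || any(times <= 0))
    stop("discretize_and_censor: times must be finite and > 0", call. = FALSE)
  if (censor_prob_per_day < 0 || censor_prob_per_day >= 1)
    stop("discretize_and_censor: censor_prob_per_day must be in [0, 1)", call. = FALSE)
  if (max_day < 1)
    stop("discretize_and_censor: max_day must be >= 1", call. = FALSE)
  n <- length(times)
  death_day <- pmax(1L, as.integer(ceiling(times)))
  if (censor_prob_per_day > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    # first 'loss' day is geometric on {1, 2, ...}
    loss_day <- stats::rgeom(n, censor_prob_per_day) + 1L
  } else {
    loss_day <- rep(Inf, n)
  }
  event_day <- pmin(death_day, loss_day)
  status <- ifelse(loss_day < death_day, "censored", "death")
  over <- event_day > max_day
  event_day[over] <- max_day
  status[over] <- "censored"
  event_table(data.frame(
    individual_id = paste0(id_prefix, seq_len(n)),
    group = group, replicate = as.character(replicate),
    event_day = as.integer(event_day), status = status,
    stringsAsFactors = FALSE))
}

#' Simulate a replicated survival cohort
#'
#' Convenience wrapper combining \code{\link{sample_gm_lifetimes}} and
#' \code{\link{discretize_and_censor}} for several independent replicate
#' experiments of the same condition, mirroring the usual assay design of
#' about 100 worms per condition scored daily in three independent
#' experiments.
#'
#' @param params a \code{\link{gm_params}} object.
#' @param n_individuals worms per replicate.
#' @param n_replicates number of independent replicate experiments.
#' @param censor_prob_per_day per-day loss probability in [0, 1).
#' @param max_day observation horizon in days.
#' @param seed integer master seed; each replicate and process draws from its
#'   own substream.
#' @param group condition label for all records.
#' @return An \code{\link{event_table}} with one stratum per replicate.
#' @examples
#' ev <- simulate_cohort(gm_params(0.004, 0.25), n_individuals = 50,
#'                       n_replicates = 3, seed = 7)
#' table(ev$replicate, ev$status)
#' @export
simulate_cohort <- function(params, n_individuals = 100, n_replicates = 3,
                            censor_prob_per_day = 0, max_day = Inf,
                            seed = 1, group = "cohort") {
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  reps <- lapply(seq_len(n_replicates), function(r) {
    t <- sample_gm_lifetimes(params, n_individuals,
                             seed = substream_seed(seed, 2L * r))
    discretize_and_censor(t, censor_prob_per_day, max_day,
                          seed = substream_seed(seed, 2L * r + 1L),
                          group = group, replicate = as.character(r),
                          id_prefix = paste0("r", r, "w"))
  })
  event_table(do.call(rbind, reps))
}

#' Simulate daily progeny schedules
#'
#' For each individual a reproduction cessation day is drawn from
#' \code{cessation}, then daily progeny counts are Poisson-distributed around
#' \code{daily_counts} for days up to and including the cessation day and
#' exactly zero afterwards. \code{cessation} is a list naming a distribution:
#' \code{list(name = "fixed", day = 7)},
#' \code{list(name = "normal", mean = 7, sd = 1)} (rounded to the nearest
#' day), or \code{list(name = "poisson", lambda = 6)} (shifted so day >= 1);
#' draws are clamped to >= 1.
#'
#' @param daily_counts expected progeny per day of adulthood (day 1 first).
#' @param cessation cessation-day distribution specification (see above).
#' @param n_individuals number of hermaphrodites.
#' @param seed integer seed.
#' @param group,replicate labels attached to every record.
#' @return A progeny table: data.frame with columns \code{individual_id},
#'   \code{group}, \code{replicate}, \code{day}, \code{progeny_count}, one
#'   row per individual-day up to \code{length(daily_counts)} days.
#' @examples
#' pr <- simulate_repro_schedules(c(50, 120, 90, 40, 15, 5, 2),
#'                                cessation = list(name = "fixed", day = 5),
#'                                n_individuals = 3, seed = 1)
#' aggregate(progeny_count ~ individual_id, pr, sum)
#' @export
simulate_repro_schedules <- function(daily_counts, cessation,
                                     n_individuals, seed,
                                     group = "cohort", replicate = "1") {
  if (length(daily_counts) == 0)
    stop("simulate_repro_schedules: daily_counts must be non-empty", call. = FALSE)
  if (any(daily_counts < 0) || any(!is.finite(daily_counts)))
    stop("simulate_repro_schedules: daily_counts must be finite and >= 0", call. = FALSE)
  n_days <- length(daily_counts)
  old <- local_seed(substream_seed(seed, 101L))
  on.exit(restore_seed(old))
  cess <- switch(cessation$name,
    fixed = rep(cessation$day, n_individuals),
    normal = round(stats::rnorm(n_individuals, cessation$mean, cessation$sd)),
    poisson = stats::rpois(n_individuals, cessation$lambda) + 1L,
    stop("unknown cessation distribution: ", cessation$name, call. = FALSE))
  cess <- pmax(1, cess)
  restore_seed(old)
  old <- local_seed(substream_seed(seed, 102L))
  rows <- lapply(seq_len(n_individuals), function(i) {
    active <- seq_len(n_days) <= cess[i]
    counts <- integer(n_days)
    counts[active] <- stats::rpois(sum(active), daily_counts[active])
    data.frame(individual_id = paste0("h", i), group = group,
               replicate = as.character(replicate),
               day = seq_len(n_days), progeny_count = counts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
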