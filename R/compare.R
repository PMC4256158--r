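#' Comparison results
#'
#' Light S3 container for a two-group statistical comparison: the test
#' statistic, raw and multiplicity-adjusted p-values, and the signed percent
#' change of the summary being compared.
#'
#' @name comparison-results
NULL

new_comparison <- function(statistic, p_raw, percent_change, test_name,
                           p_adjusted = p_raw) {
  structure(list(statistic = statistic, p_raw = p_raw,
                 p_adjusted = p_adjusted, percent_change = percent_change,
                 test_name = test_name),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g (adjusted %.4g), change = %+.1f%%\n",
              x$test_name, x$statistic, x$p_raw, x$p_adjusted, x$percent_change))
  invisible(x)
}

#' Two-group log-rank test on survival event tables
#'
#' Standard 1-df log-rank chi-square comparing the survival distributions of
#' two cohorts on the shared day grid; censored individuals are handled
#' through the risk sets. The percent change reported is the change in
#' restricted mean lifespan of cohort A relative to cohort B.
#'
#' @param events_a,events_b \code{\link{event_table}} strata (treatment and
#'   control); each non-empty, with at least one death between them.
#' @return A \code{"comparison_result"} with \code{test_name = "logrank"}.
#' @export
logrank_test <- function(events_a, events_b) {
  a <- as.data.frame(events_a)
  b <- as.data.frame(events_b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("logrank_test: both strata must be non-empty", call. = FALSE)
  if (sum(a$status == "death") + sum(b$status == "death") == 0)
    stop("logrank_test: undefined with zero deaths in both strata", call. = FALSE)
  time <- c(a$event_day, b$event_day)
  event <- c(a$status, b$status) == "death"
  arm <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
  stat <- unname(sd$chisq)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pct <- 100 * (mean_lifespan(event_table_quiet(a)) /
                  mean_lifespan(event_table_quiet(b)) - 1)
  new_comparison(stat, p, pct, "logrank")
}

# internal: rebuild an event_table without re-validating ids (strata may
# reuse ids across sources)
event_table_quiet <- function(df) {
  df$individual_id <- paste0(seq_len(nrow(df)), "_", df$individual_id)
  event_table(df)
}

#' Two-group comparison of mean lifespan
#'
#' Student t-test on the per-individual adult lifespans (death days) of two
#' pooled cohorts. This targets the mean-lifespan axis of the demographic
#' classification directly, whereas \code{\link{logrank_test}} compares the
#' whole survival distribution (and so also reacts to shape differences
#' with identical means). Censored individuals carry no observed lifespan
#' and are excluded; with heavy censoring prefer the restricted-mean
#' summary of \code{\link{mean_lifespan}}.
#'
#' @param events_a,events_b \code{\link{event_table}} strata with >= 2
#'   deaths each.
#' @return A \code{"comparison_result"} with \code{test_name = "t_test"}.
#' @export
mean_lifespan_test <- function(events_a, events_b) {
  a <- as.data.frame(events_a)
  b <- as.data.frame(events_b)
  da <- a$event_day[a$status == "death"]
  db <- b$event_day[b$status == "death"]
  if (length(da) < 2 || length(db) < 2)
    stop("mean_lifespan_test: need >= 2 deaths per stratum", call. = FALSE)
  two_sample_t(da, db)
}

#' Holm (Bonferroni step-down) p-value adjustment
#'
#' Sequentially rejective correction: the i-th smallest p-value is
#' multiplied by (m - i + 1), monotone non-decrease is enforced along the
#' sorted sequence, values are capped at 1, and results are returned in the
#' original order.
#'
#' @param p_values numeric vector of probabilities in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("holm_adjust: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Two-sample Student t-test with percent change
#'
#' Two-sided pooled-variance (Student) t-test, as used for reproductive
#' lifespan, brood size and developmental-time comparisons. The percent
#' change is \eqn{100 (\bar a - \bar b) / \bar b}. Two constant groups with
#' equal means return p = 1 by convention.
#'
#' @param values_a,values_b numeric measurement vectors, >= 2 values each.
#' @return A \code{"comparison_result"} with \code{test_name = "t_test"}.
#' @export
two_sample_t <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("two_sample_t: need >= 2 values per group", call. = FALSE)
  pct <- 100 * (mean(values_a) - mean(values_b)) / mean(values_b)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(new_comparison(0, 1, 0, "t_test"))
    return(new_comparison(sign(mean(values_a) - mean(values_b)) * Inf, 0,
                          pct, "t_test"))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  new_comparison(unname(tt$statistic), tt$p.value, pct, "t_test")
}

#' Classify a gene inactivation into a demographic effect group
#'
#' Operationalises the four observed patterns of somatic-aging effects.
#' Significant effects on IMR and RoA are judged by two-sample t-tests on
#' the per-replicate fitted parameters at level \code{alpha}, with direction
#' from the means (both significance and a consistent sign are required);
#' the lifespan effect comes from the supplied combined-experiment
#' comparison (log-rank on pooled replicates). Groups:
#' \itemize{
#'   \item Group 1: RoA down, IMR unchanged, lifespan up
#'   \item Group 2: IMR down, RoA unchanged, lifespan up
#'   \item Group 3: IMR down, RoA up, lifespan unchanged
#'   \item Group 4: no effect on IMR, RoA or lifespan
#' }
#' Any other pattern is returned as unclassified (\code{group = NA}).
#'
#' @param treatment,control \code{"replicate_fits"} objects with >= 2
#'   replicates each.
#' @param lifespan_comparison a \code{"comparison_result"} for mean lifespan
#'   (e.g. \code{\link{logrank_test}} treatment vs control).
#' @param alpha significance level for each effect test (default 0.05).
#' @return An object of class \code{"demographic_call"}: list with
#'   \code{imr_effect}, \code{roa_effect}, \code{lifespan_effect} (each
#'   \code{"down"}, \code{"none"} or \code{"up"}) and \code{group}
#'   (integer 1-4 or \code{NA} for unclassified).
#' @export
classify_demographic_group <- function(treatment, control,
                                       lifespan_comparison, alpha = 0.05) {
  stopifnot(inherits(treatment, "replicate_fits"),
            inherits(control, "replicate_fits"))
  if (length(treatment$fits) < 2 || length(control$fits) < 2)
    stop("classify_demographic_group: need >= 2 replicates per arm", call. = FALSE)
  effect <- function(t_vals, c_vals) {
    cmp <- two_sample_t(t_vals, c_vals)
    if (cmp$p_raw >= alpha || mean(t_vals) == mean(c_vals)) "none"
    else if (mean(t_vals) < mean(c_vals)) "down" else "up"
  }
  imr_effect <- effect(treatment$imr, control$imr)
  roa_effect <- effect(treatment$roa, control$roa)
  lp <- lifespan_comparison
  lifespan_effect <- if (lp$p_adjusted >= alpha || lp$percent_change == 0) "none"
    else if (lp$percent_change > 0) "up" else "down"
  key <- paste(imr_effect, roa_effect, lifespan_effect)
  group <- switch(key,
                  "none down up" = 1L,
                  "down none up" = 2L,
                  "down up none" = 3L,
                  "none none none" = 4L,
                  NA_integer_)
  structure(list(imr_effect = imr_effect, roa_effect = roa_effect,
                 lifespan_effect = lifespan_effect, group = group),
            class = "demographic_call")
}

#' @export
print.demographic_call <- function(x, ...) {
  lab <- if (is.na(x$group)) "unclassified" else paste("Group", x$group)
  cat(sprintf("<demographic_call> %s (IMR %s, RoA %s, lifespan %s)\n",
              lab, x$imr_effect, x$roa_effect, x$lifespan_effect))
  invisible(x)
}

#' Percent reduction of IMR and RoA relative to control
#'
#' \eqn{100 (\bar\theta_{ctrl} - \bar\theta_{trt}) / \bar\theta_{ctrl}} for
#' each mortality parameter, averaged over replicates. Positive values are
#' reductions; a treatment increase gives a negative "reduction".
#'
#' @param treatment,control \code{"replicate_fits"} objects.
#' @return Named numeric vector \code{c(imr_pct, roa_pct)}.
#' @export
percent_change_params <- function(treatment, control) {
  if (control$imr_mean == 0 || control$roa_mean == 0)
    stop("percent_change_params: zero control mean", call. = FALSE)
  c(imr_pct = 100 * (control$imr_mean - treatment$imr_mean) / control$imr_mean,
    roa_pct = 100 * (control$roa_mean - treatment$roa_mean) / control$roa_mean)
}
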