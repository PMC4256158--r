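#' Fit the Gompertz-Makeham model to a survival curve
#'
#' Nonlinear least squares fit of the GM survival function
#' \eqn{S(x) = \exp[(M_0/G)(1 - e^{G x}) - M_\infty x]} to an empirical
#' survival curve, normally the Kaplan-Meier estimate at each observed day
#' (which handles censoring). The sum of squared deviations
#' \eqn{\sum_i (S(x_i) - \hat S_i)^2} is minimised over the box
#' \eqn{M_0 \in [10^{-8}, 1]}, \eqn{G \in [0, 2]},
#' \eqn{M_\infty \in [0, 1]} per day with a bounded quasi-Newton
#' (trust-region-type PORT) optimiser, \code{M0} parameterised on the log
#' scale for conditioning. Starting values come from an ordinary linear
#' regression of \eqn{\log m_x} on \eqn{x} over days with
#' \eqn{0 < q_x < 1} (Gompertz log-linearity), \code{Minf} starting at 0;
#' the optimiser is restarted from three deterministically jittered starts
#' and the lowest-RSS solution kept.
#'
#' Survival points after the day the curve first reaches 0 are excluded (the
#' model never reaches exactly 0, and a run of exact zeros would overweight
#' the tail).
#'
#' @param survival_curve data.frame with columns \code{day} and
#'   \code{survival} (e.g. from \code{\link{km_survival}}), at least 4
#'   distinct days with at least one point below 0.9.
#' @param group,replicate optional labels carried into the result.
#' @return An object of class \code{"gm_fit"}: list with \code{params}
#'   (\code{\link{gm_params}}), \code{IMR} (= M0), \code{RoA} (= G),
#'   \code{rss}, \code{n_points}, \code{converged}, \code{group},
#'   \code{replicate}.
#' @examples
#' p <- gm_params(0.002, 0.25)
#' curve <- data.frame(day = 1:30, survival = gm_survival(p, 1:30))
#' fit_gm(curve)
#' @export
fit_gm <- function(survival_curve, group = NA_character_,
                   replicate = NA_character_) {
  sc <- as.data.frame(survival_curve)
  if (!all(c("day", "survival") %in% names(sc)))
    stop("fit_gm: survival_curve needs columns 'day' and 'survival'", call. = FALSE)
  sc <- sc[order(sc$day), , drop = FALSE]
  zero <- which(sc$survival <= 0)
  if (length(zero)) sc <- sc[seq_len(zero[1]), , drop = FALSE]
  day <- sc$day
  surv <- sc$survival
  if (length(unique(day)) < 4)
    stop("fit_gm: need at least 4 distinct days", call. = FALSE)
  if (min(surv) >= 0.9)
    stop("fit_gm: survival curve is non-identifiable (no decline below 0.9)",
         call. = FALSE)

  # model in optimisation coordinates (log10 M0, G, Minf)
  surv_fn <- function(par, x) {
    p <- list(M0 = 10^par[1], G = par[2], Minf = par[3])
    if (p$G == 0) exp(-(p$M0 + p$Minf) * x)
    else exp((p$M0 / p$G) * (1 - exp(p$G * x)) - p$Minf * x)
  }
  rss_fn <- function(par) sum((surv_fn(par, day) - surv)^2)

  start <- gm_start_values(day, surv)
  starts <- list(start,
                 c(start[1] - 1, max(start[2] * 0.5, 0.01), 0),
                 c(start[1] + 0.5, min(start[2] * 2, 1.5), 1e-4))
  lower <- c(-8, 0, 0)
  upper <- c(0, 2, 1)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    opt <- tryCatch(
      stats::nlminb(s, rss_fn, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000,
                                   rel.tol = 1e-10, abs.tol = 1e-30)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("fit_gm: optimiser failed from every start", call. = FALSE)
  params <- gm_params(M0 = 10^best$par[1], G = best$par[2], Minf = best$par[3])
  structure(list(params = params, IMR = params$M0, RoA = params$G,
                 rss = best$objective, n_points = length(day),
                 converged = best$convergence == 0,
                 group = group, replicate = replicate),
            class = "gm_fit")
}

# log-mortality regression start: log m_x = log M0 + G x
gm_start_values <- function(day, surv) {
  s_prev <- c(1, surv[-length(surv)])
  qx <- 1 - surv / s_prev
  ok <- qx > 0 & qx < 1 & s_prev > 0
  if (sum(ok) >= 2) {
    mx <- -log1p(-qx[ok])
    co <- stats::coef(stats::lm(log(mx) ~ day[ok]))
    m0 <- exp(unname(co[1]))
    g <- max(unname(co[2]), 0)
    c(log10(min(max(m0, 1e-8), 1)), min(g, 2), 0)
  } else {
    c(log10(0.01), 0.1, 0)
  }
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(sprintf("<gm_fit> IMR (M0) = %.4g, RoA (G) = %.4g, Minf = %.4g per day\n",
              x$IMR, x$RoA, x$params$Minf))
  cat(sprintf("  RSS = %.3g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Lifespan summaries derived from a fitted GM model
#'
#' From a converged fit: the median lifespan solving \eqn{S(x) = 0.5}, the
#' "maximum" lifespan defined as the age at 1\% estimated survival
#' (\eqn{S(x) = 0.01}; a model-derived quantile, not the oldest observed
#' death), and the mean lifespan \eqn{\int_0^\infty S(x)\,dx} by adaptive
#' quadrature with an analytic tail bound.
#'
#' @param fit a \code{"gm_fit"} or \code{\link{gm_params}} object.
#' @return Named numeric vector \code{c(median, mean, max1pct)}, days.
#' @export
derived_lifespans <- function(fit) {
  params <- if (inherits(fit, "gm_fit")) {
    if (!fit$converged) stop("derived_lifespans: fit did not converge", call. = FALSE)
    fit$params
  } else as_gm_params(fit)
  c(median = gm_quantile(params, 0.5),
    mean = gm_mean(params),
    max1pct = gm_quantile(params, 0.99))
}

#' Fit the GM model to every replicate of a condition
#'
#' Builds the per-replicate Kaplan-Meier curve and fits each one, matching
#' the presentation of mortality parameters as the average with standard
#' deviation of independent experiments.
#'
#' @param events an \code{\link{event_table}}.
#' @param group condition label.
#' @return A \code{"replicate_fits"} object; see
#'   \code{\link{summarize_replicates}}.
#' @export
fit_gm_replicates <- function(events, group = NULL) {
  x <- stratum(events, group)
  fits <- lapply(sort(unique(x$replicate)), function(r) {
    fit_gm(km_survival(x, replicate = r), group = group %||% "all",
           replicate = r)
  })
  summarize_replicates(fits)
}

#' Summarise GM fits across replicate experiments
#'
#' Per-parameter mean and sample standard deviation of IMR and RoA across
#' replicates (sd is \code{NA} for a single replicate).
#'
#' @param fits list of converged \code{"gm_fit"} objects, one per replicate.
#' @return A \code{"replicate_fits"} object: list with \code{fits},
#'   per-replicate vectors \code{imr}, \code{roa}, and \code{imr_mean},
#'   \code{imr_sd}, \code{roa_mean}, \code{roa_sd}.
#' @export
summarize_replicates <- function(fits) {
  if (length(fits) < 1) stop("summarize_replicates: need >= 1 fit", call. = FALSE)
  if (inherits(fits, "gm_fit")) fits <- list(fits)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    stop("summarize_replicates: ", sum(!conv), " unconverged fit(s)", call. = FALSE)
  imr <- vapply(fits, `[[`, numeric(1), "IMR")
  roa <- vapply(fits, `[[`, numeric(1), "RoA")
  structure(list(fits = fits, imr = imr, roa = roa,
                 imr_mean = mean(imr),
                 imr_sd = if (length(imr) >= 2) stats::sd(imr) else NA_real_,
                 roa_mean = mean(roa),
                 roa_sd = if (length(roa) >= 2) stats::sd(roa) else NA_real_),
            class = "replicate_fits")
}

#' @export
print.replicate_fits <- function(x, ...) {
  cat(sprintf("<replicate_fits> %d replicate(s)\n", length(x$fits)))
  cat(sprintf("  IMR: mean %.4g, sd %.4g\n", x$imr_mean, x$imr_sd))
  cat(sprintf("  RoA: mean %.4g, sd %.4g\n", x$roa_mean, x$roa_sd))
  invisible(x)
}
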