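#' Discrete-day lifetable
#'
#' Tallies the classic lifetable quantities per day of adult life for one
#' stratum of an event table: \code{Nx} (number entering the interval),
#' \code{dx} (deaths), \code{cx} (censored), the interval probability of
#' death \eqn{q_x = d_x / N_x}, the force of mortality
#' \eqn{m_x = -\log(1 - q_x)}, and the Kaplan-Meier survival proportion
#' \eqn{KM(x) = \prod_{x' \le x} (1 - q_{x'})}.
#'
#' Censored individuals are counted in \code{Nx} for their final observed day
#' and leave the risk set afterwards; no actuarial half-interval correction
#' is applied. Days with \eqn{q_x = 1} give \eqn{m_x = +\infty}; such days
#' are flagged (column \code{mx_defined}) and must be excluded from any
#' regression on \eqn{m_x}. The table ends on the last day any individual is
#' under observation.
#'
#' @param events an \code{\link{event_table}} (or coercible data.frame).
#' @param group condition label selecting the stratum; \code{NULL} keeps all.
#' @param replicate replicate id, or \code{"all"} (default) to pool
#'   replicates of the group.
#' @return A data.frame of class \code{c("lifetable", "data.frame")} with
#'   columns \code{day}, \code{Nx}, \code{dx}, \code{cx}, \code{qx},
#'   \code{mx}, \code{km}, \code{mx_defined}, and attributes \code{group},
#'   \code{replicate} and \code{n} (cohort size).
#' @examples
#' ev <- event_table(data.frame(
#'   individual_id = 1:4, group = "ctrl", replicate = 1,
#'   event_day = c(1, 1, 2, 2),
#'   status = c("death", "death", "death", "censored")))
#' make_lifetable(ev, "ctrl")
#' @export
make_lifetable <- function(events, group = NULL, replicate = "all") {
  x <- stratum(events, group, replicate)
  n <- nrow(x)
  last <- max(x$event_day)
  days <- seq_len(last)
  dx <- tabulate(x$event_day[x$status == "death"], nbins = last)
  cx <- tabulate(x$event_day[x$status == "censored"], nbins = last)
  Nx <- n - cumsum(c(0L, (dx + cx)[-last]))
  keep <- Nx > 0
  days <- days[keep]; dx <- dx[keep]; cx <- cx[keep]; Nx <- Nx[keep]
  qx <- dx / Nx
  mx <- -log1p(-qx)
  km <- cumprod(1 - qx)
  lt <- data.frame(day = days, Nx = Nx, dx = dx, cx = cx, qx = qx,
                   mx = mx, km = km, mx_defined = qx < 1)
  structure(lt, class = c("lifetable", "data.frame"),
            group = group %||% "all", replicate = replicate, n = n)
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> group '%s', replicate '%s', n = %d, days 1..%d\n",
              attr(x, "group"), paste(attr(x, "replicate"), collapse = ","),
              attr(x, "n"), max(x$day)))
  if (any(!x$mx_defined))
    cat("  note:", sum(!x$mx_defined), "day(s) with qx = 1 (mx infinite, flagged)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Kaplan-Meier survival on the daily grid
#'
#' Product-limit estimate of survival after each scored day,
#' \eqn{\hat S(x) = \prod_{x' \le x} (1 - d_{x'}/N_{x'})}, with censored
#' individuals leaving the risk set after their censoring day. Without
#' censoring this equals the raw fraction of the cohort alive after day
#' \code{x}.
#'
#' @inheritParams make_lifetable
#' @return data.frame with columns \code{day} and \code{survival}.
#' @export
km_survival <- function(events, group = NULL, replicate = "all") {
  lt <- make_lifetable(events, group, replicate)
  data.frame(day = lt$day, survival = lt$km)
}

#' Restricted mean lifespan
#'
#' Mean lifespan as the area under the Kaplan-Meier curve up to the last
#' observed day (the restricted mean survival time). On the daily grid with
#' interval \code{x} covering \code{(x-1, x]} this is
#' \eqn{\sum_{x=1}^{L} \hat S(x-1)} days. Without censoring it reduces to
#' the arithmetic mean of the death days.
#'
#' @inheritParams make_lifetable
#' @return Mean lifespan in days.
#' @export
mean_lifespan <- function(events, group = NULL, replicate = "all") {
  lt <- make_lifetable(events, group, replicate)
  sum(c(1, lt$km[-nrow(lt)]))
}

#' Write a lifetable as CSV
#'
#' Column order is fixed (day, Nx, dx, cx, qx, mx, km) so outputs diff
#' bit-exactly between runs.
#'
#' @param lt a \code{\link{make_lifetable}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  out <- as.data.frame(lt)[c("day", "Nx", "dx", "cx", "qx", "mx", "km")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
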