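#' Per-individual survival event table
#'
#' The canonical container for survival data on the daily scoring grid: one
#' row per worm with its condition label, replicate experiment, the day of
#' its final observation and whether that observation was a death or a
#' censoring (e.g. lost at transfer). Day 1 is the first day of adulthood;
#' interval \code{x} covers \code{(x-1, x]}.
#'
#' @param data a data.frame with columns \code{individual_id}, \code{group},
#'   \code{replicate}, \code{event_day}, \code{status}.
#' @return A validated data.frame of class \code{c("event_table", "data.frame")}.
#' @export
event_table <- function(data) {
  required <- c("individual_id", "group", "replicate", "event_day", "status")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop("event_table: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[required]
  data$individual_id <- as.character(data$individual_id)
  data$group <- as.character(data$group)
  data$replicate <- as.character(data$replicate)
  data$status <- as.character(data$status)
  if (!is.numeric(data$event_day) || any(!is.finite(data$event_day)) ||
      any(data$event_day < 1) || any(data$event_day != round(data$event_day)))
    stop("event_table: event_day must be a positive integer day (>= 1)",
         call. = FALSE)
  data$event_day <- as.integer(data$event_day)
  bad <- !data$status %in% c("death", "censored")
  if (any(bad))
    stop("event_table: invalid status at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         " (must be 'death' or 'censored')", call. = FALSE)
  key <- paste(data$group, data$replicate, data$individual_id, sep = "\r")
  if (anyDuplicated(key))
    stop("event_table: duplicate individual_id within a (group, replicate) stratum",
         call. = FALSE)
  class(data) <- c("event_table", "data.frame")
  data
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d individuals, %d group(s), %d replicate(s); %d deaths, %d censored\n",
              nrow(x), length(unique(x$group)), length(unique(x$replicate)),
              sum(x$status == "death"), sum(x$status == "censored")))
  NextMethod()
}

#' Select a (group, replicate) stratum of an event table
#'
#' @param events an \code{\link{event_table}} or coercible data.frame.
#' @param group condition label; \code{NULL} keeps all groups.
#' @param replicate replicate id(s), or \code{"all"} (default) to pool.
#' @return The selected rows as a data.frame; an empty selection is an
#'   error (empty cohort).
#' @export
stratum <- function(events, group = NULL, replicate = "all") {
  x <- as.data.frame(events)
  if (!is.null(group)) x <- x[x$group == group, , drop = FALSE]
  if (!identical(replicate, "all"))
    x <- x[x$replicate %in% as.character(replicate), , drop = FALSE]
  if (nrow(x) == 0)
    stop("empty cohort: no records for group '", group %||% "<any>",
         "', replicate '", paste(replicate, collapse = ","), "'", call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
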