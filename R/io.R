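#' Read and write event tables as CSV
#'
#' The canonical interchange dialect: a plain CSV with header
#' \code{individual_id, group, replicate, event_day, status}. Malformed rows
#' are reported with their line numbers; an invalid status is a hard
#' failure.
#'
#' @param path CSV file path.
#' @return \code{read_event_table}: a validated \code{\link{event_table}}.
#' @export
read_event_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("individual_id", "group", "replicate", "event_day", "status")
  if (!all(required %in% names(raw)))
    stop("read_event_table: header must contain ",
         paste(required, collapse = ", "), call. = FALSE)
  day <- suppressWarnings(as.numeric(raw$event_day))
  bad_day <- !is.finite(day) | day < 1 | day != round(day)
  bad_status <- !raw$status %in% c("death", "censored")
  bad <- bad_day | bad_status
  if (any(bad))
    stop("read_event_table: malformed row(s) at data line(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         " of ", basename(path),
         " (event_day must be a positive integer; status death|censored)",
         call. = FALSE)
  raw$event_day <- as.integer(day)
  event_table(raw)
}

#' @rdname read_event_table
#' @param events an \code{\link{event_table}} to write.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read a daily progeny table CSV
#'
#' Expected header: \code{individual_id, group, replicate, day,
#' progeny_count}, one row per individual-day.
#'
#' @param path CSV file path.
#' @return A validated progeny data.frame.
#' @export
read_progeny_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "group", "replicate", "day", "progeny_count")
  if (!all(required %in% names(raw)))
    stop("read_progeny_table: header must contain ",
         paste(required, collapse = ", "), call. = FALSE)
  if (any(!is.finite(raw$day)) || any(raw$day < 1) || any(raw$day != round(raw$day)))
    stop("read_progeny_table: day must be a positive integer", call. = FALSE)
  if (any(!is.finite(raw$progeny_count)) || any(raw$progeny_count < 0))
    stop("read_progeny_table: progeny_count must be >= 0", call. = FALSE)
  raw$individual_id <- as.character(raw$individual_id)
  raw$group <- as.character(raw$group)
  raw$replicate <- as.character(raw$replicate)
  raw[required]
}

#' Read a pipeline run configuration (YAML)
#'
#' Recognised fields: \code{events} (event-table CSV path), \code{progeny}
#' (optional progeny CSV path), \code{control} (control group label),
#' \code{genes} (treatment group labels; default every non-control group),
#' \code{alpha} (default 0.05), \code{hit_threshold_pct} (default 25),
#' \code{seed} (default 1), \code{out_dir}, and \code{stages} (subset of
#' \code{lifetable}, \code{fit}, \code{compare}, \code{screen}; default
#' all applicable).
#'
#' @param path YAML file path.
#' @return A named list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  defaults <- list(progeny = NULL, genes = NULL, alpha = 0.05,
                   hit_threshold_pct = 25, seed = 1L, out_dir = ".",
                   stages = c("lifetable", "fit", "compare", "screen"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$events)) stop("run config: 'events' path is required", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("run config: alpha must lie in (0, 1)", call. = FALSE)
  if (any(c("compare", "screen") %in% cfg$stages) && is.null(cfg$control))
    stop("run config: 'control' label required when comparisons are requested",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run the full demographic/screen pipeline
#'
#' Deterministic end-to-end run over an event table (and optionally a
#' progeny table): per-stratum lifetables and Kaplan-Meier curves,
#' per-replicate Gompertz-Makeham fits, treatment-vs-control log-rank
#' comparisons with Holm adjustment across all genes in the run, demographic
#' group calls, reproductive-lifespan screen calls, and a JSON manifest
#' recording the configuration. A failing stage for one gene is isolated:
#' the pipeline continues and reports per-gene status.
#'
#' @param config a \code{"run_config"} (see \code{\link{read_run_config}})
#'   or a plain list with the same fields.
#' @return Invisibly, a list with elements \code{lifetables}, \code{fits}
#'   (data.frame), \code{comparisons} (data.frame), \code{screen}
#'   (data.frame or NULL) and \code{manifest}; the same tables are written
#'   as CSV under \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  events <- if (is.character(cfg$events)) read_event_table(cfg$events)
            else event_table(cfg$events)
  progeny <- if (is.null(cfg$progeny)) NULL
             else if (is.character(cfg$progeny)) read_progeny_table(cfg$progeny)
             else cfg$progeny
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- sort(unique(events$group))
  genes <- cfg$genes %||% setdiff(groups, cfg$control)
  genes <- sort(genes)

  lifetables <- list()
  if ("lifetable" %in% cfg$stages) {
    for (g in groups) {
      lt <- make_lifetable(events, g)
      lifetables[[g]] <- lt
      write_lifetable(lt, file.path(cfg$out_dir, paste0("lifetable_", g, ".csv")))
    }
  }

  fits_df <- NULL
  rep_fits <- list()
  if ("fit" %in% cfg$stages) {
    rows <- list()
    for (g in groups) {
      rf <- tryCatch(fit_gm_replicates(events, g), error = function(e) e)
      if (inherits(rf, "error")) {
        rows[[g]] <- data.frame(group = g, replicate = NA, M0 = NA, G = NA,
                                Minf = NA, RSS = NA, converged = FALSE,
                                median = NA, mean = NA, max1pct = NA,
                                status = conditionMessage(rf))
        next
      }
      rep_fits[[g]] <- rf
      rows[[g]] <- do.call(rbind, lapply(rf$fits, function(f) {
        dl <- derived_lifespans(f)
        data.frame(group = g, replicate = f$replicate, M0 = f$params$M0,
                   G = f$params$G, Minf = f$params$Minf, RSS = f$rss,
                   converged = f$converged, median = dl[["median"]],
                   mean = dl[["mean"]], max1pct = dl[["max1pct"]],
                   status = "ok")
      }))
    }
    fits_df <- do.call(rbind, rows)
    rownames(fits_df) <- NULL
    utils::write.csv(fits_df, file.path(cfg$out_dir, "gm_fits.csv"),
                     row.names = FALSE)
  }

  comparisons <- NULL
  if ("compare" %in% cfg$stages && length(genes)) {
    ctrl <- stratum(events, cfg$control)
    cmps <- lapply(genes, function(g)
      tryCatch(logrank_test(stratum(events, g), ctrl), error = function(e) e))
    names(cmps) <- genes
    # Holm family = all gene comparisons in this run
    ok <- !vapply(cmps, inherits, logical(1), "error")
    p_adj <- rep(NA_real_, length(genes))
    p_adj[ok] <- holm_adjust(vapply(cmps[ok], `[[`, numeric(1), "p_raw"))
    rows <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      cmp <- cmps[[i]]
      if (inherits(cmp, "error"))
        return(data.frame(gene = g, test = "logrank", statistic = NA_real_,
                          p_raw = NA_real_, p_adjusted = NA_real_,
                          percent_change = NA_real_, group_call = NA_integer_,
                          status = conditionMessage(cmp)))
      cmp$p_adjusted <- p_adj[i]
      call <- if (!is.null(rep_fits[[g]]) && !is.null(rep_fits[[cfg$control]]))
        tryCatch(classify_demographic_group(
          rep_fits[[g]], rep_fits[[cfg$control]],
          mean_lifespan_test(stratum(events, g), ctrl), cfg$alpha),
          error = function(e) NULL)
      else NULL
      data.frame(gene = g, test = "logrank", statistic = cmp$statistic,
                 p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
                 percent_change = cmp$percent_change,
                 group_call = if (is.null(call)) NA_integer_ else call$group,
                 status = "ok")
    })
    comparisons <- do.call(rbind, rows)
    rownames(comparisons) <- NULL
    utils::write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }

  screen <- NULL
  if ("screen" %in% cfg$stages && !is.null(progeny)) {
    scored <- score_progeny_table(progeny)
    ctrl_sc <- scored[scored$group == cfg$control, ]
    screen_genes <- intersect(sort(unique(scored$group)), genes)
    rows <- lapply(screen_genes, function(g) {
      trt_sc <- scored[scored$group == g, ]
      reps <- sort(intersect(unique(trt_sc$replicate), unique(ctrl_sc$replicate)))
      res <- tryCatch({
        sc <- call_hit(
          lapply(reps, function(r) trt_sc$rls[trt_sc$replicate == r]),
          lapply(reps, function(r) ctrl_sc$rls[ctrl_sc$replicate == r]),
          threshold_pct = cfg$hit_threshold_pct, alpha = cfg$alpha, gene = g)
        data.frame(gene = g, mean_rls_treatment = sc$mean_rls_treatment,
                   mean_rls_control = sc$mean_rls_control,
                   extension_pct = sc$extension_pct, p = sc$p, hit = sc$hit,
                   status = "ok")
      }, error = function(e)
        data.frame(gene = g, mean_rls_treatment = NA_real_,
                   mean_rls_control = NA_real_, extension_pct = NA_real_,
                   p = NA_real_, hit = NA, status = conditionMessage(e)))
      res
    })
    screen <- do.call(rbind, rows)
    rownames(screen) <- NULL
    utils::write.csv(screen, file.path(cfg$out_dir, "screen_calls.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "wormdemog",
    version = as.character(utils::packageVersion("wormdemog")),
    control = cfg$control, genes = genes, alpha = cfg$alpha,
    hit_threshold_pct = cfg$hit_threshold_pct, seed = cfg$seed,
    stages = cfg$stages,
    fit_bounds = list(M0 = c(1e-8, 1), G = c(0, 2), Minf = c(0, 1)),
    fit_tolerance = 1e-10)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(lifetables = lifetables, fits = fits_df,
                 comparisons = comparisons, screen = screen,
                 manifest = manifest))
}
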