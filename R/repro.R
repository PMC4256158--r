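#' Reproductive-span scoring from daily progeny schedules
#'
#' A progeny schedule is the daily count of live progeny for one
#' hermaphrodite. Interior zero-count days do not end the reproductive span
#' (animals are transferred until no progeny are scored for at least two
#' days, so single-day gaps are tolerated); the span ends at the final
#' nonzero day.
#'
#' \code{self_rls} scores the self-fertilising reproductive lifespan: the
#' first day of reproduction is indexed as day 1, so
#' RLS = last nonzero day - first nonzero day + 1.
#' \code{mated_cessation_day} returns the absolute last day of live progeny
#' production (the day of reproduction cessation in mated assays); these
#' per-individual days feed \code{\link{km_survival}} and
#' \code{\link{logrank_test}} as reproductive "survival" events.
#' \code{total_brood} is the total progeny over all days.
#'
#' @param schedule either a numeric vector of daily progeny counts (element
#'   i = day i) or a data.frame with columns \code{day} and
#'   \code{progeny_count}.
#' @return \code{self_rls}, \code{mated_cessation_day}: a day count;
#'   \code{total_brood}: a progeny count.
#' @examples
#' self_rls(c(0, 5, 3, 0, 2))          # first day 2, last day 5 -> RLS 4
#' mated_cessation_day(c(0, 5, 3, 0, 2))  # 5
#' total_brood(c(0, 5, 3, 0, 2))       # 10
#' @export
self_rls <- function(schedule) {
  counts <- schedule_counts(schedule)
  nz <- which(counts > 0)
  if (length(nz) == 0)
    stop("self_rls: no reproduction scored in schedule", call. = FALSE)
  max(nz) - min(nz) + 1L
}

#' @rdname self_rls
#' @export
mated_cessation_day <- function(schedule) {
  counts <- schedule_counts(schedule)
  nz <- which(counts > 0)
  if (length(nz) == 0)
    stop("mated_cessation_day: no reproduction scored in schedule", call. = FALSE)
  max(nz)
}

#' @rdname self_rls
#' @export
total_brood <- function(schedule) {
  sum(schedule_counts(schedule))
}

# normalise a schedule (vector or day/progeny_count data.frame) to a dense
# per-day count vector
schedule_counts <- function(schedule) {
  if (is.data.frame(schedule)) {
    if (!all(c("day", "progeny_count") %in% names(schedule)))
      stop("schedule data.frame needs columns 'day' and 'progeny_count'",
           call. = FALSE)
    if (any(schedule$day < 1))
      stop("schedule days must be >= 1", call. = FALSE)
    counts <- numeric(max(schedule$day))
    counts[schedule$day] <- counts[schedule$day] + schedule$progeny_count
    counts
  } else {
    as.numeric(schedule)
  }
}

#' Score every individual of a progeny table
#'
#' @param progeny data.frame with columns \code{individual_id}, \code{group},
#'   \code{replicate}, \code{day}, \code{progeny_count}.
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{group}, \code{replicate}, \code{rls}, \code{cessation_day},
#'   \code{total_brood}. Individuals with no progeny at all are dropped with
#'   a warning.
#' @export
score_progeny_table <- function(progeny) {
  required <- c("individual_id", "group", "replicate", "day", "progeny_count")
  if (!all(required %in% names(progeny)))
    stop("score_progeny_table: missing column(s): ",
         paste(setdiff(required, names(progeny)), collapse = ", "), call. = FALSE)
  key <- interaction(progeny$group, progeny$replicate, progeny$individual_id,
                     drop = TRUE)
  parts <- split(progeny, key)
  barren <- vapply(parts, function(p) all(p$progeny_count == 0), logical(1))
  if (any(barren)) {
    warning(sum(barren), " individual(s) with no progeny dropped from scoring")
    parts <- parts[!barren]
  }
  out <- lapply(parts, function(p) {
    data.frame(individual_id = p$individual_id[1], group = p$group[1],
               replicate = p$replicate[1],
               rls = self_rls(p[c("day", "progeny_count")]),
               cessation_day = mated_cessation_day(p[c("day", "progeny_count")]),
               total_brood = total_brood(p[c("day", "progeny_count")]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, res$replicate, res$individual_id), ]
}

#' Call a reproductive-lifespan screen hit
#'
#' A gene inactivation is a hit when it prolongs reproductive lifespan by
#' more than \code{threshold_pct} (computed from the means over all pooled
#' individuals) AND the treatment-vs-control Student t-test is significant
#' at \code{alpha} within every replicate experiment — the "scored positive
#' three times" rule (defaults: 3 replicates, 25\%, 0.05).
#'
#' @param treatment_rls,control_rls per-replicate reproductive lifespans:
#'   a list of numeric vectors (one per replicate, matched by position) with
#'   >= 2 individuals per arm per replicate.
#' @param threshold_pct minimum percent extension of mean RLS (default 25).
#' @param alpha per-replicate significance level (default 0.05).
#' @param gene label carried into the result.
#' @return An object of class \code{"screen_call"}: list with \code{gene},
#'   \code{mean_rls_treatment}, \code{mean_rls_control},
#'   \code{extension_pct}, \code{p} (largest per-replicate p-value, the one
#'   binding the call), \code{p_replicates}, \code{hit}.
#' @export
call_hit <- function(treatment_rls, control_rls, threshold_pct = 25,
                     alpha = 0.05, gene = NA_character_) {
  if (!is.list(treatment_rls)) treatment_rls <- list(treatment_rls)
  if (!is.list(control_rls)) control_rls <- list(control_rls)
  if (length(control_rls) == 0)
    stop("call_hit: missing control arm", call. = FALSE)
  if (length(treatment_rls) != length(control_rls))
    stop("call_hit: treatment and control must have the same number of replicates",
         call. = FALSE)
  p_rep <- mapply(function(t, c) two_sample_t(t, c)$p_raw,
                  treatment_rls, control_rls)
  mean_t <- mean(unlist(treatment_rls))
  mean_c <- mean(unlist(control_rls))
  ext <- 100 * (mean_t - mean_c) / mean_c
  structure(list(gene = gene, mean_rls_treatment = mean_t,
                 mean_rls_control = mean_c, extension_pct = ext,
                 p = max(p_rep), p_replicates = unname(p_rep),
                 hit = ext > threshold_pct && all(p_rep < alpha)),
            class = "screen_call")
}

#' @export
print.screen_call <- function(x, ...) {
  cat(sprintf("<screen_call> %s: RLS %.2f vs %.2f days (%+.1f%%), worst replicate p = %.3g -> %s\n",
              x$gene, x$mean_rls_treatment, x$mean_rls_control,
              x$extension_pct, x$p, if (x$hit) "HIT" else "not a hit"))
  invisible(x)
}

#' Classify pathway epistasis from mutant-background extension flags
#'
#' Given whether a gene inactivation still delays reproductive senescence in
#' the daf-2 (insulin/IGF-1 receptor), daf-16 (FOXO effector) and sma-2
#' (TGF-beta Smad) mutant backgrounds (wet-lab readouts supplied as flags,
#' not inferred here), assigns:
#'
#' insulin/IGF-1 (IIS) relation:
#' \itemize{
#'   \item \code{independent}: extends in both daf-2 and daf-16
#'   \item \code{non_additive_daf2}: extends in daf-16 but not daf-2
#'   \item \code{daf16_dependent_additive}: extends in daf-2 but not daf-16
#'   \item \code{fully_dependent}: extends in neither
#' }
#' pathway class:
#' \itemize{
#'   \item \code{independent_of_both}: IIS-independent and extends in sma-2
#'   \item \code{tgfb_specific}: IIS-independent but fails in sma-2
#'   \item \code{iis_specific}: IIS-interacting but extends in sma-2
#'   \item \code{both_pathways}: IIS-interacting and fails in sma-2
#' }
#'
#' @param extends_daf2,extends_daf16,extends_sma2 logical flags (vectorised,
#'   recycled to common length).
#' @param gene optional label(s).
#' @return data.frame with columns \code{gene}, \code{extends_daf2},
#'   \code{extends_daf16}, \code{extends_sma2}, \code{iis_relation},
#'   \code{pathway_class}.
#' @examples
#' classify_epistasis(TRUE, TRUE, TRUE)   # independent_of_both (nhx-2/sgk-1 class)
#' classify_epistasis(TRUE, TRUE, FALSE)  # tgfb_specific
#' @export
classify_epistasis <- function(extends_daf2, extends_daf16, extends_sma2,
                               gene = NA_character_) {
  n <- max(length(extends_daf2), length(extends_daf16), length(extends_sma2))
  d2 <- rep_len(as.logical(extends_daf2), n)
  d16 <- rep_len(as.logical(extends_daf16), n)
  sm <- rep_len(as.logical(extends_sma2), n)
  if (any(is.na(d2) | is.na(d16) | is.na(sm)))
    stop("classify_epistasis: flags must be TRUE/FALSE", call. = FALSE)
  iis <- ifelse(d2 & d16, "independent",
         ifelse(d16 & !d2, "non_additive_daf2",
         ifelse(!d16 & d2, "daf16_dependent_additive", "fully_dependent")))
  indep <- iis == "independent"
  pathway <- ifelse(indep & sm, "independent_of_both",
             ifelse(indep & !sm, "tgfb_specific",
             ifelse(!indep & sm, "iis_specific", "both_pathways")))
  data.frame(gene = rep_len(gene, n), extends_daf2 = d2, extends_daf16 = d16,
             extends_sma2 = sm, iis_relation = iis, pathway_class = pathway,
             stringsAsFactors = FALSE)
}
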