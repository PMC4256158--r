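# Four-record toy cohort used for hand-enumerated lifetable checks:
# deaths on days {1, 1, 2}, one censoring on day 2.
toy_events <- function(group = "ctrl", replicate = "1") {
  event_table(data.frame(
    individual_id = paste0("w", 1:4),
    group = group, replicate = replicate,
    event_day = c(1L, 1L, 2L, 2L),
    status = c("death", "death", "death", "censored")))
}

# event table with all deaths at given days, no censoring
deaths_at <- function(days, group = "g", replicate = "1") {
  event_table(data.frame(
    individual_id = paste0("w", seq_along(days)),
    group = group, replicate = replicate,
    event_day = as.integer(days), status = "death"))
}

# minimal converged gm_fit stand-ins for classification tests
fake_fit <- function(imr, roa, replicate = NA_character_) {
  structure(list(params = gm_params(imr, roa), IMR = imr, RoA = roa,
                 rss = 0, n_points = 0L, converged = TRUE,
                 group = NA_character_, replicate = replicate),
            class = "gm_fit")
}

fake_replicate_fits <- function(imr, roa) {
  summarize_replicates(Map(fake_fit, imr, roa))
}

fake_comparison <- function(p, pct, test_name = "t_test") {
  structure(list(statistic = 0, p_raw = p, p_adjusted = p,
                 percent_change = pct, test_name = test_name),
            class = "comparison_result")
}

# brute-force Holm step-down straight from the definition
holm_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, v)
    adj[ord[i]] <- running
  }
  adj
}
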