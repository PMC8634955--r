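# Monte-Carlo sensitivity over transition-probability confidence intervals ----
#
# Each sensitivity run redraws every sampled flow's probability from within
# its 95% confidence interval (uniform by default; a truncated normal with
# sd = CI width / 3.92 is offered as an option) and re-runs the projection.
# Draws come from one seeded stream in a documented deterministic order
# (row-major within a run, runs in sequence), so a run list is reproducible
# from its seed alone.

sample_one_table <- function(rates, u, sampling) {
  lo <- pmax(0, rates$lo95)
  hi <- pmin(1, rates$hi95)
  if (sampling == "uniform") {
    val <- lo + u * (hi - lo)
  } else {
    sdv <- (rates$hi95 - rates$lo95) / 3.92
    val <- ifelse(
      sdv > 0,
      qnorm(pnorm(lo, rates$mean, pmax(sdv, 1e-12)) +
              u * (pnorm(hi, rates$mean, pmax(sdv, 1e-12)) -
                     pnorm(lo, rates$mean, pmax(sdv, 1e-12))),
            rates$mean, pmax(sdv, 1e-12)),
      rates$mean
    )
  }
  val <- pmin(pmax(val, lo), hi)
  rates$mean <- val
  rates
}

#' Draw sensitivity replicates of a rate table
#'
#' Produces `n_runs` copies of `rates` in which every sampled flow's mean is
#' redrawn independently per run from within `[lo95, hi95]` (clamped to
#' `[0, 1]`); unsampled flows keep their means.  Sampling is reproducible:
#' one `set.seed(seed)` stream supplies all draws, consumed row-by-row within
#' a run and run-by-run in order.
#'
#' @param rates A [rate_table()].
#' @param n_runs Number of replicates (the reference procedure uses 1,000).
#' @param seed Integer seed.
#' @param sampling `"uniform"` on the CI (default) or `"truncated_normal"`
#'   (mean-centred, sd = CI width / 3.92).
#' @param rows Optional logical or integer index of table rows to sample;
#'   default all rows.
#' @return A list of `n_runs` [rate_table()]s.
#' @export
sample_rate_tables <- function(rates, n_runs, seed,
                               sampling = c("uniform", "truncated_normal"),
                               rows = NULL) {
  sampling <- match.arg(sampling)
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  products <- rate_products(rates)
  if (is.null(rows)) rows <- seq_len(nrow(rates))
  if (is.logical(rows)) rows <- which(rows)
  sub <- rates[rows, ]
  u <- with_seed(seed, matrix(runif(length(rows) * n_runs), nrow = length(rows)))
  lapply(seq_len(n_runs), function(i) {
    out <- rates
    out[rows, ] <- sample_one_table(sub, u[, i], sampling)
    new_rate_table(out, products)
  })
}

#' Run the Monte-Carlo sensitivity analysis
#'
#' Redraws the scenario's transition probabilities within their 95% CIs
#' ([sample_rate_tables()]) and re-runs the projection `n_runs` times,
#' recording smoking prevalence, alternative-product prevalence and the
#' life-years-lost reduction versus the baseline at `at_year`.
#'
#' @param bundle An [input_bundle()].
#' @param scen The [scenario()] whose rates are sampled.
#' @param baseline A baseline `projection_result` run over at least the same
#'   horizon (deterministic, not resampled).
#' @param n_runs Number of runs.
#' @param seed Integer seed.
#' @param start_year,end_year Projection horizon per run.
#' @param at_year Year at which the outputs are read (default `end_year`).
#' @param sampling Passed to [sample_rate_tables()].
#' @return A tibble of class `sensitivity_runs` with one row per run:
#'   `run, smoking_prevalence, prrp_prevalence, lyl_reduction_m`.
#' @export
run_sensitivity <- function(bundle, scen, baseline, n_runs = 1000L, seed = 1L,
                            start_year = 2001L, end_year = 2050L,
                            at_year = end_year,
                            sampling = c("uniform", "truncated_normal")) {
  sampling <- match.arg(sampling)
  tables <- sample_rate_tables(scen$rates, n_runs, seed, sampling)
  j <- match(at_year, baseline$series$year)
  if (is.na(j)) abort("`at_year` must lie inside the baseline's horizon.")
  base_lyl <- baseline$series$cum_life_years_lost[j]
  rows <- lapply(seq_len(n_runs), function(i) {
    scen_i <- scen
    scen_i$rates <- tables[[i]]
    r <- run_scenario(bundle, scen_i, start_year, end_year)
    k <- match(at_year, r$series$year)
    tibble::tibble(
      run = i,
      smoking_prevalence = r$series$smoking_prevalence[k],
      prrp_prevalence = r$series$prrp_prevalence[k],
      lyl_reduction_m = (base_lyl - r$series$cum_life_years_lost[k]) / 1e6
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "at_year") <- at_year
  attr(out, "seed") <- seed
  attr(out, "sampling") <- sampling
  class(out) <- c("sensitivity_runs", class(out))
  out
}

#' Summarise sensitivity runs
#'
#' For each recorded output, reports min, max, mean, median, standard
#' deviation, the lower-tail percentiles (linear interpolation between order
#' statistics, `stats::quantile` type 7), and the fraction of runs in which
#' the value is negative (for the life-years-lost reduction this is the share
#' of runs where the product increases life-years lost).
#'
#' @param runs A `sensitivity_runs` tibble (or any tibble of per-run metric
#'   columns plus an optional `run` column).
#' @param probs Percentile levels (default 5/10/15/20/25%).
#' @return A tibble with one row per metric.
#' @export
summarize_runs <- function(runs, probs = c(0.05, 0.10, 0.15, 0.20, 0.25)) {
  metrics <- setdiff(names(runs), "run")
  out <- lapply(metrics, function(m) {
    x <- runs[[m]]
    qs <- quantile(x, probs = probs, type = 7, names = FALSE)
    row <- tibble::tibble(
      metric = m, min = min(x), max = max(x), mean = mean(x),
      median = median(x), sd = if (length(x) > 1) sd(x) else 0,
      share_negative = mean(x < 0)
    )
    for (k in seq_along(probs)) {
      row[[sprintf("p%g", 100 * probs[k])]] <- qs[k]
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Plot the distribution of sensitivity runs
#'
#' @param object A `sensitivity_runs` tibble.
#' @param ... Unused.
#' @return A ggplot of per-metric histograms.
#' @export
autoplot.sensitivity_runs <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"run",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Runs") +
    ggplot2::theme_minimal()
}
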