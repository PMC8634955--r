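# Broom-style and plotting methods ---------------------------------------------

#' @export
print.projection_result <- function(x, ...) {
  s <- x$series
  cat(sprintf("<projection_result> '%s' (%s), %d-%d\n",
              x$scenario, paste(x$products, collapse = " + "),
              x$start_year, x$end_year))
  cat(sprintf("  smoking prevalence (14+): %.1f%% -> %.1f%%\n",
              s$smoking_prevalence[1], tail(s$smoking_prevalence, 1)))
  if (length(x$products) > 1L) {
    cat(sprintf("  PRRP prevalence (14+):    %.1f%% -> %.1f%%\n",
                s$prrp_prevalence[1], tail(s$prrp_prevalence, 1)))
  }
  cat(sprintf("  cumulative life-years lost: %.2f million\n",
              tail(s$cum_life_years_lost, 1) / 1e6))
  invisible(x)
}

#' Tidy a projection result
#'
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return A long tibble `scenario, year, metric, value`.
#' @export
tidy.projection_result <- function(x, ...) {
  x$series |>
    tidyr::pivot_longer(-"year", names_to = "metric", values_to = "value") |>
    dplyr::mutate(scenario = x$scenario, .before = 1)
}

#' One-row summary of a projection result
#'
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.projection_result <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    scenario = x$scenario,
    n_products = length(x$products),
    start_year = x$start_year, end_year = x$end_year,
    smoking_prevalence_start = s$smoking_prevalence[1],
    smoking_prevalence_end = tail(s$smoking_prevalence, 1),
    prrp_prevalence_end = tail(s$prrp_prevalence, 1),
    cum_life_years_lost_m = tail(s$cum_life_years_lost, 1) / 1e6,
    max_conservation_residual = max(abs(s$conservation_residual))
  )
}

#' Plot a projection result
#'
#' @param object A `projection_result`.
#' @param type `"prevalence"` (per-product age-14+ prevalence over time) or
#'   `"life_years_lost"` (cumulative).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.projection_result <- function(object, type = c("prevalence", "life_years_lost"),
                                       ...) {
  type <- match.arg(type)
  s <- object$series
  if (type == "prevalence") {
    cols <- c("smoking_prevalence",
              paste0("prevalence_", object$products[-1]))
    df <- s |>
      dplyr::select("year", dplyr::all_of(cols)) |>
      tidyr::pivot_longer(-"year", names_to = "product", values_to = "prevalence") |>
      dplyr::mutate(product = sub("^(smoking_)?prevalence_?", "", .data$product),
                    product = ifelse(.data$product == "", object$products[1], .data$product))
    ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$prevalence,
                                     colour = .data$product)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "Year", y = "Prevalence, age 14+ (%)", colour = "Product",
                    title = object$scenario) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(s, ggplot2::aes(.data$year, .data$cum_life_years_lost / 1e6)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "Year", y = "Cumulative life-years lost (million)",
                    title = object$scenario) +
      ggplot2::theme_minimal()
  }
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison vs baseline '%s' (%s life-years accounting)\n",
              attr(x, "baseline"), attr(x, "lyl_mode")))
  for (metric in c("smoking_prevalence", "prrp_prevalence", "lyl_reduction_m")) {
    label <- switch(metric,
      smoking_prevalence = "Smoking prevalence (%)",
      prrp_prevalence = "PRRP prevalence (%)",
      lyl_reduction_m = "Reduction of life-years lost (million)")
    cat("\n", label, "\n", sep = "")
    wide <- tidyr::pivot_wider(
      x[, c("scenario", "year", metric)],
      names_from = "year",
      values_from = dplyr::all_of(metric)
    )
    wide[-1] <- lapply(wide[-1], round, 1)
    print(as.data.frame(wide), row.names = FALSE)
  }
  invisible(x)
}

#' Plot a scenario comparison
#'
#' @param object A `scenario_comparison` from [compare_scenarios()].
#' @param metric Column to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_comparison <- function(object,
                                         metric = c("smoking_prevalence",
                                                    "prrp_prevalence",
                                                    "lyl_reduction_m"),
                                         ...) {
  metric <- match.arg(metric)
  ylab <- switch(metric,
    smoking_prevalence = "Smoking prevalence, age 14+ (%)",
    prrp_prevalence = "PRRP prevalence, age 14+ (%)",
    lyl_reduction_m = "Reduction of life-years lost (million)")
  ggplot2::ggplot(object, ggplot2::aes(.data$year, .data[[metric]],
                                       colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Year", y = ylab, colour = "Scenario") +
    ggplot2::theme_minimal()
}
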