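# Transition probabilities -----------------------------------------------------
#
# Rates are annual transition probabilities (not instantaneous hazards),
# applied once per one-year step.  A rate table stores a (mean, lo95, hi95)
# triple per flow x gender x age band x year; "*" genders and NA years apply
# everywhere, and age bands are expanded by repetition.  Scenario modifiers
# gate flows before a product's market-introduction year and optionally decay
# cigarette initiation geometrically from a start year.

#' Construct a validated transition-rate table
#'
#' @param entries Data frame with columns `from`, `to` (state labels as in
#'   [enumerate_states()]), `gender` (`"male"`, `"female"` or `"*"`),
#'   `age_lo`, `age_hi` (inclusive band, 0-100), optional `year` (`NA` =
#'   all years), and probabilities `mean`, `lo95`, `hi95` with
#'   `0 <= lo95 <= mean <= hi95 <= 1`.  Flows absent from the table default
#'   to probability 0.
#' @param products Product labels defining the state space (first =
#'   cigarette).
#' @return A tibble of class `rate_table` with a `products` attribute.
#' @export
rate_table <- function(entries, products) {
  entries <- tibble::as_tibble(entries)
  need <- c("from", "to", "gender", "age_lo", "age_hi", "mean", "lo95", "hi95")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols) > 0L) {
    abort(paste0("rate table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"year" %in% names(entries)) entries$year <- NA_integer_
  entries <- entries[, c("from", "to", "gender", "age_lo", "age_hi", "year",
                         "mean", "lo95", "hi95")]
  entries$age_lo <- as.integer(entries$age_lo)
  entries$age_hi <- as.integer(entries$age_hi)
  entries$year <- as.integer(entries$year)
  flows <- enumerate_flows(enumerate_states(length(products), products))
  key <- paste(entries$from, entries$to, sep = ">")
  bad <- !key %in% paste(flows$from, flows$to, sep = ">")
  if (any(bad)) {
    abort(paste0("rate table rows reference inadmissible flows: ",
                 paste(unique(key[bad]), collapse = ", ")))
  }
  if (!all(entries$gender %in% c(GENDERS, "*"))) {
    abort("rate table `gender` must be 'male', 'female' or '*'.")
  }
  if (any(entries$age_lo < 0 | entries$age_hi > 100 | entries$age_lo > entries$age_hi)) {
    abort("rate table age bands must satisfy 0 <= age_lo <= age_hi <= 100.")
  }
  probs <- as.matrix(entries[, c("lo95", "mean", "hi95")])
  if (anyNA(probs) || any(probs < 0) || any(probs > 1) ||
      any(entries$lo95 > entries$mean + 1e-12) || any(entries$mean > entries$hi95 + 1e-12)) {
    abort("rate table probabilities must satisfy 0 <= lo95 <= mean <= hi95 <= 1.")
  }
  new_rate_table(entries, products)
}

new_rate_table <- function(entries, products) {
  attr(entries, "products") <- products
  class(entries) <- unique(c("rate_table", class(entries)))
  entries
}

rate_products <- function(rates) attr(rates, "products")

#' Scenario modifiers: introduction years and initiation decline
#'
#' @param intro_year Named numeric vector of market-introduction years per
#'   product; every flow changing a product is forced to zero before that
#'   product's introduction.  Products not named are available from the model
#'   start (`-Inf`); the cigarette always is.
#' @param init_decline_rate Annual fractional decline of cigarette initiation
#'   (e.g. `0.03` for 3% per year); `0` disables the decline.
#' @param init_decline_start First year the decline applies; the multiplier is
#'   `(1 - rate)^(year - start)` for `year >= start` and 1 before.
#' @return A list of class `scenario_modifiers`.
#' @export
scenario_modifiers <- function(intro_year = NULL, init_decline_rate = 0,
                               init_decline_start = 2020L) {
  if (init_decline_rate < 0 || init_decline_rate >= 1) {
    abort("`init_decline_rate` must lie in [0, 1).")
  }
  structure(
    list(intro_year = intro_year,
         init_decline_rate = init_decline_rate,
         init_decline_start = as.integer(init_decline_start)),
    class = "scenario_modifiers"
  )
}

mods_intro <- function(mods, products) {
  intro <- setNames(rep(-Inf, length(products)), products)
  if (!is.null(mods$intro_year)) {
    known <- intersect(names(mods$intro_year), products)
    intro[known] <- mods$intro_year[known]
  }
  intro[1] <- -Inf # the cigarette market exists from the model start
  intro
}

init_decline_multiplier <- function(mods, year) {
  if (mods$init_decline_rate <= 0 || year < mods$init_decline_start) return(1)
  (1 - mods$init_decline_rate)^(year - mods$init_decline_start)
}

# Base [gender, age, flow] array of mean probabilities from the all-year rows;
# specific genders override "*", later rows override earlier ones.
rt_base_array <- function(entries, flows) {
  arr <- array(0, dim = c(2L, 101L, nrow(flows)),
               dimnames = list(gender = GENDERS, age = AGES, flow = flows$flow_id))
  fidx <- match(paste(entries$from, entries$to, sep = ">"),
                paste(flows$from, flows$to, sep = ">"))
  ord <- order(entries$gender != "*") # "*" rows first so specific rows win
  for (i in ord) {
    ages <- (entries$age_lo[i]:entries$age_hi[i]) + 1L
    gs <- if (entries$gender[i] == "*") GENDERS else entries$gender[i]
    arr[gs, ages, fidx[i]] <- entries$mean[i]
  }
  arr
}

# Effective [gender, age, flow] mean probabilities for one year: year-specific
# rows override the all-year base, then introduction gates, the initiation
# decline and per-stock outflow normalisation are applied.
rt_effective_array <- function(rates, flows, year, mods, normalize = TRUE,
                               base = NULL) {
  products <- rate_products(rates)
  if (is.null(base)) base <- rt_base_array(rates[is.na(rates$year), ], flows)
  arr <- base
  yr_rows <- rates[!is.na(rates$year) & rates$year == year, ]
  if (nrow(yr_rows) > 0L) {
    fidx <- match(paste(yr_rows$from, yr_rows$to, sep = ">"),
                  paste(flows$from, flows$to, sep = ">"))
    ord <- order(yr_rows$gender != "*")
    for (i in ord) {
      ages <- (yr_rows$age_lo[i]:yr_rows$age_hi[i]) + 1L
      gs <- if (yr_rows$gender[i] == "*") GENDERS else yr_rows$gender[i]
      arr[gs, ages, fidx[i]] <- yr_rows$mean[i]
    }
  }
  intro <- mods_intro(mods, products)
  changed <- strsplit(flows$changed, "+", fixed = TRUE)
  for (f in seq_len(nrow(flows))) {
    idx <- as.integer(changed[[f]])
    if (any(year < intro[idx])) arr[, , f] <- 0
  }
  mult <- init_decline_multiplier(mods, year)
  if (mult != 1) {
    move1 <- flows[[paste0("move_", products[1])]]
    arr[, , which(move1 == "initiate")] <- arr[, , which(move1 == "initiate")] * mult
  }
  if (normalize) {
    for (s in unique(flows$from_id)) {
      idx <- which(flows$from_id == s)
      tot <- apply(arr[, , idx, drop = FALSE], c(1, 2), sum)
      if (any(tot > 1)) {
        fac <- ifelse(tot > 1, 1 / tot, 1)
        arr[, , idx] <- arr[, , idx, drop = FALSE] * as.vector(fac)
      }
    }
  }
  arr
}

#' Effective transition probability for one flow
#'
#' Resolves the table entry for a flow at a given gender, age and year
#' (specific genders and years take precedence over `"*"`/all-year rows,
#' missing flows default to 0) and applies the scenario modifiers: the
#' introduction-year gate of every product the flow changes, and the
#' geometric cigarette-initiation decline.  Per-stock outflow normalisation is
#' a separate step ([normalize_outflows()]).
#'
#' @param rates A [rate_table()].
#' @param from,to State labels identifying the flow.
#' @param gender `"male"` or `"female"`.
#' @param age Single age in 0-100.
#' @param year Calendar year.
#' @param mods A [scenario_modifiers()].
#' @return A single probability.
#' @export
effective_rate <- function(rates, from, to, gender, age, year,
                           mods = scenario_modifiers()) {
  products <- rate_products(rates)
  flows <- enumerate_flows(enumerate_states(length(products), products))
  f <- which(flows$from == from & flows$to == to)
  if (length(f) != 1L) abort(sprintf("no admissible flow %s -> %s.", from, to))
  arr <- rt_effective_array(rates, flows, year, mods, normalize = FALSE)
  arr[gender, as.character(age), f]
}

#' Blend two rate tables into a pseudo-product table
#'
#' Forms the transition table of a synthetic "pseudo-PRRP" by taking the
#' weighted average, row by row, of two structurally identical two-product
#' tables (cigarette + one PRRP each): every `mean`, `lo95` and `hi95` becomes
#' `weight_A * A + (1 - weight_A) * B`.  CI bounds are blended with the same
#' weights as the means.
#'
#' @param table_A,table_B [rate_table()]s over the same flow structure and the
#'   same `(from, to, gender, age band, year)` keys.
#' @param weight_A Weight on `table_A` in `[0, 1]`.
#' @param products Product labels for the blended table; defaults to
#'   `table_A`'s labels when the two tables agree, else
#'   `c(<cigarette>, "pseudo_prrp")`.
#' @return A [rate_table()].
#' @export
combine_pseudo_prrp <- function(table_A, table_B, weight_A, products = NULL) {
  if (weight_A < 0 || weight_A > 1) abort("`weight_A` must lie in [0, 1].")
  pa <- rate_products(table_A); pb <- rate_products(table_B)
  if (length(pa) != length(pb)) {
    abort("the two tables must describe the same number of products.")
  }
  key <- function(t) paste(t$from, t$to, t$gender, t$age_lo, t$age_hi, t$year, sep = "|")
  a <- table_A[order(key(table_A)), ]
  b <- table_B[order(key(table_B)), ]
  if (nrow(a) != nrow(b) || !identical(key(a), key(b))) {
    abort("the two tables must share an identical set of flow/gender/age/year rows.")
  }
  if (is.null(products)) {
    products <- if (identical(pa, pb)) pa else c(pa[1], "pseudo_prrp")
  }
  out <- a
  for (col in c("mean", "lo95", "hi95")) {
    out[[col]] <- weight_A * a[[col]] + (1 - weight_A) * b[[col]]
  }
  new_rate_table(out, products)
}

#' Blend two excess-risk fractions into a pseudo-product fraction
#'
#' The pseudo-PRRP's risk, as a fraction of the combustible cigarette's excess
#' risk, is the weighted average of the two component products' fractions.
#'
#' @param f_A,f_B Excess-risk fractions in `[0, 1]` (e.g. 0.05 and 0.10).
#' @param weight_A Weight on `f_A` in `[0, 1]`.
#' @return A fraction: `weight_A * f_A + (1 - weight_A) * f_B`.
#' @examples
#' combine_pseudo_risk(0.05, 0.10, 0.5) # 0.075
#' @export
combine_pseudo_risk <- function(f_A, f_B, weight_A) {
  if (weight_A < 0 || weight_A > 1) abort("`weight_A` must lie in [0, 1].")
  if (any(c(f_A, f_B) < 0) || any(c(f_A, f_B) > 1)) {
    abort("excess-risk fractions must lie in [0, 1].")
  }
  weight_A * f_A + (1 - weight_A) * f_B
}

#' Normalise per-stock outflow probabilities
#'
#' Wherever the mean outflow probabilities leaving one stock for one (gender,
#' age, year) sum to `S > 1`, all of that stock's outflows (means and CI
#' bounds alike) are scaled by `1/S`.  Age bands are expanded to single ages
#' first, so the returned table has `age_lo == age_hi` rows.
#'
#' @param rates A [rate_table()].
#' @return A [rate_table()] with single-age rows; a message reports how many
#'   (stock, gender, age, year) groups were rescaled.
#' @export
normalize_outflows <- function(rates) {
  products <- rate_products(rates)
  if (nrow(rates) == 0L) return(rates)
  expanded <- rates |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::mutate(age = list(.data$age_lo:.data$age_hi),
                  g = list(if (.data$gender == "*") GENDERS else .data$gender)) |>
    dplyr::ungroup() |>
    tidyr::unnest("age") |>
    tidyr::unnest("g") |>
    dplyr::mutate(gender = .data$g, age_lo = .data$age, age_hi = .data$age) |>
    dplyr::select(-"g", -"age", -".row")
  expanded <- expanded |>
    dplyr::group_by(.data$from, .data$gender, .data$age_lo, .data$year) |>
    dplyr::mutate(.S = sum(.data$mean)) |>
    dplyr::ungroup()
  n_scaled <- expanded |>
    dplyr::filter(.data$.S > 1) |>
    dplyr::distinct(.data$from, .data$gender, .data$age_lo, .data$year) |>
    nrow()
  if (n_scaled > 0L) {
    inform(sprintf("normalize_outflows: rescaled outflows in %d (stock, gender, age, year) group(s) whose means summed above 1.", n_scaled))
  }
  fac <- ifelse(expanded$.S > 1, 1 / expanded$.S, 1)
  for (col in c("mean", "lo95", "hi95")) expanded[[col]] <- expanded[[col]] * fac
  expanded$.S <- NULL
  new_rate_table(expanded, products)
}

#' Calibrate initiation hazards from an ever-use prevalence curve
#'
#' Converts a cross-sectional ever-smoking prevalence curve `E(a)` into annual
#' initiation probabilities via the discrete hazard
#' `h(a) = (E(a + 1) - E(a)) / (1 - E(a))`, floored at zero, inside a
#' configurable initiation age window (zero outside).  Simulating a
#' never/ever cohort with these hazards reproduces the input curve.
#'
#' @param ever_prevalence Tibble `gender, age, ever` (fractions `< 1`) covering
#'   at least the window plus one year.
#' @param age_window Inclusive ages at which initiation can occur (default
#'   11-30).
#' @return Tibble `gender, age, initiation` over the window ages.
#' @export
calibrate_initiation_from_prevalence <- function(ever_prevalence,
                                                 age_window = c(11L, 30L)) {
  if (any(ever_prevalence$ever >= 1)) {
    abort("ever-prevalence must be < 1 at every age (a hazard cannot absorb everyone).")
  }
  ages <- age_window[1]:age_window[2]
  out <- lapply(unique(ever_prevalence$gender), function(g) {
    sub <- ever_prevalence[ever_prevalence$gender == g, ]
    E <- setNames(sub$ever, as.character(sub$age))
    need <- as.character(c(ages, age_window[2] + 1L))
    if (!all(need %in% names(E))) {
      abort(sprintf("ever-prevalence for gender %s must cover ages %d-%d.",
                    g, age_window[1], age_window[2] + 1L))
    }
    h <- (E[as.character(ages + 1L)] - E[as.character(ages)]) /
      (1 - E[as.character(ages)])
    if (any(h < 0)) {
      warn("ever-prevalence decreases across some ages; hazards floored at 0.")
      h <- pmax(h, 0)
    }
    tibble::tibble(gender = g, age = ages, initiation = unname(h))
  })
  dplyr::bind_rows(out)
}

#' Default relapse decline over quit-time bins
#'
#' The base cigarette relapse probability is multiplied by a per-bin factor
#' that declines geometrically with years abstinent (factor 1 in bin 1).
#'
#' @param ratio Geometric ratio per additional year abstinent.
#' @return Named vector over bins `"1"..."20", "20+"`.
#' @export
default_relapse_multiplier <- function(ratio = 0.75) {
  setNames(ratio^(0:20), QUIT_BINS[-(1:2)])
}

# Expand a bin-level relapse multiplier to the full internal bin axis
# ("none" and the transient "0" bin carry factor 1; neither is ever queried
# by a relapse flow).
relapse_mult_full <- function(mult) {
  full <- setNames(rep(1, length(QUIT_BINS)), QUIT_BINS)
  full[names(mult)] <- mult
  full
}
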