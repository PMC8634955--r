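# Simulation engine ------------------------------------------------------------
#
# One-year-step loop over 2001-2100 with a fixed, audited sub-step order:
# (1) status-specific mortality, (2) product transitions applied to survivors,
# (3) ageing + quit-clock advance, (4) births, (5) net migration.  The
# never-smoker mortality baseline is derived once per (gender, age) at model
# initialisation from the initial product-status composition and rescaled with
# the life table thereafter; this avoids circularity as prevalence evolves.

#' Bundle the model inputs
#'
#' @param pyramid Tibble `gender, age, count` (ages 0-100).
#' @param life_table A [life_table()].
#' @param prevalence Tibble `gender, age, current, former` cigarette-smoking
#'   fractions.
#' @param quit_time Tibble `bin, share` quit-time distribution of former
#'   smokers.
#' @param births Tibble `gender, year, count`.
#' @param migration_total Tibble `year, count` (net persons per year).
#' @param migration_age Tibble `gender, age, share` summing to 1.
#' @param risk A [risk_model()].
#' @param relapse_multiplier Named per-bin relapse decline vector
#'   ([default_relapse_multiplier()]).
#' @param rates Optional named list of [rate_table()]s shipped with the
#'   bundle.
#' @return A list of class `input_bundle`.
#' @export
input_bundle <- function(pyramid, life_table, prevalence, quit_time, births,
                         migration_total, migration_age, risk,
                         relapse_multiplier = default_relapse_multiplier(),
                         rates = list()) {
  if (abs(sum(migration_age$share) - 1) > 1e-6 && nrow(migration_age) > 0 &&
      sum(migration_age$share) > 0) {
    abort("`migration_age` shares must sum to 1.")
  }
  structure(
    list(pyramid = tibble::as_tibble(pyramid), life_table = life_table,
         prevalence = tibble::as_tibble(prevalence),
         quit_time = tibble::as_tibble(quit_time),
         births = tibble::as_tibble(births),
         migration_total = tibble::as_tibble(migration_total),
         migration_age = tibble::as_tibble(migration_age),
         risk = risk, relapse_multiplier = relapse_multiplier, rates = rates),
    class = "input_bundle"
  )
}

bundle_schedules <- function(bundle) {
  list(births = bundle$births, migration_total = bundle$migration_total,
       migration_age = bundle$migration_age)
}

#' Define a market scenario
#'
#' @param name Scenario label.
#' @param rates A [rate_table()]; its products define the state space.
#' @param modifiers A [scenario_modifiers()].
#' @param prrp_excess_fraction Optional named overrides of the bundle risk
#'   model's per-product excess-risk fractions (e.g. `c(pseudo_prrp = 0.075)`).
#' @return A list of class `tobacco_scenario`.
#' @export
scenario <- function(name, rates, modifiers = scenario_modifiers(),
                     prrp_excess_fraction = NULL) {
  structure(
    list(name = name, rates = rates, modifiers = modifiers,
         prrp_excess_fraction = prrp_excess_fraction),
    class = "tobacco_scenario"
  )
}

## Internal context -------------------------------------------------------------

new_sim_context <- function(pop, rates, lifetable, riskmodel, schedules, mods,
                            relapse_multiplier) {
  states <- pop$states
  products <- pop$products
  flows <- enumerate_flows(states)
  rr_arr <- state_rr_array(states, riskmodel)
  lt0 <- lt_arrays(lifetable, pop$year)
  m_never <- derive_never_mortality_array(pop$counts, rr_arr, lt0$mortality)

  move1 <- flows[[paste0("move_", products[1])]]
  routing <- ifelse(is.na(move1), "keep",
                    ifelse(move1 == "quit", "quit",
                           ifelse(move1 == "relapse", "relapse", "keep")))
  changed_idx <- lapply(strsplit(flows$changed, "+", fixed = TRUE), as.integer)
  out_idx <- split(seq_len(nrow(flows)), flows$from_id)

  share <- matrix(0, 2, 101, dimnames = list(gender = GENDERS, age = AGES))
  ma <- schedules$migration_age
  for (i in seq_len(nrow(ma))) share[ma$gender[i], as.character(ma$age[i])] <- ma$share[i]

  env <- new.env(parent = emptyenv())
  list(states = states, products = products, flows = flows,
       rates = rates, base = rt_base_array(rates[is.na(rates$year), ], flows),
       has_year_rows = any(!is.na(rates$year)),
       routing = routing, changed_idx = changed_idx, out_idx = out_idx,
       init_flows = which(move1 == "initiate"),
       relapse_full = relapse_mult_full(relapse_multiplier),
       rr_arr = rr_arr, m_never = m_never, m0 = lt0$mortality,
       lifetable = lifetable, schedules = schedules, mods = mods,
       intro = mods_intro(mods, products),
       all_never = state_label(rep("never", length(products))),
       mig_share = share, cache = env)
}

ctx_death_probs <- function(ctx, year) {
  lt <- lt_arrays(ctx$lifetable, year)
  key <- paste0("d", lt$year)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  scale <- ifelse(ctx$m0 > 0, lt$mortality / ctx$m0, 1)
  d <- death_prob_array(ctx$m_never * scale, ctx$rr_arr)
  ctx$cache[[key]] <- list(d = d, ex = lt$life_expectancy)
  ctx$cache[[key]]
}

ctx_rate_array <- function(ctx, year) {
  if (ctx$has_year_rows) {
    return(rt_effective_array(ctx$rates, ctx$flows, year, ctx$mods,
                              normalize = TRUE, base = ctx$base))
  }
  arr <- ctx$base
  for (f in seq_len(nrow(ctx$flows))) {
    if (any(year < ctx$intro[ctx$changed_idx[[f]]])) arr[, , f] <- 0
  }
  mult <- init_decline_multiplier(ctx$mods, year)
  if (mult != 1 && length(ctx$init_flows) > 0L) {
    arr[, , ctx$init_flows] <- arr[, , ctx$init_flows] * mult
  }
  for (idx in ctx$out_idx) {
    tot <- rowSums(arr[, , idx, drop = FALSE], dims = 2)
    if (any(tot > 1)) {
      fac <- ifelse(tot > 1, 1 / tot, 1)
      arr[, , idx] <- arr[, , idx, drop = FALSE] * as.vector(fac)
    }
  }
  arr
}

# One simulated year on a raw counts array.  Returns the new counts plus the
# reconciliation terms for the conservation diagnostic.
ctx_step <- function(ctx, counts, year) {
  dp <- ctx_death_probs(ctx, year)
  deaths <- counts * dp$d
  counts <- counts - deaths
  deaths_ga <- rowSums(deaths, dims = 2)

  p_arr <- ctx_rate_array(ctx, year)
  delta <- array(0, dim = dim(counts))
  nQ <- length(QUIT_BINS)
  for (f in seq_len(nrow(ctx$flows))) {
    pf <- p_arr[, , f]
    if (all(pf == 0)) next
    from <- ctx$flows$from_id[f]; to <- ctx$flows$to_id[f]
    moved <- counts[, , from, ] * as.vector(pf)
    if (ctx$routing[f] == "relapse") {
      moved <- moved * rep(ctx$relapse_full, each = 202L)
    }
    delta[, , from, ] <- delta[, , from, ] - moved
    if (ctx$routing[f] == "keep") {
      delta[, , to, ] <- delta[, , to, ] + moved
    } else if (ctx$routing[f] == "quit") {
      delta[, , to, 2L] <- delta[, , to, 2L] + rowSums(moved, dims = 2) # bin "0"
    } else {
      delta[, , to, 1L] <- delta[, , to, 1L] + rowSums(moved, dims = 2) # bin "none"
    }
  }
  counts <- counts + delta

  sh <- shift_ages(counts)
  counts <- sh$counts

  b <- births_for_year(ctx$schedules$births, year)
  counts[, 1L, ctx$all_never, 1L] <- counts[, 1L, ctx$all_never, 1L] + b

  mt <- ctx$schedules$migration_total
  yr <- lt_pick_year(mt$year, year)
  net <- if (is.na(yr)) 0 else mt$count[mt$year == yr][1]
  mig <- apply_migration_counts(counts, net * ctx$mig_share, ctx$all_never)
  counts <- mig$counts

  list(counts = counts, deaths_ga = deaths_ga, ex = dp$ex,
       births = sum(b), mig_applied = mig$applied, mig_clamped = mig$clamped,
       aged_out = sh$aged_out)
}

prevalence_from_counts <- function(counts, states, product, min_age = 14,
                                   dual = c("inclusive", "exclusive")) {
  dual <- match.arg(dual)
  ages <- (min_age:100) + 1L
  elig <- sum(counts[, ages, , ])
  if (elig <= 0) return(0)
  statuses <- as.matrix(states[, state_products(states), drop = FALSE])
  p <- match(product, state_products(states))
  sel <- statuses[, p] == "current"
  if (dual == "exclusive") {
    others <- statuses[, -p, drop = FALSE]
    sel <- sel & rowSums(others == "current") == 0L
  }
  100 * sum(counts[, ages, which(sel), ]) / elig
}

## Public operations ------------------------------------------------------------

#' Advance a population by one simulated year
#'
#' Applies the engine's fixed sub-step order (mortality, transitions, ageing,
#' births, migration) once.
#'
#' @param pop A `population_state`.
#' @param rates A [rate_table()] over `pop`'s products.
#' @param lifetable A [life_table()].
#' @param riskmodel A [risk_model()].
#' @param schedules List with `births`, `migration_total`, `migration_age`.
#' @param year Calendar year to simulate (defaults to `pop$year`).
#' @param mods A [scenario_modifiers()].
#' @param relapse_multiplier Per-bin relapse decline
#'   ([default_relapse_multiplier()]).
#' @param never_rate Optional fixed `[gender, age]` never-smoker mortality
#'   baseline; derived from `pop`'s composition when `NULL`.
#' @return List with the advanced `population` (year + 1), a `deaths` tibble
#'   (`gender, age, deaths`) and a `diagnostics` list (births, migration
#'   applied/clamped, conservation residual).
#' @export
step_year <- function(pop, rates, lifetable, riskmodel, schedules,
                      year = pop$year, mods = scenario_modifiers(),
                      relapse_multiplier = default_relapse_multiplier(),
                      never_rate = NULL) {
  ctx <- new_sim_context(pop, rates, lifetable, riskmodel, schedules, mods,
                         relapse_multiplier)
  if (!is.null(never_rate)) ctx$m_never <- never_rate
  before <- sum(pop$counts)
  res <- ctx_step(ctx, pop$counts, year)
  out <- new_population_state(res$counts, pop$products, year + 1L)
  deaths_total <- sum(res$deaths_ga)
  residual <- sum(res$counts) -
    (before - deaths_total + res$births + res$mig_applied - res$aged_out)
  df <- as.data.frame.table(res$deaths_ga, responseName = "deaths",
                            stringsAsFactors = FALSE)
  names(df) <- c("gender", "age", "deaths")
  df$age <- as.integer(df$age)
  list(
    population = out,
    deaths = tibble::as_tibble(df),
    diagnostics = list(deaths = deaths_total, births = res$births,
                       migration_applied = res$mig_applied,
                       migration_clamped = res$mig_clamped,
                       conservation_residual = residual)
  )
}

#' Run a scenario projection
#'
#' Initialises the population at `start_year` from the bundle's pyramid and
#' smoking prevalence (alternative-product stocks start empty until their
#' introduction year) and steps the engine to `end_year`, recording yearly
#' prevalence (age 14+, dual users counted under every product they currently
#' use), deaths, and cumulative life-years lost (deaths weighted by the life
#' table's remaining life expectancy at the age of death).
#'
#' @param bundle An [input_bundle()].
#' @param scen A [scenario()].
#' @param start_year,end_year Projection horizon (1-year steps).
#' @return A `projection_result`: a list carrying the yearly `series` tibble,
#'   a `deaths_by_age` array, the final `population_state` and run metadata.
#' @export
run_scenario <- function(bundle, scen, start_year = 2001L, end_year = 2100L) {
  if (start_year >= end_year) abort("`start_year` must precede `end_year`.")
  products <- rate_products(scen$rates)
  risk <- bundle$risk
  if (!is.null(scen$prrp_excess_fraction)) {
    for (nm in names(scen$prrp_excess_fraction)) {
      risk$prrp_excess_fraction[[nm]] <- scen$prrp_excess_fraction[[nm]]
    }
  }
  pop <- init_population(bundle$pyramid, bundle$prevalence, bundle$quit_time,
                         products, start_year)
  ctx <- new_sim_context(pop, scen$rates, bundle$life_table, risk,
                         bundle_schedules(bundle), scen$modifiers,
                         bundle$relapse_multiplier)
  years <- start_year:end_year
  n <- length(years)
  counts <- pop$counts
  deaths_by_age <- array(0, dim = c(n, 2L, 101L),
                         dimnames = list(year = years, gender = GENDERS, age = AGES))
  prev_cols <- matrix(0, n, length(products),
                      dimnames = list(NULL, products))
  statuses <- as.matrix(ctx$states[, products, drop = FALSE])
  current_idx <- lapply(seq_along(products),
                        function(p) which(statuses[, p] == "current"))
  ages14 <- 15:101
  population <- deaths <- lyl <- resid <- numeric(n)
  clamped_total <- 0
  for (i in seq_len(n)) {
    y <- years[i]
    adult <- counts[, ages14, , , drop = FALSE]
    elig <- sum(adult)
    if (elig > 0) {
      for (p in seq_along(products)) {
        prev_cols[i, p] <- 100 * sum(adult[, , current_idx[[p]], ]) / elig
      }
    }
    population[i] <- sum(counts)
    res <- ctx_step(ctx, counts, y)
    deaths_by_age[i, , ] <- res$deaths_ga
    deaths[i] <- sum(res$deaths_ga)
    lyl[i] <- sum(res$deaths_ga * res$ex)
    resid[i] <- sum(res$counts) -
      (population[i] - deaths[i] + res$births + res$mig_applied - res$aged_out)
    clamped_total <- clamped_total + res$mig_clamped
    counts <- res$counts
  }
  series <- tibble::tibble(
    year = years, population = population, deaths = deaths,
    life_years_lost = lyl, cum_life_years_lost = cumsum(lyl),
    conservation_residual = resid,
    smoking_prevalence = prev_cols[, 1]
  )
  for (p in products[-1]) series[[paste0("prevalence_", p)]] <- prev_cols[, p]
  series$prrp_prevalence <- if (length(products) > 1L) {
    rowSums(prev_cols[, -1, drop = FALSE])
  } else 0
  structure(
    list(scenario = scen$name, products = products, series = series,
         deaths_by_age = deaths_by_age,
         final_population = new_population_state(counts, products, end_year + 1L),
         start_year = start_year, end_year = end_year,
         modifiers = scen$modifiers, migration_clamped = clamped_total),
    class = "projection_result"
  )
}

#' Product-use prevalence of a population
#'
#' @param pop A `population_state`.
#' @param product Product label (default: the cigarette).
#' @param min_age Minimum age counted (default 14).
#' @param dual `"inclusive"` counts dual users under every product they
#'   currently use (the default reporting convention); `"exclusive"` counts
#'   only people whose sole current product is `product`.
#' @return Prevalence as a percentage of the age-eligible population.
#' @export
prevalence <- function(pop, product = pop$products[1], min_age = 14,
                       dual = c("inclusive", "exclusive")) {
  prevalence_from_counts(pop$counts, pop$states, product, min_age,
                         match.arg(dual))
}

#' Life-years lost from a death series
#'
#' Weights each death by the life table's remaining life expectancy at the age
#' of death and accumulates over the horizon.
#'
#' @param deaths Tibble `year, gender, age, deaths`.
#' @param lifetable A [life_table()] supplying `life_expectancy`.
#' @return Tibble `year, life_years_lost, cum_life_years_lost`.
#' @export
life_years_lost <- function(deaths, lifetable) {
  out <- lapply(sort(unique(deaths$year)), function(y) {
    lt <- lt_arrays(lifetable, y)
    sub <- deaths[deaths$year == y, ]
    ex <- lt$life_expectancy[cbind(sub$gender, as.character(sub$age))]
    tibble::tibble(year = y, life_years_lost = sum(sub$deaths * ex))
  })
  out <- dplyr::bind_rows(out)
  out$cum_life_years_lost <- cumsum(out$life_years_lost)
  out
}

#' Compare scenario projections against a baseline
#'
#' Samples each projection at the requested years and reports smoking and
#' alternative-product prevalence plus the reduction in cumulative life-years
#' lost relative to the baseline scenario, in millions of person-years.
#'
#' @param results Named list of `projection_result`s.
#' @param baseline Name (or index) of the baseline scenario.
#' @param years Report years (default each decade 2010-2100).
#' @param lyl_mode `"expectancy"` (deaths weighted by remaining life
#'   expectancy, the default) or `"person_years"` (cumulative difference in
#'   person-years lived between the scenario and the baseline).
#' @return A tibble of class `scenario_comparison` with columns `scenario`,
#'   `year`, `smoking_prevalence`, `prrp_prevalence`, `lyl_reduction_m`.
#' @export
compare_scenarios <- function(results, baseline = 1L,
                              years = seq(2010L, 2100L, by = 10L),
                              lyl_mode = c("expectancy", "person_years")) {
  lyl_mode <- match.arg(lyl_mode)
  if (is.null(names(results))) {
    names(results) <- vapply(results, function(r) r$scenario, character(1))
  }
  base <- results[[baseline]]
  out <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    yrs <- intersect(years, r$series$year)
    i <- match(yrs, r$series$year)
    j <- match(yrs, base$series$year)
    red <- if (lyl_mode == "expectancy") {
      base$series$cum_life_years_lost[j] - r$series$cum_life_years_lost[i]
    } else {
      cumsum(r$series$population - base$series$population)[i]
    }
    tibble::tibble(
      scenario = nm, year = yrs,
      smoking_prevalence = r$series$smoking_prevalence[i],
      prrp_prevalence = r$series$prrp_prevalence[i],
      lyl_reduction_m = red / 1e6
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "baseline") <- if (is.numeric(baseline)) names(results)[baseline] else baseline
  attr(out, "lyl_mode") <- lyl_mode
  class(out) <- c("scenario_comparison", class(out))
  out
}
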