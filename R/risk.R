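# Product-status-specific mortality -------------------------------------------
#
# Current smokers carry an age/gender relative risk vs never-smokers; former
# users' excess risk (RR - 1) decays as a negative exponential with a
# configurable half-life; alternative products carry a configurable fraction
# of the cigarette's excess risk ("X% the risk of cigarettes" scales the
# excess, so never-users stay at RR = 1); dual use takes the maximum of the
# component excesses (smoking dominates).  Never-smoker mortality is derived
# from the all-cause rate by prevalence-weighted decomposition.

#' Construct a risk model
#'
#' @param rr_current Tibble `gender, age_lo, age_hi, rr` of current-smoker
#'   relative risks (vs never-smokers, `rr >= 1`); `gender` may be `"*"`.
#' @param decay_halflife Half-life (years) of former-user excess risk.
#' @param prrp_excess_fraction Named fractions of the cigarette excess risk
#'   carried by each alternative product (default e-cigarette 5%, THP 10%).
#' @param quit20plus_years Representative years abstinent at which the open
#'   20+ quit-time pool is evaluated.
#' @param dual_use_rule Combination rule for multi-product excesses; only
#'   `"max_product_risk"` (smoking dominates) is implemented.
#' @return A list of class `risk_model`.
#' @export
risk_model <- function(rr_current,
                       decay_halflife = 10,
                       prrp_excess_fraction = c(ecig = 0.05, thp = 0.10),
                       quit20plus_years = 25,
                       dual_use_rule = "max_product_risk") {
  rr_current <- tibble::as_tibble(rr_current)
  need <- c("gender", "age_lo", "age_hi", "rr")
  if (!all(need %in% names(rr_current))) {
    abort(paste0("`rr_current` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(rr_current$rr < 1)) abort("current-smoker relative risks must be >= 1.")
  if (decay_halflife <= 0) abort("`decay_halflife` must be positive.")
  if (any(prrp_excess_fraction < 0 | prrp_excess_fraction > 1)) {
    abort("`prrp_excess_fraction` values must lie in [0, 1].")
  }
  dual_use_rule <- match.arg(dual_use_rule, "max_product_risk")
  structure(
    list(rr_current = rr_current,
         decay_halflife = decay_halflife,
         prrp_excess_fraction = prrp_excess_fraction,
         quit20plus_years = quit20plus_years,
         dual_use_rule = dual_use_rule),
    class = "risk_model"
  )
}

# [gender, age] matrix of current-smoker RR.
rr_current_array <- function(model) {
  arr <- matrix(1, 2, 101, dimnames = list(gender = GENDERS, age = AGES))
  rr <- model$rr_current
  ord <- order(rr$gender != "*")
  for (i in ord) {
    gs <- if (rr$gender[i] == "*") GENDERS else rr$gender[i]
    arr[gs, (rr$age_lo[i]:rr$age_hi[i]) + 1L] <- rr$rr[i]
  }
  arr
}

#' Relative risk of a former user after quitting
#'
#' Excess risk decays as a negative exponential:
#' `1 + (rr - 1) * 2^(-quit_years / halflife)`.
#'
#' @param rr Current-user relative risk (>= 1).
#' @param quit_years Years abstinent (>= 0); vectorised.
#' @param halflife Excess-risk half-life in years (> 0).
#' @return Relative risk(s) in `[1, rr]`.
#' @examples
#' former_excess_rr(3, quit_years = 10, halflife = 10) # 2: half the excess
#' @export
former_excess_rr <- function(rr, quit_years, halflife) {
  if (any(halflife <= 0)) abort("`halflife` must be positive.")
  if (any(quit_years < 0)) abort("`quit_years` must be non-negative.")
  1 + (rr - 1) * 2^(-quit_years / halflife)
}

# Excess-risk coefficient of one product status relative to the full cigarette
# excess: 1 for a current smoker, f_p for a current alternative-product user,
# decayed by quit time for former users, 0 for never.  Former users of an
# alternative product in a cell with no cigarette quit-time ledger (cigarette
# status not "former") are evaluated at quit_years = 0, i.e. undecayed - a
# conservative choice documented in the methods vignette.
status_excess_coef <- function(status, fraction, quit_years, halflife) {
  if (is.null(quit_years) || is.na(quit_years)) quit_years <- 0
  switch(status,
    never = 0,
    current = fraction,
    former = fraction * 2^(-quit_years / halflife)
  )
}

#' Joint-state relative risk
#'
#' Combines per-product excess risks for one joint product-status state:
#' each current product contributes `f_p * (rr - 1)` (with `f == 1` for the
#' cigarette), each former product the same excess decayed by the shared
#' cigarette quit-time ledger, and the combined relative risk is
#' `1 + max(excesses)` (dual use: smoking dominates).
#'
#' @param state Named character vector of statuses, one per product (names =
#'   product labels, first = cigarette), or a row from [enumerate_states()].
#' @param quit_bin Quit-time bin (`"none"`, `"0"`, `"1"`...`"20"`, `"20+"`).
#' @param model A [risk_model()].
#' @param gender,age Cell identity for the current-smoker RR lookup.
#' @return A single relative risk >= 1.
#' @export
joint_state_rr <- function(state, quit_bin, model, gender, age) {
  if (is.data.frame(state)) {
    prods <- state_products(state)
    state <- setNames(unlist(state[1, prods], use.names = FALSE), prods)
  }
  products <- names(state)
  rr <- rr_current_array(model)[gender, as.character(age)]
  qy <- qbin_years(model$quit20plus_years)[match(quit_bin, QUIT_BINS)]
  cig_former <- state[[1]] == "former"
  coefs <- vapply(seq_along(products), function(p) {
    f <- if (p == 1L) 1 else model$prrp_excess_fraction[[products[p]]]
    if (is.null(f) || is.na(f)) {
      abort(sprintf("no excess-risk fraction configured for product '%s'.", products[p]))
    }
    # the quit-time ledger follows the cigarette clock; alternative-product
    # former users without a tracked clock are evaluated undecayed
    status_excess_coef(state[[p]], f,
                       quit_years = if (cig_former) qy else NA_real_,
                       halflife = model$decay_halflife)
  }, numeric(1))
  1 + max(coefs, 0) * (rr - 1)
}

# Excess coefficient per (state, qbin): combined RR = 1 + coef * (rr - 1).
state_excess_coefs <- function(states, model) {
  products <- state_products(states)
  qy <- qbin_years(model$quit20plus_years)
  coef <- matrix(0, nrow(states), length(QUIT_BINS),
                 dimnames = list(state = states$state, qbin = QUIT_BINS))
  for (s in seq_len(nrow(states))) {
    statuses <- unlist(states[s, products], use.names = FALSE)
    for (b in seq_along(QUIT_BINS)) {
      cig_former <- statuses[1] == "former"
      if (cig_former && is.na(qy[b])) next       # former smokers never sit in "none"
      if (!cig_former && !is.na(qy[b])) next     # others only occupy "none"
      per_prod <- vapply(seq_along(products), function(p) {
        f <- if (p == 1L) 1 else model$prrp_excess_fraction[[products[p]]]
        q <- if (cig_former) qy[b] else NA_real_
        status_excess_coef(statuses[p], f, q, model$decay_halflife)
      }, numeric(1))
      coef[s, b] <- max(per_prod)
    }
  }
  coef
}

# Full [gender, age, state, qbin] relative-risk array.
state_rr_array <- function(states, model) {
  rr <- rr_current_array(model)
  coef <- state_excess_coefs(states, model)
  base <- outer(rr - 1, coef) # [gender, age, state, qbin]
  1 + base
}

#' Derive never-smoker mortality from an all-cause rate
#'
#' Solves the prevalence-weighted decomposition: with status counts `n_s` and
#' relative risks `rr_s`, the never-user rate is
#' `m_never = all_cause_rate * sum(n) / sum(n * rr)` and each status's rate is
#' `m_never * rr_s`, so the weighted average reconstructs the all-cause rate.
#'
#' @param all_cause_rate Observed all-cause annual death probability.
#' @param composition Non-negative status counts (at least one person).
#' @param rrs Relative risks, same length as `composition`.
#' @return List with `never_rate` and `status_rates`.
#' @examples
#' derive_never_mortality(0.01, c(50, 50), c(1, 2))$never_rate # 0.01 / 1.5
#' @export
derive_never_mortality <- function(all_cause_rate, composition, rrs) {
  if (length(composition) != length(rrs)) {
    abort("`composition` and `rrs` must have equal length.")
  }
  if (any(composition < 0) || sum(composition) <= 0) {
    abort("`composition` must be non-negative with at least one person.")
  }
  denom <- sum(composition * rrs)
  if (denom <= 0) abort("all relative-risk weights are zero; mortality cannot be decomposed.")
  never <- all_cause_rate * sum(composition) / denom
  list(never_rate = never, status_rates = never * rrs)
}

# Never-user baseline mortality [gender, age] for a population under a risk
# model: the all-cause life-table rate divided by the mean RR of the cell.
derive_never_mortality_array <- function(counts, rr_arr, all_cause) {
  tot <- apply(counts, c(1, 2), sum)
  wsum <- apply(counts * rr_arr, c(1, 2), sum)
  never <- all_cause
  occ <- tot > 0 & wsum > 0
  never[occ] <- all_cause[occ] * tot[occ] / wsum[occ]
  never
}

# Death probability array [gender, age, state, qbin] given the never baseline;
# age 100 dies with certainty regardless of status.
death_prob_array <- function(never, rr_arr) {
  d <- as.vector(never) * rr_arr
  d[d > 1] <- 1
  d[, 101, , ] <- 1
  d
}

#' Apply status-specific mortality to a population
#'
#' Reduces every cell by its status-specific annual death probability.  The
#' never-smoker baseline is derived from the supplied life table and the
#' population's own composition (or taken from `never_rate` when the caller
#' holds a fixed baseline, as the simulation engine does).
#'
#' @param pop A `population_state`.
#' @param lifetable A [life_table()].
#' @param riskmodel A [risk_model()].
#' @param year Calendar year for the life-table lookup.
#' @param never_rate Optional `[gender, age]` matrix of never-user death
#'   probabilities overriding the derivation.
#' @return List with the surviving `population` and a `deaths` tibble
#'   (`gender, age, state, deaths`).
#' @export
apply_status_mortality <- function(pop, lifetable, riskmodel, year = pop$year,
                                   never_rate = NULL) {
  rr_arr <- state_rr_array(pop$states, riskmodel)
  lt <- lt_arrays(lifetable, year)
  if (is.null(never_rate)) {
    never_rate <- derive_never_mortality_array(pop$counts, rr_arr, lt$mortality)
  }
  d <- death_prob_array(never_rate, rr_arr)
  deaths <- pop$counts * d
  pop$counts <- pop$counts - deaths
  by_state <- apply(deaths, c(1, 2, 3), sum)
  df <- as.data.frame.table(by_state, responseName = "deaths", stringsAsFactors = FALSE)
  names(df) <- c("gender", "age", "state", "deaths")
  df$age <- as.integer(df$age)
  list(population = pop, deaths = tibble::as_tibble(df))
}
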