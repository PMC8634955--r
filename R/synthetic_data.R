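# Synthetic Italy-shaped fixtures ----------------------------------------------
#
# Seeded generator of a complete, schema-valid input bundle so every module is
# runnable and testable without external data: a Gompertz-Makeham life table
# with internally consistent remaining life expectancy, an old-heavy age
# pyramid, logistic ever-smoking curves scaled exactly to a target age-14+
# current-smoking prevalence, a geometric quit-time distribution, birth and
# net-migration schedules, a current-smoker relative-risk schedule, and
# transition-rate tables for a cigarette-only market plus e-cigarette-like and
# heated-tobacco-like two-product markets.  The two styles differ only in the
# structure reported for the underlying estimation sources: the THP-like table
# has one quarter the never-user initiation and double the smoker uptake of
# the e-cigarette-like table.

#' Specification of the synthetic fixture bundle
#'
#' Defaults describe a stylised Italy around the start of the projection
#' horizon; all randomness (a small smoothness-breaking perturbation of the
#' pyramid) flows from `seed`, so generation is pure given the spec.
#'
#' @param seed Integer seed.
#' @param population_size Total population (continuous persons).
#' @param target_smoking_prevalence Current-smoking prevalence (%) among ages
#'   14+ at initialisation; the ever-smoking curve is scaled to hit it
#'   exactly.
#' @param ... Overrides of the remaining generator parameters (see the
#'   function body; documented in the methods vignette).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 4242L, population_size = 6e7,
                         target_smoking_prevalence = 19.7, ...) {
  spec <- list(
    seed = as.integer(seed),
    population_size = population_size,
    target_smoking_prevalence = target_smoking_prevalence,
    # mortality: m(a) = makeham + a_coef * exp(b_coef * a), infant bump at 0
    gompertz = list(male = c(a = 2.0e-5, b = 0.100),
                    female = c(a = 1.2e-5, b = 0.100)),
    makeham = 2e-4,
    infant_mortality = c(male = 0.0035, female = 0.0030),
    # ever-smoking logistic: midpoint / scale in years; initiation window
    ever_midpoint = 19, ever_scale = 2.5, init_window = c(11L, 30L),
    gender_smoking_mult = c(male = 1.15, female = 0.85),
    former_share_slope = 0.016, former_share_start = 24, former_share_max = 0.85,
    quit_time_ratio = 0.92,
    # cigarette transitions
    cig_quit = tibble::tibble(age_lo = c(14L, 45L, 65L), age_hi = c(44L, 64L, 100L),
                              mean = c(0.025, 0.035, 0.045)),
    relapse_base = 0.08, relapse_ratio = 0.75,
    dual_quit_uplift = 2.5,
    # alternative-product transitions (e-cigarette-like reference values)
    prrp_never_init = 0.008, prrp_init_ages = c(14L, 34L),
    prrp_smoker_uptake = 0.03, prrp_former_uptake = 0.005,
    prrp_quit = 0.12, prrp_relapse = 0.05,
    thp_never_init_factor = 0.25, thp_uptake_factor = 2,
    ci_width = 0.4,
    # risk
    rr_bands = tibble::tibble(
      age_lo = c(0L, 18L, 35L, 45L, 55L, 65L, 75L, 85L),
      age_hi = c(17L, 34L, 44L, 54L, 64L, 74L, 84L, 100L),
      rr = c(1.0, 1.8, 2.3, 2.8, 3.0, 2.8, 2.3, 1.8)
    ),
    decay_halflife = 10, prrp_excess_fraction = c(ecig = 0.05, thp = 0.10),
    quit20plus_years = 25,
    # demography schedules
    birth_decline = 0.003, male_birth_share = 0.512,
    migration_net = 120000, migration_ages = c(15L, 64L), migration_peak = 27,
    male_migration_share = 0.52,
    birth_history_growth = 0.004, birth_history_cap = 60,
    pyramid_noise_sd = 0.01,
    start_year = 2001L, end_year = 2100L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0L) {
    abort(paste0("unknown fixture_spec field(s): ", paste(unknown, collapse = ", ")))
  }
  spec[names(dots)] <- dots
  structure(spec, class = "fixture_spec")
}

generate_life_table <- function(spec) {
  rows <- lapply(GENDERS, function(g) {
    gp <- spec$gompertz[[g]]
    m <- pmin(1, spec$makeham + gp["a"] * exp(gp["b"] * AGES))
    m[1] <- spec$infant_mortality[[g]]
    m[101] <- 1
    l <- cumprod(c(1, 1 - m))[1:101] # survivors to exact age a
    l_next <- l * (1 - m)
    L <- (l + l_next) / 2
    Tx <- rev(cumsum(rev(L)))
    ex <- ifelse(l > 0, Tx / l, 0)
    tibble::tibble(gender = g, age = AGES, year = NA_integer_,
                   mortality = unname(m), life_expectancy = unname(ex))
  })
  life_table(dplyr::bind_rows(rows))
}

generate_pyramid <- function(spec, lt) {
  noise <- with_seed(spec$seed, matrix(rnorm(202, 0, spec$pyramid_noise_sd), 2,
                                       dimnames = list(GENDERS, NULL)))
  rows <- lapply(GENDERS, function(g) {
    m <- lt$mortality[lt$gender == g]
    surv <- cumprod(c(1, (1 - m)[1:100]))
    birth_hist <- (1 + spec$birth_history_growth)^pmin(AGES, spec$birth_history_cap)
    share <- if (g == "male") spec$male_birth_share else 1 - spec$male_birth_share
    raw <- share * birth_hist * surv * exp(noise[g, ])
    tibble::tibble(gender = g, age = AGES, count = raw)
  })
  out <- dplyr::bind_rows(rows)
  tot <- sum(out$count)
  out$count <- if (tot > 0) out$count * spec$population_size / tot else out$count * 0
  out
}

generate_prevalence <- function(spec, pyramid) {
  shape <- plogis((AGES - spec$ever_midpoint) / spec$ever_scale)
  base <- plogis((spec$init_window[1] - spec$ever_midpoint) / spec$ever_scale)
  shape <- pmax(0, (shape - base) / (1 - base)) # exactly 0 up to the window start
  fs <- pmin(spec$former_share_max,
             pmax(0, (AGES - spec$former_share_start) * spec$former_share_slope))
  rows <- lapply(GENDERS, function(g) {
    tibble::tibble(gender = g, age = AGES,
                   ever_base = spec$gender_smoking_mult[[g]] * shape,
                   former_share = fs)
  })
  df <- dplyr::bind_rows(rows)
  df <- dplyr::left_join(df, pyramid, by = c("gender", "age"))
  adult <- df$age >= 14
  w <- df$count[adult]
  cur_base <- df$ever_base[adult] * (1 - df$former_share[adult])
  k <- if (sum(w) > 0 && sum(w * cur_base) > 0) {
    (spec$target_smoking_prevalence / 100) * sum(w) / sum(w * cur_base)
  } else if (mean(cur_base) > 0) {
    (spec$target_smoking_prevalence / 100) / mean(cur_base)
  } else 0
  ever <- k * df$ever_base
  if (any(ever > 0.95)) {
    abort("fixture target prevalence implies ever-smoking above 95%; lower the target.")
  }
  tibble::tibble(
    gender = df$gender, age = df$age,
    current = ever * (1 - df$former_share),
    former = ever * df$former_share,
    ever = ever
  )
}

generate_quit_time <- function(spec) {
  r <- spec$quit_time_ratio
  w <- r^(0:19)
  tail20 <- r^20 / (1 - r)
  share <- c(w, tail20)
  tibble::tibble(bin = c(as.character(1:20), "20+"), share = share / sum(share))
}

generate_schedules <- function(spec, pyramid) {
  years <- spec$start_year:spec$end_year
  base_births <- sum(pyramid$count[pyramid$age == 0])
  births <- dplyr::bind_rows(lapply(GENDERS, function(g) {
    share <- if (g == "male") spec$male_birth_share else 1 - spec$male_birth_share
    tibble::tibble(gender = g, year = years,
                   count = share * base_births * (1 - spec$birth_decline)^(years - spec$start_year))
  }))
  migration_total <- tibble::tibble(year = spec$start_year, count = spec$migration_net)
  ages <- spec$migration_ages[1]:spec$migration_ages[2]
  tri <- pmax(0, 1 - abs(ages - spec$migration_peak) /
                (spec$migration_ages[2] - spec$migration_peak + 1))
  migration_age <- dplyr::bind_rows(lapply(GENDERS, function(g) {
    share <- if (g == "male") spec$male_migration_share else 1 - spec$male_migration_share
    tibble::tibble(gender = g, age = ages, share = share * tri / sum(tri))
  }))
  list(births = births, migration_total = migration_total, migration_age = migration_age)
}

ci_row <- function(mean, width) {
  tibble::tibble(mean = mean, lo95 = pmax(0, mean * (1 - width)),
                 hi95 = pmin(1, mean * (1 + width)))
}

# Core rate-table builder over an arbitrary product set.  `prrp_params` is a
# named list per non-cigarette product with elements never_init, smoker_uptake,
# former_uptake, quit, relapse; NULL leaves that product's flows at zero.
build_rate_table <- function(spec, products, prrp_params, prevalence) {
  states <- enumerate_states(length(products), products)
  flows <- enumerate_flows(states)
  move1 <- flows[[paste0("move_", products[1])]]
  statuses <- as.matrix(states[, products, drop = FALSE])
  w <- spec$ci_width
  init <- calibrate_initiation_from_prevalence(prevalence, spec$init_window)
  rows <- list()
  add <- function(from, to, gender, age_lo, age_hi, mean) {
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(from = from, to = to, gender = gender,
                     age_lo = age_lo, age_hi = age_hi, year = NA_integer_),
      ci_row(mean, w)
    )
  }
  single <- flows$n_changed == 1L
  for (f in which(single)) {
    from <- flows$from[f]; to <- flows$to[f]
    from_status <- statuses[flows$from_id[f], ]
    if (!is.na(move1[f])) {
      # cigarette flow; identical across alternative-product statuses apart
      # from the dual-user cessation uplift
      if (move1[f] == "initiate") {
        for (g in GENDERS) {
          sub <- init[init$gender == g, ]
          for (i in seq_len(nrow(sub))) {
            add(from, to, g, sub$age[i], sub$age[i], sub$initiation[i])
          }
        }
      } else if (move1[f] == "quit") {
        uplift <- if (any(from_status[-1] == "current")) spec$dual_quit_uplift else 1
        for (i in seq_len(nrow(spec$cig_quit))) {
          add(from, to, "*", spec$cig_quit$age_lo[i], spec$cig_quit$age_hi[i],
              pmin(1, spec$cig_quit$mean[i] * uplift))
        }
      } else {
        add(from, to, "*", 14L, 100L, spec$relapse_base)
      }
    } else {
      p <- as.integer(flows$changed[f])
      pars <- prrp_params[[products[p]]]
      if (is.null(pars)) next
      kind <- flows[[paste0("move_", products[p])]][f]
      if (kind == "initiate") {
        rate <- switch(from_status[1],
                       never = pars$never_init,
                       current = pars$smoker_uptake,
                       former = pars$former_uptake)
        if (from_status[1] == "never") {
          add(from, to, "*", spec$prrp_init_ages[1], spec$prrp_init_ages[2], rate)
        } else {
          add(from, to, "*", 14L, 100L, rate)
        }
      } else if (kind == "quit") {
        add(from, to, "*", 14L, 100L, pars$quit)
      } else {
        add(from, to, "*", 14L, 100L, pars$relapse)
      }
    }
  }
  rate_table(dplyr::bind_rows(rows), products)
}

prrp_param_set <- function(spec, style) {
  ni <- spec$prrp_never_init
  up <- spec$prrp_smoker_uptake
  if (style == "thp_like") {
    ni <- ni * spec$thp_never_init_factor
    up <- up * spec$thp_uptake_factor
  }
  list(never_init = ni, smoker_uptake = up,
       former_uptake = spec$prrp_former_uptake,
       quit = spec$prrp_quit, relapse = spec$prrp_relapse)
}

#' Generate a two-product transition-rate table
#'
#' Builds the cigarette + alternative-product rate table for one of the two
#' reference market styles.  The heated-tobacco-like style has one quarter the
#' never-user product initiation and double the smoker uptake of the
#' e-cigarette-like style; every other flow is shared.
#'
#' @param style `"ecig_like"` or `"thp_like"`.
#' @param spec A [fixture_spec()].
#' @return A [rate_table()] over `c("cigarette", "ecig")` or
#'   `c("cigarette", "thp")`.
#' @export
generate_two_product_rates <- function(style = c("ecig_like", "thp_like"),
                                       spec = fixture_spec()) {
  style <- match.arg(style)
  label <- if (style == "ecig_like") "ecig" else "thp"
  lt <- generate_life_table(spec)
  pyramid <- generate_pyramid(spec, lt)
  prevalence <- generate_prevalence(spec, pyramid)
  params <- setNames(list(prrp_param_set(spec, style)), label)
  build_rate_table(spec, c("cigarette", label), params, prevalence)
}

#' Generate a rate table over an arbitrary product set
#'
#' The cigarette flows are always populated; each alternative product's flows
#' are populated from its style (`"ecig_like"`, `"thp_like"`) or left at zero
#' (`NA`), which is how a structurally three-product model with inactive
#' alternative products is built.
#'
#' @param spec A [fixture_spec()].
#' @param products Product labels (first = cigarette).
#' @param styles Character vector of styles for `products[-1]`, `NA` = zero
#'   rates.
#' @return A [rate_table()].
#' @export
generate_rate_table <- function(spec = fixture_spec(),
                                products = "cigarette",
                                styles = rep(NA_character_, length(products) - 1L)) {
  lt <- generate_life_table(spec)
  pyramid <- generate_pyramid(spec, lt)
  prevalence <- generate_prevalence(spec, pyramid)
  params <- setNames(vector("list", length(products) - 1L), products[-1])
  for (i in seq_along(styles)) {
    if (!is.na(styles[i])) params[[i]] <- prrp_param_set(spec, styles[i])
  }
  build_rate_table(spec, products, params, prevalence)
}

#' Generate the full synthetic input bundle
#'
#' Produces every input the engine consumes: pyramid, life table, smoking
#' prevalence (hitting the target age-14+ current prevalence exactly),
#' quit-time distribution, birth and migration schedules, risk model, and the
#' three rate tables (`smoking`, `ecig`, `thp`).  Deterministic given
#' `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return An [input_bundle()] whose `rates` element holds the three tables.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  lt <- generate_life_table(spec)
  pyramid <- generate_pyramid(spec, lt)
  prev_full <- generate_prevalence(spec, pyramid)
  prevalence <- prev_full[, c("gender", "age", "current", "former")]
  quit_time <- generate_quit_time(spec)
  sched <- generate_schedules(spec, pyramid)
  risk <- risk_model(
    dplyr::mutate(spec$rr_bands, gender = "*", .before = 1),
    decay_halflife = spec$decay_halflife,
    prrp_excess_fraction = spec$prrp_excess_fraction,
    quit20plus_years = spec$quit20plus_years
  )
  rates <- list(
    smoking = build_rate_table(spec, "cigarette", list(), prev_full),
    ecig = build_rate_table(spec, c("cigarette", "ecig"),
                            list(ecig = prrp_param_set(spec, "ecig_like")), prev_full),
    thp = build_rate_table(spec, c("cigarette", "thp"),
                           list(thp = prrp_param_set(spec, "thp_like")), prev_full)
  )
  input_bundle(
    pyramid = pyramid, life_table = lt, prevalence = prevalence,
    quit_time = quit_time, births = sched$births,
    migration_total = sched$migration_total, migration_age = sched$migration_age,
    risk = risk,
    relapse_multiplier = default_relapse_multiplier(spec$relapse_ratio),
    rates = rates
  )
}

#' Standard market scenarios over a fixture bundle
#'
#' Mirrors the reference scenario set: a cigarette-only baseline, sole
#' e-cigarette (introduced 2010), sole heated tobacco (introduced 2014), and
#' two pseudo-product blends of the sole-product tables (50:50 and 63:37 by
#' weight on the e-cigarette, with excess-risk fractions blended with the same
#' weights).  With `declining = TRUE` every scenario adds a 3%-per-year
#' cigarette-initiation decline from 2020.
#'
#' @param bundle An [input_bundle()] from [generate_fixtures()].
#' @param declining Apply the initiation decline.
#' @param decline_rate,decline_start Decline parameters.
#' @return Named list of [scenario()]s.
#' @export
default_scenarios <- function(bundle, declining = FALSE, decline_rate = 0.03,
                              decline_start = 2020L) {
  mods <- function(intro = NULL) {
    scenario_modifiers(
      intro_year = intro,
      init_decline_rate = if (declining) decline_rate else 0,
      init_decline_start = decline_start
    )
  }
  f <- bundle$risk$prrp_excess_fraction
  pseudo <- function(w) {
    scenario(
      sprintf("Smoking + %d%% e-cig %d%% THP", round(100 * w), round(100 * (1 - w))),
      rates = combine_pseudo_prrp(bundle$rates$ecig, bundle$rates$thp, w,
                                  products = c("cigarette", "pseudo_prrp")),
      modifiers = mods(c(pseudo_prrp = 2010)),
      prrp_excess_fraction = c(pseudo_prrp = combine_pseudo_risk(f[["ecig"]], f[["thp"]], w))
    )
  }
  list(
    smoking_only = scenario("Smoking only", bundle$rates$smoking, mods()),
    ecig = scenario("Smoking + E-cigarettes", bundle$rates$ecig,
                    mods(c(ecig = 2010))),
    thp = scenario("Smoking + THPs", bundle$rates$thp, mods(c(thp = 2014))),
    pseudo_50_50 = pseudo(0.50),
    pseudo_63_37 = pseudo(0.63)
  )
}
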