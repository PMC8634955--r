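# Cohort-component demography --------------------------------------------------
#
# The population is held as continuous (fractional) person counts indexed by
# gender, single year of age 0-100, joint product-status state, and - for
# stocks whose cigarette status is "former" - the number of years abstinent
# from smoking, binned 1..20 with a combined 20+ grouping.  A transient "0"
# bin holds people who quit during the current simulated year; the ageing step
# advances it to bin 1, so a smoker quitting in year t is one year abstinent
# at the start of year t + 1.  Mortality at age 100 is 100%, which closes the
# age ladder.

GENDERS <- c("male", "female")
AGES <- 0:100
QUIT_BINS <- c("none", "0", as.character(1:20), "20+")

# Destination bin index under one year of ageing: none stays, 0 -> 1, ...,
# 19 -> 20, 20 and 20+ pool into 20+.
qbin_age_dest <- function() {
  d <- seq_along(QUIT_BINS)
  d[2:22] <- 3:23
  d[23] <- 23L
  d[1] <- 1L
  d
}

# Years abstinent represented by each bin; "none" is NA (not a former smoker),
# the 20+ pool is evaluated at a configurable representative time by the risk
# model.
qbin_years <- function(rep_20plus = 25) {
  c(NA_real_, 0:20, rep_20plus)
}

## Life tables -----------------------------------------------------------------

#' Construct a validated period life table
#'
#' @param df Data frame with columns `gender` (`"male"`/`"female"`), `age`
#'   (0-100, complete per gender and year), optional `year`, `mortality`
#'   (annual death probability, with `mortality == 1` at age 100) and
#'   `life_expectancy` (remaining years at that age).
#' @return A tibble of class `life_table`.
#' @export
life_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("gender", "age", "mortality", "life_expectancy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("life table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"year" %in% names(df)) df$year <- NA_integer_
  df$age <- as.integer(df$age)
  df$year <- as.integer(df$year)
  if (!all(df$gender %in% GENDERS)) abort("life table `gender` must be 'male' or 'female'.")
  if (any(df$mortality < 0 | df$mortality > 1, na.rm = TRUE) || anyNA(df$mortality)) {
    abort("life table `mortality` must lie in [0, 1].")
  }
  if (any(df$life_expectancy < 0, na.rm = TRUE) || anyNA(df$life_expectancy)) {
    abort("life table `life_expectancy` must be non-negative.")
  }
  for (yr in unique(df$year)) {
    sub <- df[is_same_year(df$year, yr), ]
    for (g in GENDERS) {
      ages <- sort(sub$age[sub$gender == g])
      if (!identical(ages, AGES)) {
        abort(sprintf("life table must cover ages 0-100 exactly once per gender (gender %s).", g))
      }
    }
    if (any(abs(sub$mortality[sub$age == 100] - 1) > 1e-12)) {
      abort("life table mortality at age 100 must equal 1 (the model's closing assumption).")
    }
  }
  class(df) <- c("life_table", class(df))
  df
}

is_same_year <- function(x, yr) if (is.na(yr)) is.na(x) else !is.na(x) & x == yr

# Carry-forward year lookup: the latest table year <= `year`, else the earliest
# available (all-year rows, year NA, are the base layer).
lt_pick_year <- function(years, year) {
  ys <- sort(unique(years[!is.na(years)]))
  if (length(ys) == 0L) return(NA_integer_)
  prior <- ys[ys <= year]
  if (length(prior) > 0L) max(prior) else min(ys)
}

# [gender, age] matrices of mortality and remaining life expectancy for a year.
lt_arrays <- function(lt, year) {
  yr <- lt_pick_year(lt$year, year)
  sub <- lt[is_same_year(lt$year, yr), ]
  m <- matrix(0, 2, 101, dimnames = list(gender = GENDERS, age = AGES))
  ex <- m
  for (g in GENDERS) {
    rows <- sub[sub$gender == g, ]
    m[g, as.character(rows$age)] <- rows$mortality
    ex[g, as.character(rows$age)] <- rows$life_expectancy
  }
  list(mortality = m, life_expectancy = ex, year = yr)
}

## Population state ------------------------------------------------------------

new_population_state <- function(counts, products, year) {
  structure(
    list(counts = counts, products = products,
         states = enumerate_states(length(products), products),
         year = as.integer(year)),
    class = "population_state"
  )
}

#' An empty population state
#'
#' @param products Product labels (first = cigarette).
#' @param year Calendar year labelling the state (1 January).
#' @return A `population_state` with all counts zero.
#' @export
empty_population <- function(products = "cigarette", year = 2001L) {
  states <- enumerate_states(length(products), products)
  counts <- array(
    0,
    dim = c(2L, 101L, nrow(states), length(QUIT_BINS)),
    dimnames = list(gender = GENDERS, age = AGES, state = states$state, qbin = QUIT_BINS)
  )
  new_population_state(counts, products, year)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "<population_state> year %d | products: %s | total %.1f persons\n",
    x$year, paste(x$products, collapse = ", "), sum(x$counts)
  ))
  invisible(x)
}

#' Tidy a population state into long format
#'
#' @param x A `population_state`.
#' @param ... Unused.
#' @param drop_zero Drop all-zero cells (default `TRUE`).
#' @return Tibble with columns `gender`, `age`, `state`, `qbin`, `count`.
#' @export
as_tibble.population_state <- function(x, ..., drop_zero = TRUE) {
  df <- as.data.frame.table(x$counts, responseName = "count", stringsAsFactors = FALSE)
  names(df) <- c("gender", "age", "state", "qbin", "count")
  df$age <- as.integer(df$age)
  out <- tibble::as_tibble(df)
  if (drop_zero) out <- out[out$count != 0, ]
  out
}

#' Total person count of a population state
#' @param pop A `population_state`.
#' @return A number.
#' @export
population_total <- function(pop) sum(pop$counts)

#' Initialise a population from a pyramid and smoking prevalence
#'
#' Builds the start-of-horizon population: the age pyramid is split into never,
#' current and former cigarette smokers by the prevalence curves; former
#' smokers are spread over the quit-time bins by `quit_time`; every
#' alternative-product status starts at "never" (PRRP stocks are empty until
#' their market-introduction year).
#'
#' @param pyramid Tibble `gender, age, count` covering ages 0-100.
#' @param prevalence Tibble `gender, age, current, former` (fractions,
#'   `current + former <= 1`), covering ages 0-100.
#' @param quit_time Tibble `bin, share` over bins `"1"..."20", "20+"`, shares
#'   summing to 1.
#' @param products Product labels (first = cigarette).
#' @param year Start year.
#' @return A `population_state`.
#' @export
init_population <- function(pyramid, prevalence, quit_time, products = "cigarette",
                            year = 2001L) {
  pop <- empty_population(products, year)
  n <- length(products)
  all_never <- state_label(rep("never", n))
  cur_state <- state_label(c("current", rep("never", n - 1L)))
  fmr_state <- state_label(c("former", rep("never", n - 1L)))

  qshare <- setNames(quit_time$share, as.character(quit_time$bin))
  if (abs(sum(qshare) - 1) > 1e-8) abort("`quit_time` shares must sum to 1.")
  if (!all(names(qshare) %in% QUIT_BINS[-(1:2)])) {
    abort("`quit_time` bins must be '1'..'20' or '20+'.")
  }

  prev <- dplyr::left_join(pyramid, prevalence, by = c("gender", "age"))
  if (anyNA(prev$current) || anyNA(prev$former)) {
    abort("`prevalence` must cover every (gender, age) in the pyramid.")
  }
  if (any(prev$current < 0 | prev$former < 0 | prev$current + prev$former > 1 + 1e-9)) {
    abort("`prevalence` fractions must be non-negative with current + former <= 1.")
  }
  for (i in seq_len(nrow(prev))) {
    g <- prev$gender[i]; a <- as.character(prev$age[i]); tot <- prev$count[i]
    cur <- tot * prev$current[i]
    fmr <- tot * prev$former[i]
    pop$counts[g, a, all_never, "none"] <- tot - cur - fmr
    pop$counts[g, a, cur_state, "none"] <- cur
    pop$counts[g, a, fmr_state, names(qshare)] <- fmr * qshare
  }
  pop
}

## Demographic operators --------------------------------------------------------

# Pure array version of one year of ageing; returns the shifted array and the
# mass aged out of the open 100 cell (zero in the engine, where age-100
# mortality has already removed it).
shift_ages <- function(counts) {
  out <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  dest <- qbin_age_dest()
  for (b in seq_along(QUIT_BINS)) {
    out[, 2:101, , dest[b]] <- out[, 2:101, , dest[b]] + counts[, 1:100, , b]
  }
  list(counts = out, aged_out = sum(counts[, 101, , ]))
}

#' Age a population by one year
#'
#' Every cohort's age increments by one; the age-100 cell (whose mortality is
#' 100%) contributes no survivors; quit-time bins advance by one year,
#' saturating at the 20+ pool.
#'
#' @param pop A `population_state`.
#' @return The aged `population_state`, labelled with `year + 1`; the mass
#'   removed from the open age-100 cell is attached as attribute `"aged_out"`.
#' @export
age_population <- function(pop) {
  sh <- shift_ages(pop$counts)
  out <- new_population_state(sh$counts, pop$products, pop$year + 1L)
  attr(out, "aged_out") <- sh$aged_out
  out
}

# Birth count lookup with carry-forward of the latest schedule year.
births_for_year <- function(births, year) {
  out <- setNames(numeric(2), GENDERS)
  for (g in GENDERS) {
    rows <- births[births$gender == g, ]
    if (nrow(rows) == 0L) next
    yr <- lt_pick_year(rows$year, year)
    if (!is.na(yr)) out[g] <- rows$count[rows$year == yr][1]
  }
  out
}

#' Add the year's births to a population
#'
#' Newborns enter at age 0, never-users of every product.
#'
#' @param pop A `population_state`.
#' @param schedules A list with element `births` (tibble `gender, year,
#'   count`); later years carry the last available value forward.
#' @param year Calendar year of the birth cohort.
#' @return The updated `population_state`.
#' @export
apply_births <- function(pop, schedules, year = pop$year) {
  b <- births_for_year(schedules$births, year)
  all_never <- state_label(rep("never", length(pop$products)))
  pop$counts[, "0", all_never, "none"] <- pop$counts[, "0", all_never, "none"] + b
  pop
}

# Array-level migration; returns updated counts plus the net mass actually
# applied and any mass clamped (removals exceeding a cell).
apply_migration_counts <- function(counts, add, all_never) {
  tot <- rowSums(counts, dims = 2)
  occupied <- tot > 0
  factor <- matrix(1, 2, 101, dimnames = dimnames(tot))
  factor[occupied] <- 1 + add[occupied] / tot[occupied]
  clamped <- sum(pmax(0, -(tot + add))[occupied])
  factor <- pmax(factor, 0)
  counts <- counts * as.vector(factor)
  # positive migrants into an empty cell have no local mix to copy; they enter
  # as never-users
  into_empty <- !occupied & add > 0
  if (any(into_empty)) {
    counts[, , all_never, "none"][into_empty] <-
      counts[, , all_never, "none"][into_empty] + add[into_empty]
  }
  ignored <- sum(add[!occupied & add < 0])
  applied <- sum(add) - ignored + clamped
  list(counts = counts, applied = applied, clamped = clamped - ignored)
}

#' Apply the year's net migration to a population
#'
#' The year's net migration total is spread over gender and age by the
#' schedule's age distribution; migrants adopt the product-status mix of the
#' resident cell they join (or enter as never-users if the cell is empty).
#' Net removals larger than a cell are clamped at zero with a warning.
#'
#' @param pop A `population_state`.
#' @param schedules A list with elements `migration_total` (tibble `year,
#'   count`, carry-forward) and `migration_age` (tibble `gender, age, share`
#'   summing to 1).
#' @param year Calendar year.
#' @return The updated `population_state`; attributes `"migration_applied"`
#'   and `"migration_clamped"` carry the reconciliation terms.
#' @export
apply_migration <- function(pop, schedules, year = pop$year) {
  mt <- schedules$migration_total
  yr <- lt_pick_year(mt$year, year)
  net <- if (is.na(yr)) 0 else mt$count[mt$year == yr][1]
  share <- matrix(0, 2, 101, dimnames = list(gender = GENDERS, age = AGES))
  ma <- schedules$migration_age
  for (i in seq_len(nrow(ma))) {
    share[ma$gender[i], as.character(ma$age[i])] <- ma$share[i]
  }
  all_never <- state_label(rep("never", length(pop$products)))
  res <- apply_migration_counts(pop$counts, net * share, all_never)
  if (res$clamped > 1e-12) {
    warn(sprintf("net migration removed more people than present in some cells; %.3f person(s) clamped at zero.",
                 res$clamped))
  }
  pop$counts <- res$counts
  attr(pop, "migration_applied") <- res$applied
  attr(pop, "migration_clamped") <- res$clamped
  pop
}
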