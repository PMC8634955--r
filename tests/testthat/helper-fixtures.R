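# Shared fixtures, built in code.  The synthetic bundle is cached per test run
# (generation is deterministic given the spec seed).

.fixture_cache <- new.env(parent = emptyenv())

tiny_spec <- function(...) {
  args <- list(seed = 99L, population_size = 1e6)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fixture_spec, args)
}

tiny_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_fixtures(tiny_spec())
  }
  .fixture_cache$bundle
}

quit_bins <- c(as.character(1:20), "20+")

flat_relapse <- function() setNames(rep(1, 21), quit_bins)

# Life table with zero mortality everywhere except the mandatory age-100
# closure; constant remaining life expectancy.
toy_life_table <- function(ex = 50) {
  life_table(dplyr::bind_rows(lapply(c("male", "female"), function(g) {
    tibble::tibble(gender = g, age = 0:100,
                   mortality = c(rep(0, 100), 1), life_expectancy = ex)
  })))
}

toy_pyramid <- function(cells = list()) {
  df <- tidyr::expand_grid(gender = c("male", "female"), age = 0:100)
  df$count <- 0
  for (cell in cells) {
    df$count[df$gender == cell$gender & df$age == cell$age] <- cell$count
  }
  df
}

toy_prevalence <- function(cells = list()) {
  df <- tidyr::expand_grid(gender = c("male", "female"), age = 0:100)
  df$current <- 0
  df$former <- 0
  for (cell in cells) {
    i <- df$gender == cell$gender & df$age == cell$age
    df$current[i] <- cell$current
    df$former[i] <- cell$former
  }
  df
}

toy_quit_time <- function() tibble::tibble(bin = "1", share = 1)

toy_risk <- function(rr = 1) {
  risk_model(tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = rr))
}

zero_births <- function() {
  tibble::tibble(gender = c("male", "female"), year = 2001L, count = 0)
}

zero_migration_total <- function() tibble::tibble(year = 2001L, count = 0)

zero_migration_age <- function() {
  tibble::tibble(gender = "male", age = 30L, share = 0)
}

# A one-product rate table with flat, age/gender-invariant annual
# probabilities for initiation (h), cessation (q) and relapse (rl).
one_product_rates <- function(h = 0, q = 0, rl = 0) {
  rows <- tibble::tibble(
    from = c("N", "C", "F"), to = c("C", "F", "C"),
    gender = "*", age_lo = 0L, age_hi = 100L, year = NA_integer_,
    mean = c(h, q, rl), lo95 = c(h, q, rl), hi95 = c(h, q, rl)
  )
  rate_table(rows, "cigarette")
}

toy_bundle <- function(pyramid = toy_pyramid(), prevalence = toy_prevalence(),
                       risk = toy_risk(), life_table = toy_life_table(),
                       births = zero_births(), rates = list()) {
  input_bundle(
    pyramid = pyramid, life_table = life_table, prevalence = prevalence,
    quit_time = toy_quit_time(), births = births,
    migration_total = zero_migration_total(),
    migration_age = zero_migration_age(),
    risk = risk, relapse_multiplier = flat_relapse(), rates = rates
  )
}
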