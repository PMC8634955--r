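test_that("former-user excess risk decays as a negative exponential", {
  expect_equal(former_excess_rr(3, 0, 10), 3)
  expect_equal(former_excess_rr(3, 10, 10), 2) # one half-life: half the excess
  expect_equal(former_excess_rr(3, 1e6, 10), 1, tolerance = 1e-12)
  expect_equal(former_excess_rr(2, c(0, 10, 20), 10), c(2, 1.5, 1.25))
  expect_error(former_excess_rr(3, 5, 0), "positive")
  expect_error(former_excess_rr(3, -1, 10), "non-negative")
})

test_that("joint-state relative risk follows the max-excess dual-use rule", {
  model <- risk_model(
    tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = 2),
    prrp_excess_fraction = c(thp = 0.10, ecig = 0.05)
  )
  expect_equal(
    joint_state_rr(c(cigarette = "never", thp = "never"), "none", model, "male", 50),
    1)
  # current smoker + current THP: smoking dominates
  expect_equal(
    joint_state_rr(c(cigarette = "current", thp = "current"), "none", model, "male", 50),
    2)
  # exclusive current e-cigarette: 1 + 0.05 * (2 - 1)
  expect_equal(
    joint_state_rr(c(cigarette = "never", ecig = "current"), "none", model, "male", 50),
    1.05)
  # former smoker one half-life out: 1 + 0.5 * (2 - 1)
  model10 <- risk_model(
    tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = 2),
    decay_halflife = 10
  )
  expect_equal(
    joint_state_rr(c(cigarette = "former"), "10", model10, "female", 60),
    1.5)
  # the open 20+ pool is evaluated at its representative time
  m25 <- risk_model(tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = 3),
                    decay_halflife = 10, quit20plus_years = 25)
  expect_equal(joint_state_rr(c(cigarette = "former"), "20+", m25, "male", 70),
               1 + 2 * 2^(-2.5))
})

test_that("raising any product's excess fraction never lowers a state's risk", {
  states <- enumerate_states(3)
  lo <- risk_model(tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = 2.5),
                   prrp_excess_fraction = c(ecig = 0.05, thp = 0.10))
  hi <- risk_model(tibble::tibble(gender = "*", age_lo = 0L, age_hi = 100L, rr = 2.5),
                   prrp_excess_fraction = c(ecig = 0.25, thp = 0.10))
  for (i in seq_len(nrow(states))) {
    bin <- if (states$cigarette[i] == "former") "5" else "none"
    r_lo <- joint_state_rr(states[i, ], bin, lo, "male", 55)
    r_hi <- joint_state_rr(states[i, ], bin, hi, "male", 55)
    expect_gte(r_hi, r_lo)
    expect_gte(r_lo, 1)
  }
})

test_that("never-smoker mortality decomposition reconstructs the all-cause rate", {
  expect_equal(derive_never_mortality(0.01, c(100), c(1))$never_rate, 0.01)
  d <- derive_never_mortality(0.01, c(50, 50), c(1, 2))
  expect_equal(d$never_rate, 0.01 / 1.5)
  expect_equal(d$status_rates, 0.01 / 1.5 * c(1, 2))
  expect_equal(derive_never_mortality(0, c(10, 20), c(1, 3))$never_rate, 0)
  # reconstruction property for arbitrary compositions
  set.seed(42)
  for (i in 1:20) {
    n <- runif(4, 0, 100)
    rr <- 1 + runif(4, 0, 3)
    m <- runif(1, 0, 0.1)
    d <- derive_never_mortality(m, n, rr)
    expect_equal(sum(n * d$status_rates) / sum(n), m, tolerance = 1e-12)
  }
  expect_error(derive_never_mortality(0.01, c(0, 0), c(1, 2)), "at least one")
  expect_error(derive_never_mortality(0.01, c(1, 1), c(0, 0)), "weights")
})

test_that("status-specific mortality conserves expected deaths", {
  pyr <- toy_pyramid(list(list(gender = "male", age = 60, count = 1000)))
  prev <- toy_prevalence(list(list(gender = "male", age = 60,
                                   current = 0.4, former = 0)))
  pop <- init_population(pyr, prev, toy_quit_time(), "cigarette", 2001)
  lt_rows <- dplyr::bind_rows(lapply(c("male", "female"), function(g) {
    tibble::tibble(gender = g, age = 0:100,
                   mortality = c(rep(0.01, 100), 1), life_expectancy = 20)
  }))
  lt <- life_table(lt_rows)
  rm2 <- toy_risk(rr = 2)
  res <- apply_status_mortality(pop, lt, rm2, 2001)
  # aggregate deaths match the unstratified life table at the derivation year
  expect_equal(sum(res$deaths$deaths), 1000 * 0.01, tolerance = 1e-9)
  # never-smokers die at the derived lower rate, smokers at twice it
  m_never <- 0.01 / (0.6 + 0.4 * 2)
  expect_equal(sum(res$deaths$deaths[res$deaths$state == "N"]),
               600 * m_never, tolerance = 1e-9)
  expect_equal(sum(res$deaths$deaths[res$deaths$state == "C"]),
               400 * 2 * m_never, tolerance = 1e-9)
  # with rr = 1 everywhere, scenario mortality equals the life table
  res1 <- apply_status_mortality(pop, lt, toy_risk(rr = 1), 2001)
  expect_equal(sum(res1$deaths$deaths[res1$deaths$state == "N"]), 600 * 0.01)
  expect_equal(sum(res1$deaths$deaths[res1$deaths$state == "C"]), 400 * 0.01)
})
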