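two_product_table <- function(rows) {
  rate_table(rows, c("cigarette", "ecig"))
}

test_that("rate tables validate flows and probability ordering", {
  good <- tibble::tibble(from = "N", to = "C", gender = "*", age_lo = 0L,
                         age_hi = 100L, year = NA_integer_,
                         mean = 0.02, lo95 = 0.01, hi95 = 0.05)
  expect_s3_class(rate_table(good, "cigarette"), "rate_table")
  expect_error(rate_table(dplyr::mutate(good, to = "F"), "cigarette"),
               "inadmissible")
  expect_error(rate_table(dplyr::mutate(good, lo95 = 0.03), "cigarette"),
               "lo95 <= mean")
  expect_error(rate_table(dplyr::mutate(good, hi95 = 1.2), "cigarette"),
               "lo95 <= mean <= hi95")
})

test_that("effective rates gate flows before a product's introduction year", {
  rows <- tibble::tibble(
    from = c("N.N", "N.N"), to = c("C.N", "N.C"), gender = "*",
    age_lo = 0L, age_hi = 100L, year = NA_integer_,
    mean = c(0.02, 0.01), lo95 = c(0.02, 0.01), hi95 = c(0.02, 0.01)
  )
  rt <- two_product_table(rows)
  mods <- scenario_modifiers(intro_year = c(ecig = 2014))
  expect_equal(effective_rate(rt, "N.N", "N.C", "male", 20, 2012, mods), 0)
  expect_equal(effective_rate(rt, "N.N", "N.C", "male", 20, 2014, mods), 0.01)
  # the cigarette market exists from the model start regardless
  expect_equal(effective_rate(rt, "N.N", "C.N", "male", 20, 2012, mods), 0.02)
})

test_that("the initiation decline is geometric and cigarette-specific", {
  rows <- tibble::tibble(
    from = c("N.N", "N.N"), to = c("C.N", "N.C"), gender = "*",
    age_lo = 0L, age_hi = 100L, year = NA_integer_,
    mean = c(0.02, 0.01), lo95 = c(0.02, 0.01), hi95 = c(0.02, 0.01)
  )
  rt <- two_product_table(rows)
  mods <- scenario_modifiers(init_decline_rate = 0.03, init_decline_start = 2020)
  expect_equal(effective_rate(rt, "N.N", "C.N", "male", 20, 2020, mods), 0.02)
  expect_equal(effective_rate(rt, "N.N", "C.N", "male", 20, 2030, mods),
               0.02 * 0.97^10)
  expect_equal(effective_rate(rt, "N.N", "C.N", "male", 20, 2019, mods), 0.02)
  # alternative-product initiation is untouched
  expect_equal(effective_rate(rt, "N.N", "N.C", "male", 20, 2030, mods), 0.01)
  # without a decline, rates are time-invariant after introduction
  mods0 <- scenario_modifiers()
  expect_equal(effective_rate(rt, "N.N", "C.N", "male", 20, 2005, mods0),
               effective_rate(rt, "N.N", "C.N", "male", 20, 2095, mods0))
})

test_that("pseudo-product blending is a row-wise affine combination", {
  rows_a <- tibble::tibble(
    from = c("C.N", "N.N"), to = c("C.C", "N.C"), gender = "*",
    age_lo = 14L, age_hi = 100L, year = NA_integer_,
    mean = c(0.10, 0.008), lo95 = c(0.05, 0.004), hi95 = c(0.15, 0.012)
  )
  rows_b <- rows_a
  rows_b$mean <- c(0.20, 0.002)
  rows_b$lo95 <- c(0.10, 0.001)
  rows_b$hi95 <- c(0.30, 0.003)
  a <- two_product_table(rows_a)
  b <- rate_table(rows_b, c("cigarette", "thp"))
  half <- combine_pseudo_prrp(a, b, 0.5)
  expect_equal(half$mean[half$from == "C.N"], 0.15)
  expect_equal(combine_pseudo_prrp(a, b, 0.63)$mean[1], 0.137)
  # CI bounds blend with the same weights
  expect_equal(half$lo95[1], 0.075)
  # weight 1 reproduces table A exactly
  w1 <- combine_pseudo_prrp(a, b, 1)
  expect_equal(w1$mean, a$mean)
  expect_equal(w1$hi95, a$hi95)
  # affine: blending a table with itself is the identity at any weight
  for (w in c(0, 0.3, 0.77)) {
    self <- combine_pseudo_prrp(a, a, w)
    expect_equal(self$mean, a$mean)
  }
  expect_error(combine_pseudo_prrp(a, b[-1, ], 0.5), "identical set")
})

test_that("pseudo-product risk fractions blend to the reported values", {
  expect_equal(100 * combine_pseudo_risk(0.05, 0.10, 0.50), 7.5)
  expect_equal(100 * combine_pseudo_risk(0.05, 0.10, 0.63), 6.85)
  expect_equal(combine_pseudo_risk(0.05, 0.10, 1), 0.05)
  expect_error(combine_pseudo_risk(0.05, 0.10, 1.2), "\\[0, 1\\]")
})

test_that("outflow sums above one are rescaled proportionally", {
  rows <- tibble::tibble(
    from = c("C", "C"), to = c("F", "F"), gender = c("male", "male"),
    age_lo = c(30L, 30L), age_hi = c(30L, 30L), year = NA_integer_,
    mean = c(0.8, 0.6), lo95 = c(0.8, 0.6), hi95 = c(0.8, 0.6)
  )
  # two rows feeding the same stock's outflow sum; S = 1.4
  rt <- rate_table(rows, "cigarette")
  expect_message(norm <- normalize_outflows(rt), "rescaled")
  expect_equal(sort(norm$mean[norm$gender == "male" & norm$age_lo == 30]),
               sort(c(0.8, 0.6) / 1.4))
  # sums at or below one are untouched
  ok <- rate_table(tibble::tibble(
    from = c("N", "C"), to = c("C", "F"), gender = "*", age_lo = 20L,
    age_hi = 20L, year = NA_integer_, mean = c(0.3, 0.3),
    lo95 = c(0.3, 0.3), hi95 = c(0.3, 0.3)
  ), "cigarette")
  expect_equal(sort(normalize_outflows(ok)$mean), rep(0.3, 4))
  # empty table passes through
  empty <- rate_table(rows[0, ], "cigarette")
  expect_equal(nrow(normalize_outflows(empty)), 0L)
})

test_that("initiation hazards are the discrete increments of ever-prevalence", {
  ever <- tibble::tibble(gender = "male", age = 10:35,
                         ever = c(rep(0, 5), seq(0, 0.42, length.out = 21)))
  h <- calibrate_initiation_from_prevalence(ever, c(15L, 30L))
  expect_equal(nrow(h), 16L)
  # hand value: E(15) = 0.10, E(16) = 0.19 -> h(15) = 0.10
  ever2 <- tibble::tibble(gender = "female", age = c(15, 16),
                          ever = c(0.10, 0.19))
  h2 <- calibrate_initiation_from_prevalence(ever2, c(15L, 15L))
  expect_equal(h2$initiation, 0.1)
  # flat prevalence gives zero initiation
  flat <- tibble::tibble(gender = "male", age = 10:31, ever = 0.3)
  expect_equal(calibrate_initiation_from_prevalence(flat, c(11L, 30L))$initiation,
               rep(0, 20))
  # decreasing prevalence floors at zero with a warning
  dec <- tibble::tibble(gender = "male", age = c(20, 21), ever = c(0.3, 0.25))
  expect_warning(hd <- calibrate_initiation_from_prevalence(dec, c(20L, 20L)),
                 "floored")
  expect_equal(hd$initiation, 0)
  expect_error(
    calibrate_initiation_from_prevalence(
      tibble::tibble(gender = "male", age = c(20, 21), ever = c(1, 1)),
      c(20L, 20L)),
    "< 1")
})

test_that("calibrated hazards reproduce the input curve under the recursion", {
  ever <- tibble::tibble(gender = "male", age = 11:31,
                         ever = 0.45 * plogis((11:31 - 19) / 2.5))
  ever$ever <- ever$ever - ever$ever[1] # zero at the window start
  h <- calibrate_initiation_from_prevalence(ever, c(11L, 30L))
  E <- 0
  for (i in seq_len(nrow(h))) {
    expect_equal(E, ever$ever[ever$age == h$age[i]], tolerance = 1e-12)
    E <- E + (1 - E) * h$initiation[i]
  }
  expect_equal(E, ever$ever[ever$age == 31], tolerance = 1e-12)
})
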