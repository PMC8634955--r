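test_that("life table construction enforces the schema and closing assumptions", {
  expect_s3_class(toy_life_table(), "life_table")
  bad <- tibble::as_tibble(toy_life_table())
  bad$mortality[bad$age == 100] <- 0.5
  expect_error(life_table(bad), "age 100")
  expect_error(life_table(bad[, -3]), "missing column")
  bad2 <- tibble::as_tibble(toy_life_table())
  bad2$mortality[5] <- 1.2
  expect_error(life_table(bad2), "\\[0, 1\\]")
})

test_that("initialisation splits the pyramid by smoking status and quit time", {
  pyr <- toy_pyramid(list(list(gender = "male", age = 40, count = 1000)))
  prev <- toy_prevalence(list(list(gender = "male", age = 40,
                                   current = 0.3, former = 0.2)))
  qt <- tibble::tibble(bin = c("1", "5", "20+"), share = c(0.5, 0.3, 0.2))
  pop <- init_population(pyr, prev, qt, "cigarette", 2001)
  expect_equal(population_total(pop), 1000)
  expect_equal(sum(pop$counts["male", "40", "C", ]), 300)
  expect_equal(pop$counts["male", "40", "F", "5"], 200 * 0.3)
  expect_equal(sum(pop$counts["male", "40", "N", ]), 500)
  # quit-time bins only carry former smokers
  expect_equal(sum(pop$counts[, , c("N", "C"), quit_bins]), 0)
  expect_equal(sum(pop$counts[, , "F", "none"]), 0)
})

test_that("ageing is a pure one-year shift that advances the quit clock", {
  pop <- empty_population("cigarette", 2001)
  pop$counts["male", "30", "C", "none"] <- 10
  pop$counts["female", "60", "F", "20"] <- 5
  pop$counts["male", "100", "N", "none"] <- 7
  aged <- age_population(pop)
  expect_equal(aged$year, 2002L)
  expect_equal(aged$counts["male", "31", "C", "none"], 10)
  expect_equal(aged$counts["female", "61", "F", "20+"], 5) # 20 saturates to 20+
  expect_equal(attr(aged, "aged_out"), 7) # the open age-100 cell empties
  expect_equal(population_total(aged), 15)
  # empty population stays empty
  expect_equal(population_total(age_population(empty_population())), 0)
})

test_that("births enter at age zero as never-users, split by gender", {
  pop <- empty_population("cigarette", 2001)
  sched <- list(births = tibble::tibble(gender = c("male", "female"),
                                        year = 2001L, count = c(60, 40)))
  pop2 <- apply_births(pop, sched, 2001)
  expect_equal(pop2$counts["male", "0", "N", "none"], 60)
  expect_equal(pop2$counts["female", "0", "N", "none"], 40)
  # carry-forward: later years reuse the last schedule year
  pop3 <- apply_births(pop, sched, 2050)
  expect_equal(population_total(pop3), 100)
})

test_that("migrants copy the resident product-status mix", {
  pop <- empty_population("cigarette", 2001)
  pop$counts["male", "30", "C", "none"] <- 50
  pop$counts["male", "30", "N", "none"] <- 50
  sched <- list(
    migration_total = tibble::tibble(year = 2001L, count = 100),
    migration_age = tibble::tibble(gender = "male", age = 30L, share = 1)
  )
  pop2 <- apply_migration(pop, sched, 2001)
  # +100 migrants where residents are 50% current smokers -> +50 smokers
  expect_equal(pop2$counts["male", "30", "C", "none"], 100)
  expect_equal(pop2$counts["male", "30", "N", "none"], 100)
  expect_equal(attr(pop2, "migration_applied"), 100)
})

test_that("zero net migration leaves the population unchanged", {
  pop <- empty_population("cigarette", 2001)
  pop$counts["female", "20", "N", "none"] <- 5
  sched <- list(
    migration_total = tibble::tibble(year = 2001L, count = 0),
    migration_age = tibble::tibble(gender = "female", age = 20L, share = 1)
  )
  pop2 <- apply_migration(pop, sched, 2001)
  expect_equal(pop2$counts, pop$counts)
})

test_that("removals beyond a cell are clamped at zero with a warning", {
  pop <- empty_population("cigarette", 2001)
  pop$counts["male", "30", "N", "none"] <- 4
  sched <- list(
    migration_total = tibble::tibble(year = 2001L, count = -10),
    migration_age = tibble::tibble(gender = "male", age = 30L, share = 1)
  )
  expect_warning(pop2 <- apply_migration(pop, sched, 2001), "clamped")
  expect_equal(population_total(pop2), 0)
  # removal from a fully empty cell also clamps
  empty <- empty_population("cigarette", 2001)
  expect_warning(pop3 <- apply_migration(empty, sched, 2001), "clamped")
  expect_equal(population_total(pop3), 0)
  expect_equal(attr(pop3, "migration_applied"), 0)
})

test_that("a closed population conserves its total over a long horizon", {
  pyr <- toy_pyramid(list(list(gender = "male", age = 20, count = 1234.5),
                          list(gender = "female", age = 35, count = 987.6)))
  b <- toy_bundle(pyramid = pyr)
  scen <- scenario("closed", one_product_rates(0, 0, 0))
  res <- run_scenario(b, scen, 2001, 2040)
  expect_true(all(abs(res$series$population - (1234.5 + 987.6)) <=
                    1e-9 * (1234.5 + 987.6)))
  expect_equal(res$series$deaths, rep(0, 40))
  # ageing is a pure shift: the male cohort sits at age 20 + t
  expect_equal(sum(res$final_population$counts["male", "60", , ]), 1234.5)
})

test_that("with mortality only, the population shrinks elementwise along cohorts", {
  lt_rows <- dplyr::bind_rows(lapply(c("male", "female"), function(g) {
    tibble::tibble(gender = g, age = 0:100,
                   mortality = c(rep(0.02, 100), 1), life_expectancy = 40)
  }))
  b <- toy_bundle(
    pyramid = toy_pyramid(list(list(gender = "male", age = 20, count = 100))),
    life_table = life_table(lt_rows)
  )
  res <- run_scenario(b, scenario("mortality", one_product_rates()), 2001, 2030)
  pops <- res$series$population
  expect_true(all(diff(pops) < 0))
  expect_equal(pops[2] / pops[1], 0.98, tolerance = 1e-12)
})
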