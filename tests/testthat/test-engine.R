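test_that("a step with zero rates and zero mortality is pure ageing", {
  pyr <- toy_pyramid(list(list(gender = "male", age = 30, count = 100)))
  prev <- toy_prevalence(list(list(gender = "male", age = 30,
                                   current = 0.25, former = 0.25)))
  pop <- init_population(pyr, prev, toy_quit_time(), "cigarette", 2001)
  res <- step_year(pop, one_product_rates(0, 0, 0), toy_life_table(),
                   toy_risk(), list(births = zero_births(),
                                    migration_total = zero_migration_total(),
                                    migration_age = zero_migration_age()))
  expect_equal(res$population$year, 2002L)
  expect_equal(sum(res$deaths$deaths), 0)
  expect_equal(res$population$counts["male", "31", "C", "none"], 25)
  expect_equal(res$population$counts["male", "31", "F", "2"], 25) # clock advanced
  expect_equal(abs(res$diagnostics$conservation_residual), 0)
})

test_that("a quit rate moves the expected fraction into the first quit bin", {
  pyr <- toy_pyramid(list(list(gender = "female", age = 40, count = 200)))
  prev <- toy_prevalence(list(list(gender = "female", age = 40,
                                   current = 0.5, former = 0)))
  pop <- init_population(pyr, prev, toy_quit_time(), "cigarette", 2001)
  res <- step_year(pop, one_product_rates(0, 0.2, 0), toy_life_table(),
                   toy_risk(), list(births = zero_births(),
                                    migration_total = zero_migration_total(),
                                    migration_age = zero_migration_age()))
  # 20% of the 100 current smokers quit during the year; after ageing they are
  # one year abstinent
  expect_equal(res$population$counts["female", "41", "F", "1"], 20)
  expect_equal(res$population$counts["female", "41", "C", "none"], 80)
})

test_that("alternative-product stocks stay empty before the introduction year", {
  b <- tiny_bundle()
  scen_thp <- default_scenarios(b)$thp
  res <- run_scenario(b, scen_thp, 2001, 2020)
  pre <- res$series$prevalence_thp[res$series$year < 2014]
  post <- res$series$prevalence_thp[res$series$year >= 2015]
  expect_equal(pre, rep(0, sum(res$series$year < 2014)))
  expect_true(all(post > 0))
})

test_that("prevalence is the share of age-eligible current users", {
  pop <- empty_population(c("cigarette", "ecig"), 2001)
  pop$counts["male", "30", "C.N", "none"] <- 1
  pop$counts["male", "40", "C.C", "none"] <- 1
  pop$counts["male", "50", "N.N", "none"] <- 8
  pop$counts["male", "5", "C.N", "none"] <- 3 # below the age-14 cut
  expect_equal(prevalence(pop, "cigarette"), 20)
  # dual users count under both products by default
  expect_equal(prevalence(pop, "ecig"), 10)
  # the exclusive convention drops the dual user
  expect_equal(prevalence(pop, "cigarette", dual = "exclusive"), 10)
  expect_equal(prevalence(empty_population()), 0)
  all_smokers <- empty_population("cigarette", 2001)
  all_smokers$counts["female", "20", "C", "none"] <- 7
  expect_equal(prevalence(all_smokers), 100)
})

test_that("life-years lost weight deaths by remaining life expectancy", {
  lt <- toy_life_table(ex = 22)
  deaths <- tibble::tibble(year = 2030L, gender = "male", age = 60L, deaths = 1)
  lyl <- life_years_lost(deaths, lt)
  expect_equal(lyl$life_years_lost, 22)
  expect_equal(lyl$cum_life_years_lost, 22)
  # cumulative series is non-decreasing
  deaths2 <- tibble::tibble(year = c(2030L, 2031L), gender = "male",
                            age = 60L, deaths = c(1, 0.5))
  expect_equal(life_years_lost(deaths2, lt)$cum_life_years_lost, c(22, 33))
})

test_that("identical scenarios compare to zero reduction everywhere", {
  b <- tiny_bundle()
  scen <- default_scenarios(b)$smoking_only
  r1 <- run_scenario(b, scen, 2001, 2030)
  r2 <- run_scenario(b, scen, 2001, 2030)
  cmp <- compare_scenarios(list(a = r1, b = r2), baseline = "a",
                           years = seq(2010, 2030, 10))
  expect_equal(cmp$lyl_reduction_m[cmp$scenario == "b"], rep(0, 3))
  # strictly lower mortality gives positive, non-decreasing reductions
  cmp2 <- compare_scenarios(
    list(base = r1, thp = run_scenario(b, default_scenarios(b)$thp, 2001, 2030)),
    baseline = "base", years = 2015:2030)
  red <- cmp2$lyl_reduction_m[cmp2$scenario == "thp"]
  expect_true(all(diff(red) >= 0))
})

test_that("a faster initiation decline never raises smoking prevalence", {
  b <- tiny_bundle()
  base_rates <- b$rates$smoking
  r0 <- run_scenario(b, scenario("static", base_rates), 2001, 2050)
  r3 <- run_scenario(
    b,
    scenario("declining", base_rates,
             scenario_modifiers(init_decline_rate = 0.03,
                                init_decline_start = 2020)),
    2001, 2050)
  expect_true(all(r3$series$smoking_prevalence <=
                    r0$series$smoking_prevalence + 1e-12))
  after <- r3$series$year > 2025
  expect_true(all(r3$series$smoking_prevalence[after] <
                    r0$series$smoking_prevalence[after]))
})

test_that("a pseudo-product at weight 1 reproduces the sole-product scenario", {
  b <- tiny_bundle()
  ecig <- default_scenarios(b)$ecig
  pseudo <- scenario(
    "pseudo at weight 1",
    combine_pseudo_prrp(b$rates$ecig, b$rates$thp, 1,
                        products = c("cigarette", "pseudo_prrp")),
    scenario_modifiers(intro_year = c(pseudo_prrp = 2010)),
    prrp_excess_fraction = c(pseudo_prrp = combine_pseudo_risk(0.05, 0.10, 1))
  )
  r_ecig <- run_scenario(b, ecig, 2001, 2030)
  r_pseudo <- run_scenario(b, pseudo, 2001, 2030)
  expect_equal(r_pseudo$series$smoking_prevalence,
               r_ecig$series$smoking_prevalence)
  expect_equal(r_pseudo$series$prrp_prevalence, r_ecig$series$prrp_prevalence)
  expect_equal(r_pseudo$series$cum_life_years_lost,
               r_ecig$series$cum_life_years_lost)
  # a blended scenario lies between the two sole-product scenarios early on
  mid <- run_scenario(b, default_scenarios(b)$pseudo_50_50, 2001, 2030)
  r_thp <- run_scenario(b, default_scenarios(b)$thp, 2001, 2030)
  y <- mid$series$year == 2030
  expect_lte(mid$series$smoking_prevalence[y],
             r_ecig$series$smoking_prevalence[y] + 1e-9)
  expect_gte(mid$series$smoking_prevalence[y],
             r_thp$series$smoking_prevalence[y] - 1e-9)
})

test_that("projections are deterministic given identical configuration", {
  b <- tiny_bundle()
  scen <- default_scenarios(b)$ecig
  r1 <- run_scenario(b, scen, 2001, 2030)
  r2 <- run_scenario(b, scen, 2001, 2030)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$deaths_by_age, r2$deaths_by_age)
})

test_that("tidy, glance and autoplot work on projection results", {
  b <- tiny_bundle()
  r <- run_scenario(b, default_scenarios(b)$ecig, 2001, 2015)
  td <- tidy(r)
  expect_true(all(c("scenario", "year", "metric", "value") %in% names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_lt(gl$max_conservation_residual, 1e-6)
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(r, type = "life_years_lost"), "ggplot")
})
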