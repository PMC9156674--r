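test_that("every generator is a pure function of its scenario seed", {
  fires <- data.frame(year = 2004, season = "early", amplitude = 1.0)
  fires$footprint <- list(disc_footprint(200, 200, 100))
  fscn <- fire_scenario(10, 15, years = 2000:2009, fires = fires, noise_sd = 0.05, seed = 3)
  l1 <- gen_fire_landscape(fscn); l2 <- gen_fire_landscape(fscn)
  expect_identical(l1$composites[[5]]$nir, l2$composites[[5]]$nir)
  pscn <- population_scenario(seed = 3)
  expect_identical(gen_tree_population(pscn), gen_tree_population(pscn))
  sscn <- survival_scenario(seed = 3)
  expect_identical(gen_survival_histories(sscn), gen_survival_histories(sscn))
  trees <- data.frame(series = "AAA001A", establishment_year = 1900,
                      sample_height_cm = 100, sample_type = "core",
                      pith_offset = 1, segment = 1)
  rscn <- ring_scenario(trees, seed = 3)
  expect_identical(gen_ring_series(rscn), gen_ring_series(rscn))
  fuscn <- fuel_scenario(seed = 3)
  expect_identical(gen_fuel_samples(fuscn), gen_fuel_samples(fuscn))
  # and the global RNG state is left untouched
  set.seed(1); before <- .Random.seed
  invisible(gen_fuel_samples(fuscn))
  expect_identical(.Random.seed, before)
})

test_that("fire scenarios enforce their invariants", {
  expect_error(fire_scenario(10, 10, years = 2005), "at least 2 years")
  expect_error(fire_scenario(10, 10, noise_sd = -1), "nonnegative")
  out <- data.frame(year = 2001, season = "late", amplitude = 1)
  out$footprint <- list(disc_footprint(5000, 5000, 100)) # beyond a 300 m grid
  expect_error(fire_scenario(10, 10, years = 2000:2005, fires = out), "outside the grid")
  neg <- data.frame(year = 2001, season = "late", amplitude = -0.5)
  neg$footprint <- list(disc_footprint(150, 150, 50))
  expect_error(fire_scenario(10, 10, years = 2000:2005, fires = neg), "nonnegative")
})

test_that("noiseless forcing makes the thresholded anomaly equal the truth mask", {
  fires <- data.frame(year = 2005, season = "late", amplitude = 1.0)
  fires$footprint <- list(disc_footprint(250, 200, 130))
  scn <- fire_scenario(15, 20, years = 2000:2009, fires = fires, noise_sd = 0, seed = 1)
  land <- gen_fire_landscape(scn)
  stk <- map_fire_history(land$composites, cutoff = 0.75)
  tm <- land$truth[[which(vapply(land$truth, function(m) {
    attr(m, "year") == 2005 && attr(m, "season") == "late"
  }, logical(1)))]]
  i <- which(stk$years == 2005 & stk$seasons == "late")
  expect_equal(unclass(stk$masks[[i]]), unclass(tm), ignore_attr = TRUE)
  # all other layers are burn-free
  for (j in setdiff(seq_along(stk$masks), i)) expect_false(any(stk$masks[[j]]))
})

test_that("singleton-only populations have Poisson mean counts", {
  scn <- population_scenario(domain = c(500, 100), parent_intensity_ha = 2,
                             offspring_mean = 0, singleton_intensity_ha = 3,
                             dead_prop = 0)
  counts <- vapply(1:200, function(s) {
    scn$seed <- s
    nrow(gen_tree_population(scn))
  }, numeric(1))
  lambda <- 3 * 5 # intensity x 5 ha
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 200) + 0.2)
})

test_that("population attributes respect the scenario", {
  scn <- population_scenario(dead_prop = 0, seed = 5)
  stems <- gen_tree_population(scn)
  expect_true(all(stems$status == "live"))
  only_seedlings <- population_scenario(
    mixture = c(seedling = 1, sapling = 0, small = 0, medium = 0, large = 0, very_large = 0),
    seed = 5)
  s2 <- gen_tree_population(only_seedlings)
  expect_true(all(s2$size_class == "seedling"))
  expect_true(all(s2$height_m < 0.1))
  expect_error(population_scenario(domain = cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
  # generated dimensions are consistent with the assigned class
  stems3 <- gen_tree_population(population_scenario(seed = 8))
  expect_identical(assign_size_class(stems3$height_m, stems3$d1_0_cm, "A"),
                   stems3$size_class)
})

test_that("survival chains are monotone and hit closed-form expectations", {
  scn <- survival_scenario(survival = c(adult = 0.973), census_years = c(2006, 2010, 2019),
                           initial_counts = c(adult = 1000), seed = 12)
  cen <- gen_survival_histories(scn)
  # monotone: dead at an earlier census implies dead at every later one
  expect_true(all(!(cen$status_2010 == "dead" & cen$status_2019 == "live")))
  frac <- mean(cen$status_2019 == "live")
  p13 <- 0.973^13
  expect_lt(abs(frac - p13), 4 * sqrt(p13 * (1 - p13) / 1000))
  all_live <- gen_survival_histories(
    survival_scenario(survival = c(a = 1), census_years = c(2000, 2010),
                      initial_counts = c(a = 50)))
  expect_true(all(all_live$status_2010 == "live"))
  none <- gen_survival_histories(
    survival_scenario(survival = c(a = 0), census_years = c(2000, 2001),
                      initial_counts = c(a = 50)))
  expect_true(all(none$status_2001 == "dead"))
})

test_that("ring generation rejects impossible scenarios and clamps heights", {
  trees <- data.frame(series = "BAD001A", establishment_year = 2010,
                      sample_height_cm = 130, sample_type = "core",
                      pith_offset = 10, segment = 1)
  expect_error(gen_ring_series(ring_scenario(trees, end_year = 2014)), "nonpositive")
  zero <- data.frame(series = "OK0001A", establishment_year = 2000,
                     sample_height_cm = 0, sample_type = "core",
                     pith_offset = 0, segment = 1)
  rs <- gen_ring_series(ring_scenario(zero, end_year = 2014))
  yrs <- as.integer(rownames(rs$rwl))
  expect_equal(min(yrs[!is.na(rs$rwl[[1]])]), 2000) # first ring = establishment
})

test_that("fuel samples invert the moisture conversion and match region medians", {
  scn <- fuel_scenario(regions = data.frame(region = c("lo", "hi"),
                                            median_gm2 = c(35, 70),
                                            sdlog = c(0.4, 0.7),
                                            n_units = c(63, 63)),
                       seed = 6)
  q <- gen_fuel_samples(scn)
  expect_equal(dry_load(q$fresh_g, q$moisture, q$area_m2), q$dry_gm2, tolerance = 1e-12)
  expect_lt(abs(median(q$dry_gm2[q$region == "lo"]) - 35) / 35, 0.10)
  expect_lt(abs(median(q$dry_gm2[q$region == "hi"]) - 70) / 70, 0.10)
  dry0 <- fuel_scenario(moisture_range = c(0, 0), seed = 1)
  q0 <- gen_fuel_samples(dry0)
  expect_equal(q0$fresh_g, q0$dry_gm2 * q0$area_m2, tolerance = 1e-12) # moisture 0
  expect_error(fuel_scenario(moisture_range = c(0.2, 1)), "moisture")
})
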