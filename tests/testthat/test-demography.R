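test_that("size classes follow both schemes with lower-inclusive boundaries", {
  expect_equal(assign_size_class(0.05, scheme = "A"), "seedling")
  expect_equal(assign_size_class(1.0, scheme = "A"), "sapling")
  expect_equal(assign_size_class(6, 25, scheme = "A"), "large")
  expect_equal(assign_size_class(5, 10, scheme = "A"), "medium") # boundary: 10 -> medium
  expect_equal(assign_size_class(1.0, scheme = "B"), "juvenile")
  expect_equal(assign_size_class(2, 3, scheme = "B"), "very_small")
  expect_equal(assign_size_class(NA, 30, scheme = "B"), "very_large")
  expect_error(assign_size_class(3, NA, scheme = "A"), "missing D1.0")
  # the schemes agree where their diameter classes coincide (>= 10 cm)
  for (d in c(10, 15, 20, 25, 30, 45)) {
    expect_equal(assign_size_class(5, d, scheme = "A"),
                 assign_size_class(5, d, scheme = "B"))
  }
})

test_that("segment densities scale counts by the class-specific sampled band", {
  stems <- data.frame(
    segment = rep(1:2, c(10, 20)),
    size_class = "medium", status = "live",
    dist_m = 5
  )
  d <- segment_densities(stems, segments = 1:2)
  row <- d[d$size_class == "medium" & d$status == "live", ]
  expect_equal(row$mean_ha, 30) # 20 and 40 per ha
  expect_equal(row$se_ha, 10)
  # seedlings only count within the 2 m band
  seedl <- data.frame(segment = 1, size_class = "seedling", status = "live",
                      dist_m = c(1, 1.5, 10))
  ds <- segment_densities(seedl, segments = 1)
  expect_equal(ds$mean_ha[ds$size_class == "seedling" & ds$status == "live"],
               2 / (100 * 4 / 1e4)) # 2 stems in 0.04 ha
  none <- segment_densities(stems[0, ], segments = 1:3)
  expect_true(all(none$mean_ha == 0) && all(none$se_ha == 0))
  expect_error(segment_densities(stems, segment_length_m = 0), "positive")
})

test_that("density estimator is unbiased on homogeneous Poisson populations", {
  scn0 <- population_scenario(domain = c(1000, 50), parent_intensity_ha = 0,
                              offspring_mean = 0, singleton_intensity_ha = 27,
                              mixture = c(seedling = 0, sapling = 0, small = 1,
                                          medium = 0, large = 0, very_large = 0),
                              dead_prop = 0)
  means <- vapply(1:300, function(s) {
    scn0$seed <- s
    stems <- gen_tree_population(scn0)
    d <- segment_densities(stems, segments = 1:10)
    d$mean_ha[d$size_class == "small" & d$status == "live"]
  }, numeric(1))
  expect_equal(mean(means), 27, tolerance = 0.01)
})

test_that("annualized survival implements the interval-to-annual conversion", {
  expect_equal(annualized_survival(1000, 700, 13), 97.3)
  expect_equal(annualized_survival(50, 50, 10), 100.0)
  expect_equal(annualized_survival(385, 0, 13), 0.0)
  expect_error(annualized_survival(0, 0, 13), "positive")
  expect_error(annualized_survival(10, 11, 13), "n2")
  # inverse property: recover the generating annual rate
  for (p in c(0.90, 0.95, 0.99)) {
    n1 <- 1e5
    est <- annualized_survival(n1, round(n1 * p^13), 13)
    expect_equal(est, 100 * p, tolerance = 0.1 / (100 * p))
  }
})

test_that("survival by class freezes class at tagging and recovers generator rates", {
  scn <- survival_scenario(seed = 21)
  cen <- gen_survival_histories(scn)
  out <- survival_by_class(cen, 2006, 2019)
  expect_equal(out$n_start, unname(scn$initial_counts))
  for (i in seq_len(nrow(out))) {
    cls <- out$size_class[i]
    p_true <- scn$survival[[cls]]
    n1 <- out$n_start[i]
    # binomial CI on the 13-year survival fraction, mapped through the
    # annualization; juveniles at 0.70/yr go extinct (0 is the truth's floor)
    s13 <- p_true^13
    se <- sqrt(s13 * (1 - s13) / n1)
    lo <- max(0, s13 - 4 * se); hi <- min(1, s13 + 4 * se)
    est_frac <- out$n_end[i] / n1
    expect_gte(est_frac, lo)
    expect_lte(est_frac, hi)
  }
  expect_error(survival_by_class(cen, 2006, 2006), "after")
  expect_error(survival_by_class(cen[, 1:5], 2006, 2019), "status columns")
})

test_that("stand status rule reproduces the category definitions", {
  healthy <- classify_stand_status(
    c(seedling = 2, sapling = 3, small = 4, medium = 3, large = 2, very_large = 1),
    dead_stems = 2)
  expect_equal(as.character(healthy), "healthy")
  single <- classify_stand_status(c(very_large = 1), dead_stems = 0)
  expect_equal(as.character(single), "singleton")
  new <- classify_stand_status(c(sapling = 5), dead_stems = 0)
  expect_equal(as.character(new), "new")
  recov <- classify_stand_status(c(seedling = 4, sapling = 2, small = 1), dead_stems = 3)
  expect_equal(as.character(recov), "recovering")
  degr <- classify_stand_status(c(large = 1), dead_stems = 6)
  expect_equal(as.character(degr), "degraded")
  expect_equal(as.character(classify_stand_status(integer(0), 0)), "absent")
  expect_false(is.null(attr(healthy, "rules"))) # thresholds recorded in the result
})

test_that("indicative ages reproduce the survey age-class boundaries", {
  a10 <- indicative_age(10)
  expect_equal(a10$age_yr, 58.14, tolerance = 1e-3)
  expect_equal(a10$age_decade, 60)
  a30 <- indicative_age(30)
  expect_equal(a30$age_yr, 138.14, tolerance = 1e-3)
  expect_equal(a30$age_decade, 140)
  a0 <- indicative_age(0)
  expect_equal(a0$age_yr, 18.14, tolerance = 1e-3) # seedling-to-1-m time only
  expect_error(indicative_age(10, growth_rate_mm_yr = 0), "positive")
})
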