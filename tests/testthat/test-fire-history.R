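mask_layer <- function(m, year, season) {
  attr(m, "year") <- year; attr(m, "season") <- season
  m
}

empty3 <- function() matrix(FALSE, 3, 3)

test_that("time since fire counts back to the latest burn and censors never-burnt cells", {
  burn99 <- empty3(); burn99[1, 1] <- TRUE
  burn04 <- empty3(); burn04[1, 1] <- TRUE; burn04[2, 2] <- TRUE
  masks <- list(mask_layer(burn99, 1999, "late"), mask_layer(burn04, 2004, "early"))
  for (y in 1990:2006) {
    masks[[length(masks) + 1L]] <- mask_layer(empty3(), y, "late")
  }
  stk <- fire_history_stack(masks)
  tg <- time_since_fire(stk, 2006)
  expect_equal(tg$tsf[1, 1], 2)        # burnt 1999 and 2004
  expect_equal(tg$tsf[2, 2], 2)
  expect_true(tg$censored[3, 3])
  expect_equal(tg$tsf[3, 3], 16)       # record starts 1990
  tg04 <- time_since_fire(stk, 2004)
  expect_equal(tg04$tsf[1, 1], 0)      # burnt in the query year
  expect_error(time_since_fire(stk, 1993), "five years")
})

test_that("patch extraction follows the connectivity rule and conserves area", {
  full <- list(tsf = matrix(10, 3, 3), censored = matrix(FALSE, 3, 3),
               record_years = 15, query_year = 2005,
               mask = matrix(TRUE, 3, 3), cell_size = 30)
  class(full) <- "tsf_grid"
  p <- long_unburnt_patches(full)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_ha, 0.81)
  # checkerboard: isolated under rook, a single patch under queen
  nr <- 6
  chk <- outer(1:nr, 1:nr, function(i, j) (i + j) %% 2 == 0)
  g <- full
  g$tsf <- ifelse(chk, 10, 1); g$censored <- matrix(FALSE, nr, nr)
  g$mask <- matrix(TRUE, nr, nr)
  p4 <- long_unburnt_patches(g, connectivity = 4)
  p8 <- long_unburnt_patches(g, connectivity = 8)
  expect_equal(nrow(p4), sum(chk))
  expect_equal(nrow(p8), 1)
  expect_equal(sum(p8$cells) * 30^2 / 1e4, sum(p8$area_ha))
  nomask <- full; nomask$mask <- matrix(FALSE, 3, 3)
  expect_error(long_unburnt_patches(nomask), "mask is empty")
})

test_that("TSF and patch labelling match brute-force oracles on random stacks", {
  set.seed(42)
  for (rep in 1:30) {
    stk <- random_stack(nr = 12, nc = 12, years = 1990:2000)
    qy <- sample(1995:2000, 1)
    tg <- time_since_fire(stk, qy)
    per_year <- lapply(stk$masks, identity)
    orc <- oracle_tsf(per_year, stk$years, qy, stk$first_year)
    expect_equal(tg$tsf, orc$tsf, ignore_attr = TRUE)
    expect_equal(tg$censored, orc$censored, ignore_attr = TRUE)
    conn <- sample(c(4, 8), 1)
    eligible <- (tg$censored | tg$tsf > 5)
    p <- long_unburnt_patches(tg, connectivity = conn)
    lab <- oracle_label(eligible, conn)
    expect_equal(nrow(p), max(c(0, lab), na.rm = TRUE))
    expect_equal(sum(p$cells), sum(eligible))
    expect_equal(sort(p$cells), sort(as.vector(table(lab))))
  }
})

test_that("regime summary uses union semantics and respects the analysis mask", {
  all_cells <- matrix(TRUE, 3, 3)
  masks <- list()
  for (y in 1990:1996) {
    e <- if (y == 1996) all_cells else empty3()
    l <- if (y == 1996) all_cells else empty3()
    masks <- c(masks, list(mask_layer(e, y, "early"), mask_layer(l, y, "late")))
  }
  stk <- fire_history_stack(masks)
  s <- summarize_regime(stk)
  r96 <- s[s$year == 1996, ]
  expect_equal(r96$p_total, 1) # union of identical early/late masks, not their sum
  expect_equal(r96$p_early, 1)
  r95 <- s[s$year == 1995, ]
  expect_equal(r95$p_total, 0)
  expect_equal(r95$mean_tsf, 5) # censored at record length
  # union bound across all years with data
  ok <- !is.na(s$p_total)
  expect_true(all(s$p_total[ok] <= s$p_early[ok] + s$p_late[ok] + 1e-12))
  expect_true(all(s$p_total[ok] >= pmax(s$p_early[ok], s$p_late[ok]) - 1e-12))
})

test_that("end-to-end mapping recovers generator truth exactly without noise", {
  fires <- data.frame(year = c(2003, 2003, 2011), season = c("early", "late", "late"),
                      amplitude = 1.0)
  fires$footprint <- list(disc_footprint(200, 200, 120),
                          disc_footprint(700, 350, 150),
                          disc_footprint(400, 150, 100))
  scn <- fire_scenario(20, 30, cell_size = 30, years = 2000:2019, fires = fires,
                       noise_sd = 0, seed = 11)
  land <- gen_fire_landscape(scn)
  stk <- map_fire_history(land$composites, cutoff = 0.75)
  for (tm in land$truth) {
    i <- which(stk$years == attr(tm, "year") & stk$seasons == attr(tm, "season"))
    expect_equal(unclass(stk$masks[[i]]), unclass(tm), ignore_attr = TRUE)
  }
  # constructed truth: disjoint early/late scars sum exactly in the union
  sm <- summarize_regime(stk)
  r03 <- sm[sm$year == 2003, ]
  expect_equal(r03$p_total, r03$p_early + r03$p_late, tolerance = 1e-12)
})

test_that("burn-mask recovery survives additive noise well below the cutoff margin", {
  fires <- data.frame(year = 2005, season = "late", amplitude = 1.0)
  fires$footprint <- list(disc_footprint(350, 250, 180))
  scn <- fire_scenario(20, 25, cell_size = 30, years = 2000:2019, fires = fires,
                       noise_sd = 0.05, seed = 5)
  land <- gen_fire_landscape(scn)
  stk <- map_fire_history(land$composites, cutoff = 0.75)
  tm <- land$truth[[which(vapply(land$truth, function(m) {
    attr(m, "year") == 2005 && attr(m, "season") == "late"
  }, logical(1)))]]
  mapped <- stk$masks[[which(stk$years == 2005 & stk$seasons == "late")]]
  recall <- sum(mapped & tm) / sum(tm)
  expect_gt(sum(tm), 0)
  expect_equal(recall, 1.0)
})
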