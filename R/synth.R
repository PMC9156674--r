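# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with known ground truth, so all downstream stages are
# testable without field or satellite data. All generators are pure functions
# of (scenario, seed): component streams derive from the scenario seed via
# split_seed().

# ---------------------------------------------------------------------------
# Fire landscapes

#' Fire-landscape scenario
#'
#' Describes a multi-year stack of seasonal composites containing burn scars
#' of known footprint, season, year and dNBR amplitude, over a static
#' landscape-feature field with additive noise.
#'
#' The construction works backwards from the target dNBR: within each year,
#' the MAM composite carries the baseline NBR and each later window drops by
#' the static field plus that interval's fire signal, so the seasonal dNBR
#' equals `static + amplitude * footprint + noise` exactly. A cell burning
#' `k` of `Y` years therefore retains a mean-adjusted anomaly of
#' `amplitude * (1 - k/Y)`; scenarios must keep this above the intended
#' cutoff for detectable fires.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param cell_size cell edge length (m, default 30).
#' @param years inclusive span of calendar years (>= 2 years).
#' @param fires data frame with columns `year`, `season` (`"early"`/`"late"`),
#'   `amplitude` (dNBR units, >= 0) and a list-column `footprint` of polygon
#'   vertex matrices (map units; see [disc_footprint()]).
#' @param static_field per-cell constant dNBR offset: a matrix, a scalar, or
#'   `"random"` (default) for a seeded uniform field on ±0.05.
#' @param noise_sd additive dNBR noise standard deviation (>= 0).
#' @param baseline_nbr NBR of unburnt ground in the MAM window (default 0.4).
#' @param band_sum NIR + SWIR reflectance total used to encode NBR into bands
#'   (default 0.8).
#' @param seed integer seed.
#' @return object of class `fire_scenario`.
#' @export
fire_scenario <- function(nrow, ncol, cell_size = 30, years = 2000:2019,
                          fires = NULL, static_field = "random", noise_sd = 0,
                          baseline_nbr = 0.4, band_sum = 0.8, seed = 1) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2L) stop("scenario must span at least 2 years", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (is.null(fires)) {
    fires <- data.frame(year = integer(0), season = character(0), amplitude = numeric(0))
    fires$footprint <- list()
  }
  if (nrow(fires) > 0) {
    if (any(!fires$year %in% years)) stop("fire year outside scenario span", call. = FALSE)
    if (any(!fires$season %in% c("early", "late"))) stop("fire season must be 'early' or 'late'", call. = FALSE)
    if (any(fires$amplitude < 0)) stop("fire amplitude must be nonnegative", call. = FALSE)
    xmax <- ncol * cell_size; ymax <- nrow * cell_size
    for (fp in fires$footprint) {
      fp <- as.matrix(fp)
      if (min(fp[, 1]) < 0 || max(fp[, 1]) > xmax || min(fp[, 2]) < 0 || max(fp[, 2]) > ymax) {
        stop("fire footprint lies outside the grid", call. = FALSE)
      }
    }
  }
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol), cell_size = cell_size,
         years = years, fires = fires, static_field = static_field,
         noise_sd = noise_sd, baseline_nbr = baseline_nbr, band_sum = band_sum,
         seed = as.integer(seed)),
    class = "fire_scenario"
  )
}

#' Generate a seasonal composite stack with known burn truth
#'
#' Builds three seasonal composites (MAM, JJA, SON) per year whose paired
#' dNBR exceeds the fire amplitude inside the true footprints (rasterized by
#' the center-point rule) and hovers near the static field ± noise elsewhere,
#' plus the true per-(year, season) burn masks.
#'
#' @param scenario a [fire_scenario()].
#' @return list with `composites` (list of [seasonal_composite()]), `truth`
#'   (list of logical masks with `year`/`season` attributes), and `static`
#'   (the realized static field matrix).
#' @export
gen_fire_landscape <- function(scenario) {
  stopifnot(inherits(scenario, "fire_scenario"))
  nr <- scenario$nrow; nc <- scenario$ncol
  static <- scenario$static_field
  if (identical(static, "random")) {
    static <- with_seed(split_seed(scenario$seed, 2L),
                        matrix(stats::runif(nr * nc, -0.05, 0.05), nr, nc))
  } else if (length(static) == 1L) {
    static <- matrix(as.numeric(static), nr, nc)
  }
  signal <- function(y, season) {
    # overlapping same-season footprints do not stack: a cell carries the
    # strongest signal covering it (burnt is burnt)
    D <- matrix(0, nr, nc)
    sel <- which(scenario$fires$year == y & scenario$fires$season == season)
    for (i in sel) {
      fp <- rasterize_polygon(scenario$fires$footprint[[i]], nr, nc, scenario$cell_size)
      D <- pmax(D, scenario$fires$amplitude[i] * fp)
    }
    D
  }
  truth_mask <- function(y, season) {
    m <- matrix(FALSE, nr, nc)
    sel <- which(scenario$fires$year == y & scenario$fires$season == season &
                   scenario$fires$amplitude > 0)
    for (i in sel) {
      m <- m | rasterize_polygon(scenario$fires$footprint[[i]], nr, nc, scenario$cell_size)
    }
    attr(m, "year") <- y; attr(m, "season") <- season
    m
  }
  nbr_to_composite <- function(nbr, y, window) {
    if (any(abs(nbr) > 1)) {
      stop("implied NBR outside [-1, 1]; reduce amplitude, baseline or static field",
           call. = FALSE)
    }
    seasonal_composite(y, window,
                       nir = scenario$band_sum * (1 + nbr) / 2,
                       swir = scenario$band_sum * (1 - nbr) / 2,
                       cell_size = scenario$cell_size)
  }
  composites <- list(); truth <- list()
  with_seed(split_seed(scenario$seed, 1L), {
    e_sd <- scenario$noise_sd / sqrt(2)
    for (y in scenario$years) {
      noise <- replicate(3, if (e_sd > 0) matrix(stats::rnorm(nr * nc, 0, e_sd), nr, nc)
                         else matrix(0, nr, nc), simplify = FALSE)
      De <- signal(y, "early"); Dl <- signal(y, "late")
      nbr_mam <- matrix(scenario$baseline_nbr, nr, nc) + noise[[1]]
      nbr_jja <- scenario$baseline_nbr - static - De + noise[[2]]
      nbr_son <- scenario$baseline_nbr - 2 * static - De - Dl + noise[[3]]
      composites <- c(composites, list(
        nbr_to_composite(nbr_mam, y, "MAM"),
        nbr_to_composite(nbr_jja, y, "JJA"),
        nbr_to_composite(nbr_son, y, "SON")
      ))
      truth <- c(truth, list(truth_mask(y, "early"), truth_mask(y, "late")))
    }
  })
  list(composites = composites, truth = truth, static = static)
}

# ---------------------------------------------------------------------------
# Tree populations

#' Tree-population scenario
#'
#' A parent-offspring (Thomas-type) cluster process for groves — Poisson
#' parents, Poisson offspring counts, isotropic Gaussian dispersal — plus an
#' independent Poisson process of singleton stems, over a survey domain
#' polygon. Each stem carries a size class drawn from a mixture over the six
#' transect-survey classes, with dimensions consistent with its class.
#'
#' @param domain survey polygon (two-column vertex matrix, map units in m),
#'   or `c(width, height)` for a rectangle with its corner at the origin.
#' @param parent_intensity_ha grove-parent intensity (ha^-1, >= 0).
#' @param offspring_mean mean offspring per parent (>= 0).
#' @param dispersal_m Gaussian offspring dispersal scale (m, > 0).
#' @param singleton_intensity_ha singleton intensity (ha^-1, >= 0).
#' @param mixture named proportions over `seedling`, `sapling`, `small`,
#'   `medium`, `large`, `very_large`; must sum to 1.
#' @param dead_prop proportion of stems >= 2.2 m tall that are dead (dead
#'   seedlings and saplings are never recorded in the field and are not
#'   generated).
#' @param seed integer seed.
#' @return object of class `population_scenario`.
#' @export
population_scenario <- function(domain = c(1000, 50), parent_intensity_ha = 2,
                                offspring_mean = 8, dispersal_m = 10,
                                singleton_intensity_ha = 3,
                                mixture = c(seedling = 0.25, sapling = 0.2, small = 0.15,
                                            medium = 0.15, large = 0.15, very_large = 0.1),
                                dead_prop = 0.1, seed = 1) {
  if (length(domain) == 2L && is.null(dim(domain))) {
    domain <- cbind(x = c(0, domain[1], domain[1], 0), y = c(0, 0, domain[2], domain[2]))
  }
  domain <- as.matrix(domain)
  if (nrow(domain) < 3L) stop("domain polygon needs at least 3 vertices", call. = FALSE)
  if (abs(pracma::polyarea(domain[, 1], domain[, 2])) <= 0) {
    stop("domain polygon has zero area", call. = FALSE)
  }
  if (parent_intensity_ha < 0 || singleton_intensity_ha < 0 || offspring_mean < 0) {
    stop("intensities and offspring mean must be nonnegative", call. = FALSE)
  }
  mixture <- mixture[SIZE_CLASSES_A]
  if (anyNA(mixture) || abs(sum(mixture) - 1) > 1e-8) {
    stop("`mixture` must cover the six size classes and sum to 1", call. = FALSE)
  }
  if (dead_prop < 0 || dead_prop > 1) stop("`dead_prop` must lie in [0, 1]", call. = FALSE)
  structure(
    list(domain = domain, parent_intensity_ha = parent_intensity_ha,
         offspring_mean = offspring_mean, dispersal_m = dispersal_m,
         singleton_intensity_ha = singleton_intensity_ha, mixture = mixture,
         dead_prop = dead_prop, seed = as.integer(seed)),
    class = "population_scenario"
  )
}

# Class-consistent dimensions (scheme A). Heights in m, diameters in cm.
draw_dimensions <- function(cls) {
  n <- length(cls)
  h <- rep(NA_real_, n); d <- rep(NA_real_, n)
  sel <- cls == "seedling";   h[sel] <- stats::runif(sum(sel), 0.01, 0.099)
  sel <- cls == "sapling";    h[sel] <- stats::runif(sum(sel), 0.1, 2.19)
  sel <- cls == "small";      h[sel] <- stats::runif(sum(sel), 2.2, 8);  d[sel] <- stats::runif(sum(sel), 1, 9.99)
  sel <- cls == "medium";     h[sel] <- stats::runif(sum(sel), 5, 12);   d[sel] <- stats::runif(sum(sel), 10, 19.99)
  sel <- cls == "large";      h[sel] <- stats::runif(sum(sel), 8, 16);   d[sel] <- stats::runif(sum(sel), 20, 29.99)
  sel <- cls == "very_large"; h[sel] <- stats::runif(sum(sel), 10, 20);  d[sel] <- stats::runif(sum(sel), 30, 60)
  list(height_m = h, d1_0_cm = d)
}

#' Generate a clustered stem map
#'
#' Simulates the cluster-plus-singleton point pattern of a
#' [population_scenario()] and attaches size classes, class-consistent
#' dimensions, live/dead status, 100-m segment ids (from the x coordinate)
#' and distance from the transect midline (from the y coordinate).
#'
#' @param scenario a [population_scenario()].
#' @return data frame: `tag`, `x`, `y`, `segment`, `dist_m`, `size_class`,
#'   `height_m`, `d1_0_cm`, `status`, `origin` (`"grove"`/`"singleton"`).
#' @export
gen_tree_population <- function(scenario) {
  stopifnot(inherits(scenario, "population_scenario"))
  dom <- scenario$domain
  bx <- range(dom[, 1]); by <- range(dom[, 2])
  bbox_ha <- diff(bx) * diff(by) / 1e4
  in_dom <- function(x, y) pracma::inpolygon(x, y, dom[, 1], dom[, 2], boundary = TRUE)
  with_seed(split_seed(scenario$seed, 3L), {
    # grove process: Poisson parents in the bounding box, Gaussian offspring
    n_par <- stats::rpois(1, scenario$parent_intensity_ha * bbox_ha)
    px <- stats::runif(n_par, bx[1], bx[2]); py <- stats::runif(n_par, by[1], by[2])
    keep <- in_dom(px, py); px <- px[keep]; py <- py[keep]
    ox <- numeric(0); oy <- numeric(0)
    if (length(px) > 0 && scenario$offspring_mean > 0) {
      n_off <- stats::rpois(length(px), scenario$offspring_mean)
      ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, scenario$dispersal_m)
      oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, scenario$dispersal_m)
      keep <- in_dom(ox, oy); ox <- ox[keep]; oy <- oy[keep]
    }
    # independent singletons
    n_s <- stats::rpois(1, scenario$singleton_intensity_ha * bbox_ha)
    sx <- stats::runif(n_s, bx[1], bx[2]); sy <- stats::runif(n_s, by[1], by[2])
    keep <- in_dom(sx, sy); sx <- sx[keep]; sy <- sy[keep]
    x <- c(ox, sx); y <- c(oy, sy)
    origin <- c(rep("grove", length(ox)), rep("singleton", length(sx)))
    n <- length(x)
    cls <- sample(SIZE_CLASSES_A, n, replace = TRUE, prob = scenario$mixture)
    dims <- draw_dimensions(cls)
    is_stem <- cls %in% c("small", "medium", "large", "very_large")
    status <- rep("live", n)
    status[is_stem] <- ifelse(stats::runif(sum(is_stem)) < scenario$dead_prop, "dead", "live")
    mid_y <- mean(by)
    data.frame(
      tag = if (n > 0) sprintf("T%04d", seq_len(n)) else character(0),
      x = x, y = y,
      segment = floor(x / 100) + 1L,
      dist_m = y - mid_y,
      size_class = cls,
      height_m = dims$height_m, d1_0_cm = dims$d1_0_cm,
      status = status, origin = origin
    )
  })
}

# ---------------------------------------------------------------------------
# Survival histories

#' Survival-history scenario
#'
#' Per-size-class annual survival probabilities (the generative truth the
#' annualized-survival estimator must recover), census years, and initial
#' cohort sizes.
#'
#' @param survival named vector of annual survival probabilities in \[0, 1\]
#'   over the scheme-B classes.
#' @param census_years strictly increasing census years; the first is the
#'   tagging census.
#' @param initial_counts named vector of tagged individuals per class.
#' @param seed integer seed.
#' @return object of class `survival_scenario`.
#' @export
survival_scenario <- function(survival = c(juvenile = 0.70, very_small = 0.951,
                                           small = 0.97, medium = 0.973,
                                           large = 0.988, very_large = 0.959),
                              census_years = c(2006, 2007, 2008, 2009, 2016, 2019),
                              initial_counts = c(juvenile = 385, very_small = 52,
                                                 small = 94, medium = 166,
                                                 large = 175, very_large = 220),
                              seed = 1) {
  if (any(survival < 0 | survival > 1)) stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(diff(census_years) <= 0)) stop("census years must be strictly increasing", call. = FALSE)
  if (!all(names(initial_counts) %in% names(survival))) {
    stop("every cohort class needs a survival probability", call. = FALSE)
  }
  structure(
    list(survival = survival, census_years = as.integer(census_years),
         initial_counts = initial_counts, seed = as.integer(seed)),
    class = "survival_scenario"
  )
}

# Class-consistent scheme-B start sizes.
draw_dimensions_b <- function(cls) {
  n <- length(cls)
  h <- rep(NA_real_, n); d <- rep(NA_real_, n)
  sel <- cls == "juvenile";   h[sel] <- stats::runif(sum(sel), 0.1, 1.49)
  sel <- cls == "very_small"; h[sel] <- stats::runif(sum(sel), 1.5, 4);  d[sel] <- stats::runif(sum(sel), 1, 4.99)
  sel <- cls == "small";      h[sel] <- stats::runif(sum(sel), 2.5, 8);  d[sel] <- stats::runif(sum(sel), 5, 9.99)
  sel <- cls == "medium";     h[sel] <- stats::runif(sum(sel), 5, 12);   d[sel] <- stats::runif(sum(sel), 10, 19.99)
  sel <- cls == "large";      h[sel] <- stats::runif(sum(sel), 8, 16);   d[sel] <- stats::runif(sum(sel), 20, 29.99)
  sel <- cls == "very_large"; h[sel] <- stats::runif(sum(sel), 10, 20);  d[sel] <- stats::runif(sum(sel), 30, 60)
  list(height_m = h, d1_0_cm = d)
}

#' Generate longitudinal survival histories
#'
#' Each tagged individual follows an annual Bernoulli survival chain with its
#' class's probability; once dead it stays dead. Status is recorded at each
#' census year as `"live"`/`"dead"`.
#'
#' @param scenario a [survival_scenario()].
#' @return data frame with one row per tag: `tag`, `size_class`, `height_m`,
#'   `d1_0_cm`, and a `status_<year>` column per census year.
#' @export
gen_survival_histories <- function(scenario) {
  stopifnot(inherits(scenario, "survival_scenario"))
  classes <- names(scenario$initial_counts)
  cls <- rep(classes, times = scenario$initial_counts)
  n <- length(cls)
  yrs <- scenario$census_years
  with_seed(split_seed(scenario$seed, 4L), {
    dims <- draw_dimensions_b(cls)
    out <- data.frame(tag = sprintf("S%04d", seq_len(n)), size_class = cls,
                      height_m = dims$height_m, d1_0_cm = dims$d1_0_cm)
    p <- scenario$survival[cls]
    alive <- rep(TRUE, n)
    out[[paste0("status_", yrs[1])]] <- "live"
    for (i in seq_along(yrs)[-1]) {
      gap <- yrs[i] - yrs[i - 1]
      for (g in seq_len(gap)) {
        alive <- alive & (stats::runif(n) < p)
      }
      out[[paste0("status_", yrs[i])]] <- ifelse(alive, "live", "dead")
    }
    out
  })
}

# ---------------------------------------------------------------------------
# Ring-width series

#' Ring-series scenario
#'
#' Per-tree establishment years, sampling heights, sample types and pith
#' offsets (missing inner rings), plus a common series end year and ring-width
#' distribution. The generated series are the exact inverse of the
#' establishment-dating pipeline: the innermost dated ring year is
#' `establishment + round(age_at_height(sample height)) + pith offset`.
#'
#' @param trees data frame with columns `series`, `establishment_year`,
#'   `sample_height_cm`, `sample_type` (`"core"`/`"section"`), `pith_offset`
#'   (integer >= 0), `segment`.
#' @param end_year last dated ring year shared by all series.
#' @param mean_width_mm median ring width (mm, > 0).
#' @param width_sdlog lognormal ring-width variability (sdlog).
#' @param seed integer seed.
#' @return object of class `ring_scenario`.
#' @export
ring_scenario <- function(trees, end_year = 2014, mean_width_mm = 1.2,
                          width_sdlog = 0.3, seed = 1) {
  needed <- c("series", "establishment_year", "sample_height_cm", "sample_type", "pith_offset")
  if (!all(needed %in% names(trees))) {
    stop(sprintf("`trees` needs columns %s", paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (is.null(trees$segment)) trees$segment <- 1L
  if (any(trees$pith_offset < 0)) stop("pith offsets must be nonnegative", call. = FALSE)
  if (any(!trees$sample_type %in% c("core", "section"))) {
    stop("sample type must be 'core' or 'section'", call. = FALSE)
  }
  if (any(end_year < trees$establishment_year)) {
    stop("series end year precedes an establishment year", call. = FALSE)
  }
  if (mean_width_mm <= 0 || width_sdlog < 0) stop("invalid ring-width parameters", call. = FALSE)
  structure(
    list(trees = trees, end_year = as.integer(end_year),
         mean_width_mm = mean_width_mm, width_sdlog = width_sdlog,
         seed = as.integer(seed)),
    class = "ring_scenario"
  )
}

#' Generate dated ring-width series with metadata
#'
#' Each series spans from its innermost dated ring year (establishment year
#' plus the rounded years-to-sample-height plus the pith offset) to the
#' common end year, with positive lognormal ring widths. The metadata
#' sidecar carries the sampling height, type, true pith offset, and a
#' distance-to-pith consistent with the five-innermost-rings pith estimator,
#' so the full dating pipeline recovers the establishment years exactly.
#'
#' @param scenario a [ring_scenario()].
#' @return list with `rwl` (ring-width data frame, years as row names) and
#'   `meta` (data frame: `series`, `segment`, `sample_height_cm`,
#'   `sample_type`, `pith_offset`, `distance_to_pith_mm`).
#' @export
gen_ring_series <- function(scenario) {
  stopifnot(inherits(scenario, "ring_scenario"))
  tr <- scenario$trees
  inner <- tr$establishment_year + round(age_at_height(tr$sample_height_cm)) +
    tr$pith_offset
  n_rings <- scenario$end_year - inner + 1L
  if (any(n_rings < 1)) {
    stop("implied ring count is nonpositive; corrections push a series past its end year",
         call. = FALSE)
  }
  with_seed(split_seed(scenario$seed, 5L), {
    all_years <- seq(min(inner), scenario$end_year)
    rwl <- data.frame(row.names = as.character(all_years))
    dist_mm <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      w <- stats::rlnorm(n_rings[i], meanlog = log(scenario$mean_width_mm),
                         sdlog = scenario$width_sdlog)
      col <- rep(NA_real_, length(all_years))
      col[match(seq(inner[i], scenario$end_year), all_years)] <- w
      rwl[[tr$series[i]]] <- col
      inner_w <- w[seq_len(min(5L, length(w)))]
      dist_mm[i] <- tr$pith_offset[i] * mean(inner_w)
    }
    meta <- data.frame(series = tr$series, segment = tr$segment,
                       sample_height_cm = tr$sample_height_cm,
                       sample_type = tr$sample_type,
                       pith_offset = as.integer(tr$pith_offset),
                       distance_to_pith_mm = dist_mm)
    list(rwl = rwl, meta = meta)
  })
}

# ---------------------------------------------------------------------------
# Fuel samples

#' Fuel-sampling scenario
#'
#' Per-region dry-load distributions (lognormal: the stated median with a
#' region-specific upper-tail spread), quadrat geometry and a moisture
#' distribution. Fresh weights are back-computed as `dry / (1 - moisture)`,
#' so the dry-weight conversion inverts the generator exactly.
#'
#' @param regions data frame with columns `region`, `median_gm2` (>= 0),
#'   `sdlog` (upper-tail scale, >= 0), `n_units` (segments or plots).
#' @param quadrats_per_unit quadrats sampled per segment/plot (default 8).
#' @param quadrat_area_m2 quadrat area (default 0.25).
#' @param moisture_range uniform moisture-fraction range within \[0, 1).
#' @param seed integer seed.
#' @return object of class `fuel_scenario`.
#' @export
fuel_scenario <- function(regions = data.frame(region = c("dukaladjarranj", "kakadu"),
                                               median_gm2 = c(71, 112),
                                               sdlog = c(0.5, 0.8),
                                               n_units = c(20, 32)),
                          quadrats_per_unit = 8, quadrat_area_m2 = 0.25,
                          moisture_range = c(0.2, 0.5), seed = 1) {
  if (any(regions$median_gm2 < 0) || any(regions$sdlog < 0)) {
    stop("region load parameters must be nonnegative", call. = FALSE)
  }
  if (any(moisture_range < 0) || any(moisture_range >= 1)) {
    stop("moisture fractions must lie in [0, 1)", call. = FALSE)
  }
  if (quadrat_area_m2 <= 0) stop("quadrat area must be positive", call. = FALSE)
  structure(
    list(regions = regions, quadrats_per_unit = quadrats_per_unit,
         quadrat_area_m2 = quadrat_area_m2, moisture_range = moisture_range,
         seed = as.integer(seed)),
    class = "fuel_scenario"
  )
}

#' Generate a fuel-quadrat table
#'
#' @param scenario a [fuel_scenario()].
#' @return data frame: `region`, `unit`, `quadrat`, `area_m2`, `fresh_g`,
#'   `moisture`, `dry_gm2` (the generative truth; equals
#'   [dry_load()] of the other columns).
#' @export
gen_fuel_samples <- function(scenario) {
  stopifnot(inherits(scenario, "fuel_scenario"))
  with_seed(split_seed(scenario$seed, 6L), {
    rows <- lapply(seq_len(nrow(scenario$regions)), function(i) {
      rg <- scenario$regions[i, ]
      n <- rg$n_units * scenario$quadrats_per_unit
      dry_gm2 <- stats::rlnorm(n, meanlog = log(rg$median_gm2), sdlog = rg$sdlog)
      moisture <- stats::runif(n, scenario$moisture_range[1], scenario$moisture_range[2])
      data.frame(
        region = rg$region,
        unit = rep(seq_len(rg$n_units), each = scenario$quadrats_per_unit),
        quadrat = rep(seq_len(scenario$quadrats_per_unit), times = rg$n_units),
        area_m2 = scenario$quadrat_area_m2,
        fresh_g = dry_gm2 * scenario$quadrat_area_m2 / (1 - moisture),
        moisture = moisture,
        dry_gm2 = dry_gm2
      )
    })
    do.call(rbind, rows)
  })
}
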