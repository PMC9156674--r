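# Callitris demography: size-class schemes, transect densities, stand-status
# classification, and longitudinal annualized survival.

# Scheme A (transect surveys): seedling/sapling by height, trees (>= 2.2 m
# tall) by diameter at 1 m. Scheme B (longitudinal study): juvenile < 1.5 m,
# then diameter classes with a very-small (< 5 cm) class.
SIZE_CLASSES_A <- c("seedling", "sapling", "small", "medium", "large", "very_large")
SIZE_CLASSES_B <- c("juvenile", "very_small", "small", "medium", "large", "very_large")

#' Assign a size class
#'
#' Two schemes are used in the field protocols. Scheme `"A"` (transect
#' surveys): seedling (< 0.1 m tall), sapling (0.1-2.2 m tall), then trees by
#' diameter at 1 m (D1.0): small (< 10 cm), medium (10-20), large (20-30),
#' very large (>= 30). Scheme `"B"` (longitudinal study): juvenile (< 1.5 m
#' tall), very small (< 5 cm D1.0), small (5-10), medium (10-20), large
#' (20-30), very large (>= 30). All diameter intervals are lower-inclusive,
#' upper-exclusive (a 10 cm stem is medium).
#'
#' @param height_m stem height (m); may be `NA` for stems above the height
#'   threshold when `d1_0_cm` is given.
#' @param d1_0_cm diameter at 1.0 m (cm); required for stems at or above the
#'   scheme's height threshold (2.2 m for A, 1.5 m for B).
#' @param scheme `"A"` or `"B"`.
#' @return character vector of class labels.
#' @export
assign_size_class <- function(height_m, d1_0_cm = NA_real_, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  n <- max(length(height_m), length(d1_0_cm))
  height_m <- rep_len(height_m, n); d1_0_cm <- rep_len(d1_0_cm, n)
  thr <- if (scheme == "A") 2.2 else 1.5
  vapply(seq_len(n), function(i) {
    h <- height_m[i]; d <- d1_0_cm[i]
    is_tree <- (!is.na(h) && h >= thr) || (is.na(h) && !is.na(d))
    if (!is_tree) {
      if (is.na(h)) stop("height required when D1.0 is missing", call. = FALSE)
      if (scheme == "A") {
        if (h < 0.1) return("seedling") else return("sapling")
      }
      return("juvenile")
    }
    if (is.na(d)) {
      stop(sprintf("stem >= %.1f m tall with missing D1.0", thr), call. = FALSE)
    }
    if (d <= 0) stop("D1.0 must be positive", call. = FALSE)
    if (scheme == "B" && d < 5) return("very_small")
    if (d < 10) return("small")
    if (d < 20) return("medium")
    if (d < 30) return("large")
    "very_large"
  }, character(1))
}

#' Per-class stem densities by transect segment
#'
#' Converts per-segment stem counts into densities (stems per hectare) using
#' the class-specific sampled band: seedlings are recorded only within a
#' narrow band either side of the transect midline, saplings and trees across
#' the full transect half-width. Mean and standard error are computed across
#' segments (the replicated sampling unit).
#'
#' @param stems data frame with columns `segment`, `size_class`, `status`
#'   (`"live"`/`"dead"`), and `dist_m` (absolute distance from the midline).
#' @param segments vector of all segment ids surveyed (zero-count segments
#'   must enter the mean).
#' @param segment_length_m segment length (default 100).
#' @param half_width_m sampled half-width for saplings and trees (default 25).
#' @param seedling_half_width_m sampled half-width for seedlings (default 2).
#' @param scheme size-class scheme, `"A"` (default) or `"B"`.
#' @return data frame: `size_class`, `status`, `mean_ha`, `se_ha`,
#'   `n_segments`.
#' @export
segment_densities <- function(stems, segments = unique(stems$segment),
                              segment_length_m = 100, half_width_m = 25,
                              seedling_half_width_m = 2, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  classes <- if (scheme == "A") SIZE_CLASSES_A else SIZE_CLASSES_B
  if (segment_length_m <= 0 || half_width_m <= 0 || seedling_half_width_m <= 0) {
    stop("segment dimensions must be positive", call. = FALSE)
  }
  segments <- sort(unique(segments))
  band_for <- function(cls) if (cls == "seedling") seedling_half_width_m else half_width_m
  combos <- expand.grid(size_class = classes, status = c("live", "dead"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cls <- combos$size_class[i]; st <- combos$status[i]
    bw <- band_for(cls)
    area_ha <- segment_length_m * 2 * bw / 1e4
    dens <- vapply(segments, function(sg) {
      sel <- stems$segment == sg & stems$size_class == cls & stems$status == st &
        abs(stems$dist_m) <= bw
      sum(sel) / area_ha
    }, numeric(1))
    data.frame(size_class = cls, status = st,
               mean_ha = mean(dens),
               se_ha = stats::sd(dens) / sqrt(length(dens)),
               n_segments = length(segments))
  })
  out <- do.call(rbind, rows)
  out$size_class <- factor(out$size_class, levels = classes)
  out[order(out$status, out$size_class), ]
}

#' Annualized survival
#'
#' The constant per-year survival percentage implied by survival over an
#' interval: `(n2 / n1)^(1 / y) * 100`, reported to one decimal place.
#' Individuals missing at the final census are assumed dead and so excluded
#' from `n2` by the caller.
#'
#' @param n1 live individuals at the start of the interval (> 0).
#' @param n2 live individuals at the end (0 <= n2 <= n1).
#' @param y interval length in years (> 0).
#' @return annualized survival (percent, one decimal).
#' @export
annualized_survival <- function(n1, n2, y) {
  if (any(n1 <= 0)) stop("`n1` must be positive", call. = FALSE)
  if (any(n2 < 0) || any(n2 > n1)) stop("`n2` must satisfy 0 <= n2 <= n1", call. = FALSE)
  if (any(y <= 0)) stop("`y` must be positive", call. = FALSE)
  round((n2 / n1)^(1 / y) * 100, 1)
}

#' Survival by size class over a census interval
#'
#' Freezes each individual's size class at the start census, then reports per
#' class the number tagged, the raw percentage surviving to the end census,
#' and the annualized survival percentage. Individuals with a missing final
#' status are counted dead.
#'
#' @param census data frame with one row per tagged individual: columns
#'   `height_m`, `d1_0_cm` (start-census sizes) and `status_<year>` columns
#'   coded `"live"`/`"dead"` (`NA` = missing, treated as dead).
#' @param start_year,end_year census years bounding the interval; both
#'   `status_` columns must exist and `end_year > start_year`.
#' @param scheme size-class scheme (default `"B"`, the longitudinal scheme).
#' @return data frame: `size_class`, `n_start`, `n_end`, `raw_percent`,
#'   `annualized_percent` (NA when no individuals started in a class).
#' @export
survival_by_class <- function(census, start_year, end_year, scheme = "B") {
  if (end_year <= start_year) stop("`end_year` must be after `start_year`", call. = FALSE)
  s0 <- paste0("status_", start_year); s1 <- paste0("status_", end_year)
  if (!all(c(s0, s1) %in% names(census))) {
    stop("census must contain status columns for both census years", call. = FALSE)
  }
  classes <- if (scheme == "A") SIZE_CLASSES_A else SIZE_CLASSES_B
  alive0 <- !is.na(census[[s0]]) & census[[s0]] == "live"
  census <- census[alive0, , drop = FALSE]
  cls <- assign_size_class(census$height_m, census$d1_0_cm, scheme = scheme)
  alive1 <- !is.na(census[[s1]]) & census[[s1]] == "live"
  y <- end_year - start_year
  rows <- lapply(classes, function(cl) {
    sel <- cls == cl
    n1 <- sum(sel); n2 <- sum(sel & alive1)
    data.frame(size_class = cl, n_start = n1, n_end = n2,
               raw_percent = if (n1 > 0) round(100 * n2 / n1, 1) else NA_real_,
               annualized_percent = if (n1 > 0) annualized_survival(n1, n2, y) else NA_real_)
  })
  do.call(rbind, rows)
}

# Default numeric thresholds operationalizing the qualitative stand-status
# categories; every threshold is caller-adjustable and recorded in the result.
DEFAULT_STATUS_RULES <- list(
  singleton_max_stems = 2L,   # 1-2 stems qualify as singleton
  singleton_max_juveniles = 2L, # singletons have < 3 seedlings+saplings
  healthy_min_live = 3L,      # healthy needs >= 3 live stems
  healthy_min_classes = 3L,   # ... spanning >= 3 size classes
  recovering_min_juveniles = 3L # recovering needs >= 3 seedlings+saplings
)

#' Classify the stand status of a transect segment
#'
#' Applies an explicit numeric rule to per-segment counts, operationalizing
#' the qualitative field categories: `new` (seedlings and/or saplings only),
#' `singleton` (one or two stems, majority live, few juveniles), `healthy`
#' (several live stems spanning several size classes, live outnumbering
#' dead), `recovering` (dead at least matching live among stems but multiple
#' seedlings/saplings present), `degraded` (otherwise), and `absent` (no
#' stems or regeneration at all). "Stems" are individuals >= 2.2 m tall;
#' "juveniles" here are seedlings plus saplings.
#'
#' @param live_by_class named integer vector of live counts over the six
#'   scheme-A classes (`seedling`, `sapling`, `small`, `medium`, `large`,
#'   `very_large`).
#' @param dead_stems count of dead stems (>= 2.2 m) in the segment.
#' @param rules list of numeric thresholds; see `DEFAULT_STATUS_RULES` in the
#'   package source. Partial lists are merged over the defaults.
#' @return character status, with the applied thresholds attached as
#'   attribute `rules`.
#' @export
classify_stand_status <- function(live_by_class, dead_stems = 0L,
                                  rules = list()) {
  rules <- utils::modifyList(DEFAULT_STATUS_RULES, rules)
  lv <- setNames(rep(0L, length(SIZE_CLASSES_A)), SIZE_CLASSES_A)
  lv[names(live_by_class)] <- as.integer(live_by_class)
  juv <- sum(lv[c("seedling", "sapling")])
  stem_classes <- c("small", "medium", "large", "very_large")
  live_stems <- sum(lv[stem_classes])
  total_stems <- live_stems + dead_stems
  classes_present <- sum(lv[stem_classes] > 0)
  status <- if (juv == 0 && total_stems == 0) {
    "absent"
  } else if (total_stems == 0) {
    "new"
  } else if (total_stems <= rules$singleton_max_stems &&
             live_stems > dead_stems &&
             juv <= rules$singleton_max_juveniles) {
    "singleton"
  } else if (live_stems >= rules$healthy_min_live &&
             classes_present >= rules$healthy_min_classes &&
             live_stems > dead_stems) {
    "healthy"
  } else if (dead_stems >= live_stems && juv >= rules$recovering_min_juveniles) {
    "recovering"
  } else {
    "degraded"
  }
  attr(status, "rules") <- rules
  status
}

#' Indicative age from diameter
#'
#' Converts a diameter at 1 m into an indicative age by assuming a constant
#' diameter growth rate (default 2.5 mm/yr) once the stem has reached 1 m
#' height, plus the seedling time to reach 1 m from the height-age curve
#' ([age_at_height()] at 100 cm). Rounding the result to the nearest decade
#' reproduces the survey age-class boundaries (10 cm -> 60 y, 30 cm -> 140 y).
#'
#' @param d1_0_cm diameter at 1.0 m (cm, >= 0).
#' @param growth_rate_mm_yr diameter growth rate (mm/yr, default 2.5).
#' @return list with `age_yr` (unrounded) and `age_decade` (rounded to the
#'   nearest decade).
#' @export
indicative_age <- function(d1_0_cm, growth_rate_mm_yr = 2.5) {
  if (growth_rate_mm_yr <= 0) stop("growth rate must be positive", call. = FALSE)
  if (any(d1_0_cm < 0)) stop("D1.0 must be nonnegative", call. = FALSE)
  age <- (d1_0_cm * 10) / growth_rate_mm_yr + age_at_height(100)
  list(age_yr = age, age_decade = round(age / 10) * 10)
}
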