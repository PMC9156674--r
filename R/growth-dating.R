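# Juvenile height-growth regression, the height-age curve, pith-offset
# estimation, establishment-year reconstruction, and decadal binning.

#' Fit the height-increment regression
#'
#' Ordinary least squares of annual height increment on initial height, the
#' juvenile growth model underlying the height-age curve. Model support is
#' summarized as the AIC improvement over the intercept-only model
#' (`delta_aic = AIC(null) - AIC(model)`, Gaussian likelihood; positive favors
#' the height effect).
#'
#' @param initial_height_cm initial heights (cm, > 0).
#' @param increment_cm annual height increments (cm/yr), same length.
#' @return list: `intercept`, `slope`, `r_squared`, `delta_aic`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_height_increment_model <- function(initial_height_cm, increment_cm) {
  if (length(initial_height_cm) != length(increment_cm)) {
    stop("input vectors must have equal length", call. = FALSE)
  }
  if (length(initial_height_cm) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(initial_height_cm <= 0)) stop("initial heights must be positive", call. = FALSE)
  if (stats::sd(initial_height_cm) == 0) {
    stop("initial heights are constant; the slope is not identifiable", call. = FALSE)
  }
  fit <- stats::lm(increment_cm ~ initial_height_cm)
  null <- stats::lm(increment_cm ~ 1)
  tss <- sum((increment_cm - mean(increment_cm))^2)
  # computed directly so an exact or constant fit stays numerically clean
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  if (r2 < 1e-12) r2 <- max(0, r2)
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r_squared = r2,
    delta_aic = stats::AIC(null) - stats::AIC(fit),
    n = length(increment_cm),
    fit = fit
  )
}

#' Height-age curve
#'
#' Years for a juvenile to reach a given height:
#' `age = -2.1 + 2.024 * sqrt(height)` with height in cm, clamped below at 0
#' (heights under the curve's root, about 1.08 cm, map to age 0). The value is
#' returned unrounded; rounding to whole years happens once, when composing
#' establishment years.
#'
#' @param height_cm height (cm, >= 0); vectorized.
#' @return age in years (unrounded, >= 0).
#' @export
age_at_height <- function(height_cm) {
  if (any(height_cm < 0)) stop("height must be nonnegative", call. = FALSE)
  pmax(0, -2.1 + 2.024 * sqrt(height_cm))
}

#' Estimate missing inner rings (pith offset)
#'
#' For samples that missed the stem center, the number of unmeasured inner
#' rings is estimated as the distance to the pith divided by the mean width of
#' the five innermost measured rings, rounded to the nearest ring. With fewer
#' than five rings available, all available rings are used and a warning is
#' issued (degraded mode).
#'
#' @param inner_widths_mm ring widths (mm), innermost first.
#' @param distance_to_pith_mm radial distance from the innermost measured ring
#'   to the estimated pith (mm, >= 0).
#' @return integer count of missing rings (>= 0).
#' @export
pith_offset <- function(inner_widths_mm, distance_to_pith_mm) {
  if (distance_to_pith_mm < 0) stop("distance to pith must be nonnegative", call. = FALSE)
  if (length(inner_widths_mm) == 0L || any(inner_widths_mm <= 0)) {
    stop("ring widths must be positive", call. = FALSE)
  }
  if (length(inner_widths_mm) < 5L) {
    warning(sprintf("only %d inner rings available; pith estimator uses all of them",
                    length(inner_widths_mm)))
    w <- inner_widths_mm
  } else {
    w <- inner_widths_mm[1:5]
  }
  max(0L, as.integer(round(distance_to_pith_mm / mean(w))))
}

#' Establishment year of a dated sample
#'
#' Composes the dating corrections: the tree established `pith_offset` rings
#' plus the (rounded) years-to-sample-height before its innermost dated ring,
#' i.e. `establishment = innermost ring year - pith offset -
#' round(age_at_height(sample height))`.
#'
#' @param innermost_year calendar year of the innermost dated ring.
#' @param sample_height_cm height above ground at which the core or section
#'   was taken (cm).
#' @param pith_offset estimated missing inner rings (integer >= 0).
#' @param series_end_year optional; if given, an establishment year after the
#'   series end is rejected as internally inconsistent.
#' @return establishment calendar year (integer); vectorized over all
#'   arguments.
#' @export
establishment_year <- function(innermost_year, sample_height_cm, pith_offset = 0L,
                               series_end_year = NULL) {
  if (any(pith_offset < 0)) stop("pith offset must be nonnegative", call. = FALSE)
  est <- as.integer(innermost_year) - as.integer(pith_offset) -
    as.integer(round(age_at_height(sample_height_cm)))
  if (!is.null(series_end_year) && any(est > series_end_year)) {
    stop("establishment year falls after the series end; inputs are inconsistent",
         call. = FALSE)
  }
  est
}

#' Establishment table from ring series and sample metadata
#'
#' Applies the full dating correction to every series of a ring-width table:
#' the pith offset is taken from `meta$pith_offset` when present, otherwise
#' estimated from `meta$distance_to_pith_mm` with [pith_offset()].
#'
#' @param rwl ring-width data frame as returned by [read_rwl()] (years as row
#'   names, one column per series).
#' @param meta data frame with columns `series`, `sample_height_cm`,
#'   `segment`, and either `pith_offset` or `distance_to_pith_mm`.
#' @return data frame: `series`, `segment`, `innermost_year`, `pith_offset`,
#'   `establishment_year`.
#' @export
establishment_table <- function(rwl, meta) {
  years <- as.integer(rownames(rwl))
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    s <- meta$series[i]
    if (!s %in% names(rwl)) stop(sprintf("series '%s' not found in ring-width table", s), call. = FALSE)
    w <- rwl[[s]]
    present <- !is.na(w)
    inner <- min(years[present])
    po <- if (!is.null(meta$pith_offset) && !is.na(meta$pith_offset[i])) {
      as.integer(meta$pith_offset[i])
    } else {
      pith_offset(w[present][order(years[present])], meta$distance_to_pith_mm[i])
    }
    est <- establishment_year(inner, meta$sample_height_cm[i], po,
                              series_end_year = max(years[present]))
    data.frame(series = s, segment = meta$segment[i], innermost_year = inner,
               pith_offset = po, establishment_year = est)
  })
  do.call(rbind, rows)
}

#' Bin establishment years into calendar decades by segment
#'
#' Decades are closed-open calendar decades (\[1750, 1760), \[1760, 1770),
#' ...). Each segment also carries the limit of its dendrochronological
#' record: the earliest innermost dated ring year among its samples, before
#' which establishment counts are necessarily incomplete.
#'
#' @param establishments data frame from [establishment_table()] (columns
#'   `segment`, `establishment_year`, `innermost_year`), or vectors via the
#'   `segment`/`innermost_year` arguments.
#' @param segment,innermost_year optional vectors if `establishments` is a
#'   plain vector of years.
#' @param segments optional vector of all segment ids (empty segments keep a
#'   zero row).
#' @return list with `counts` (segments x decades integer matrix) and
#'   `record_limit` (named vector, per-segment earliest innermost ring year).
#' @export
bin_establishment <- function(establishments, segment = NULL, innermost_year = NULL,
                              segments = NULL) {
  if (is.data.frame(establishments)) {
    est <- establishments$establishment_year
    segment <- establishments$segment
    innermost_year <- establishments$innermost_year
  } else {
    est <- establishments
  }
  if (any(est < 1000)) stop("establishment year before 1000 CE; likely a parse artifact", call. = FALSE)
  decade <- floor(est / 10) * 10
  segments <- if (is.null(segments)) sort(unique(segment)) else sort(unique(segments))
  dec_levels <- seq(min(decade), max(decade), by = 10)
  counts <- matrix(0L, nrow = length(segments), ncol = length(dec_levels),
                   dimnames = list(as.character(segments), as.character(dec_levels)))
  tab <- table(factor(segment, levels = segments), factor(decade, levels = dec_levels))
  counts[] <- as.integer(tab)
  limit <- if (!is.null(innermost_year)) {
    vapply(segments, function(sg) {
      sel <- segment == sg
      if (any(sel)) min(innermost_year[sel]) else NA_integer_
    }, numeric(1))
  } else {
    setNames(rep(NA_real_, length(segments)), segments)
  }
  names(limit) <- as.character(segments)
  list(counts = counts, record_limit = limit)
}
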