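# Seasonal reflectance composites and the dNBR burn-mapping arithmetic.

SEASON_WINDOWS <- c("MAM", "JJA", "SON")

# Composite window pairs defining the two dry-season burn-detection intervals:
# early fires show between the March-May and June-August composites, late
# fires between June-August and September-November.
SEASON_PAIRS <- list(early = c("MAM", "JJA"), late = c("JJA", "SON"))

#' Seasonal surface-reflectance composite
#'
#' One season-window x year snapshot of NIR and SWIR surface reflectance on a
#' regular grid, the unit the burn-mapping pipeline consumes.
#'
#' @param year calendar year.
#' @param season_window one of `"MAM"`, `"JJA"`, `"SON"`.
#' @param nir,swir reflectance matrices of identical dimension; `NA` marks
#'   nodata cells.
#' @param cell_size cell edge length (m).
#' @param xll,yll map coordinates of the grid's lower-left corner.
#' @param crs free-form coordinate reference system identifier.
#' @return object of class `seasonal_composite`.
#' @export
seasonal_composite <- function(year, season_window, nir, swir,
                               cell_size = 30, xll = 0, yll = 0, crs = NA_character_) {
  season_window <- match.arg(season_window, SEASON_WINDOWS)
  nir <- as.matrix(nir); swir <- as.matrix(swir)
  if (!identical(dim(nir), dim(swir))) {
    stop("NIR and SWIR grids must share dimensions", call. = FALSE)
  }
  if (any(!is.finite(nir) & !is.na(nir)) || any(!is.finite(swir) & !is.na(swir))) {
    stop("reflectance values must be finite or NA", call. = FALSE)
  }
  structure(
    list(year = as.integer(year), season_window = season_window,
         nir = nir, swir = swir,
         cell_size = cell_size, xll = xll, yll = yll, crs = crs),
    class = "seasonal_composite"
  )
}

#' @export
print.seasonal_composite <- function(x, ...) {
  cat(sprintf("<seasonal_composite> %d %s, %d x %d cells @ %g m\n",
              x$year, x$season_window, nrow(x$nir), ncol(x$nir), x$cell_size))
  invisible(x)
}

#' Normalized burn ratio
#'
#' NBR = (NIR - SWIR) / (NIR + SWIR) per cell. NBR drops sharply after fire,
#' so differencing NBR across a burn interval yields a positive burn signal.
#'
#' @param composite a [seasonal_composite()].
#' @return numeric matrix; `NA` where either band is nodata or the
#'   denominator is zero.
#' @export
compute_nbr <- function(composite) {
  stopifnot(inherits(composite, "seasonal_composite"))
  num <- composite$nir - composite$swir
  den <- composite$nir + composite$swir
  nbr <- num / den
  nbr[!is.na(den) & den == 0] <- NA_real_
  nbr
}

#' Seasonal differenced NBR
#'
#' dNBR = NBR(pre) - NBR(post) for a matched pre/post window pair of the same
#' year. The early dry-season interval is MAM -> JJA, the late interval
#' JJA -> SON; any other pairing is rejected.
#'
#' @param pre,post [seasonal_composite()] objects for the same year.
#' @return numeric matrix of dNBR with attributes `year` and `season`
#'   (`"early"` or `"late"`).
#' @export
seasonal_dnbr <- function(pre, post) {
  stopifnot(inherits(pre, "seasonal_composite"), inherits(post, "seasonal_composite"))
  if (pre$year != post$year) {
    stop("pre and post composites must come from the same year", call. = FALSE)
  }
  pair <- c(pre$season_window, post$season_window)
  season <- names(SEASON_PAIRS)[vapply(SEASON_PAIRS, identical, logical(1), y = pair)]
  if (length(season) != 1L) {
    stop(sprintf("window pair %s -> %s is not a valid burn-detection interval",
                 pair[1], pair[2]), call. = FALSE)
  }
  d <- compute_nbr(pre) - compute_nbr(post)
  attr(d, "year") <- pre$year
  attr(d, "season") <- season
  d
}

#' Mean-adjust a season's dNBR stack
#'
#' Subtracts the all-year mean dNBR of the season from each year's grid,
#' cellwise. This increases contrast and provably removes any static per-cell
#' landscape feature (a constant field added to every year cancels exactly).
#'
#' @param dnbr_list list of dNBR grids (from [seasonal_dnbr()]) for one season
#'   across two or more years.
#' @return list of anomaly grids, same order and attributes as the input.
#' @export
mean_adjust <- function(dnbr_list) {
  if (!is.list(dnbr_list) || length(dnbr_list) < 2L) {
    stop("mean adjustment needs dNBR grids from at least 2 years", call. = FALSE)
  }
  seasons <- vapply(dnbr_list, function(g) attr(g, "season") %||% NA_character_, character(1))
  if (length(unique(seasons)) != 1L) {
    stop("all grids in a mean-adjusted stack must be the same season", call. = FALSE)
  }
  dims <- lapply(dnbr_list, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    stop("all grids must share dimensions", call. = FALSE)
  }
  mean_grid <- Reduce(`+`, dnbr_list) / length(dnbr_list)
  lapply(dnbr_list, function(g) {
    a <- g - mean_grid
    attributes(a) <- attributes(g)
    a
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold an anomaly grid into a burn mask
#'
#' Cells with anomaly strictly greater than the cutoff are classed as burnt;
#' nodata cells are unburnt.
#'
#' @param anomaly mean-adjusted dNBR grid.
#' @param cutoff burn threshold in dNBR units (default 0.75).
#' @return logical matrix (`TRUE` = burnt) carrying the `year`/`season`
#'   attributes of the input.
#' @export
threshold_burns <- function(anomaly, cutoff = 0.75) {
  stopifnot_scalar(cutoff)
  m <- !is.na(anomaly) & anomaly > cutoff
  attr(m, "year") <- attr(anomaly, "year")
  attr(m, "season") <- attr(anomaly, "season")
  m
}
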