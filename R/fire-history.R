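# Fire-history reconstruction: burn-mask stacks, time since fire, long-unburnt
# patch mosaics, and annual regime summaries.

#' Fire-history stack
#'
#' Ordered per-(year, season) boolean burn grids restricted to an analysis
#' mask, the container all regime summaries derive from.
#'
#' @param masks list of logical burn grids, each carrying `year` and `season`
#'   attributes (as produced by [threshold_burns()]).
#' @param mask logical analysis-mask grid (`TRUE` = analysed); `NULL` means
#'   the full grid.
#' @param cell_size cell edge length (m), used for patch areas.
#' @return object of class `fire_history_stack`.
#' @export
fire_history_stack <- function(masks, mask = NULL, cell_size = 30) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  years <- vapply(masks, function(m) as.integer(attr(m, "year")), integer(1))
  seasons <- vapply(masks, function(m) as.character(attr(m, "season")), character(1))
  if (anyNA(years) || anyNA(seasons)) {
    stop("every burn grid needs `year` and `season` attributes", call. = FALSE)
  }
  if (!all(seasons %in% c("early", "late"))) {
    stop("season must be 'early' or 'late'", call. = FALSE)
  }
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    stop("all burn grids must share dimensions", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(masks[[1]]), ncol(masks[[1]]))
  }
  if (!identical(dim(mask), dims[[1]])) {
    stop("analysis mask must match the burn-grid dimensions", call. = FALSE)
  }
  ord <- order(years, match(seasons, c("early", "late")))
  structure(
    list(masks = masks[ord], years = years[ord], seasons = seasons[ord],
         mask = mask, cell_size = cell_size,
         first_year = min(years), last_year = max(years)),
    class = "fire_history_stack"
  )
}

#' @export
print.fire_history_stack <- function(x, ...) {
  cat(sprintf("<fire_history_stack> %d-%d, %d layers, %d x %d cells (%d in mask)\n",
              x$first_year, x$last_year, length(x$masks),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Time since fire
#'
#' Per-cell years elapsed since the most recent detected burn in any season up
#' to and including the query year (0 in the year a cell burns). Cells with no
#' burn on record are right-censored at the record length. At least five years
#' of fire history must precede the query year.
#'
#' @param stack a [fire_history_stack()].
#' @param query_year year to evaluate at.
#' @return object of class `tsf_grid`: list with `tsf` (numeric matrix;
#'   censored cells hold the record length), `censored` (logical matrix),
#'   `record_years` (the censoring bound `k = query_year - first record
#'   year`), and `query_year`.
#' @export
time_since_fire <- function(stack, query_year) {
  stopifnot(inherits(stack, "fire_history_stack"))
  query_year <- as.integer(query_year)
  if (query_year - stack$first_year < 5L) {
    stop("time since fire needs at least five years of fire history before the query year",
         call. = FALSE)
  }
  if (query_year > stack$last_year) {
    stop("query year is beyond the end of the record", call. = FALSE)
  }
  last_burn <- matrix(NA_integer_, nrow(stack$mask), ncol(stack$mask))
  for (i in seq_along(stack$masks)) {
    if (stack$years[i] > query_year) break
    b <- stack$masks[[i]]
    last_burn[b] <- stack$years[i]
  }
  k <- query_year - stack$first_year
  censored <- is.na(last_burn)
  tsf <- query_year - last_burn
  tsf[censored] <- k
  structure(
    list(tsf = tsf, censored = censored, record_years = k,
         query_year = query_year, mask = stack$mask,
         cell_size = stack$cell_size),
    class = "tsf_grid"
  )
}

#' Long-unburnt patches
#'
#' Connected components of cells with time since fire strictly greater than
#' `min_age` inside the analysis mask. Censored (never-burnt) cells count as
#' long-unburnt: once the record exceeds `min_age` they necessarily satisfy
#' the age condition.
#'
#' @param tsf a `tsf_grid` from [time_since_fire()].
#' @param min_age minimum age (years) for the long-unburnt class (default 5).
#' @param connectivity 4 (rook) or 8 (queen, default) neighbour rule.
#' @return data frame with one row per patch (`id`, `cells`, `area_ha`),
#'   plus attributes `connectivity`, `query_year`, `n_long_unburnt_cells`.
#' @export
long_unburnt_patches <- function(tsf, min_age = 5, connectivity = 8) {
  stopifnot(inherits(tsf, "tsf_grid"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (!any(tsf$mask)) stop("analysis mask is empty", call. = FALSE)
  eligible <- (tsf$censored | tsf$tsf > min_age) & tsf$mask
  lab <- label_patches(eligible, connectivity)
  n_cells <- tabulate(lab[!is.na(lab)])
  out <- data.frame(
    id = seq_along(n_cells),
    cells = n_cells,
    area_ha = n_cells * tsf$cell_size^2 / 1e4
  )
  attr(out, "connectivity") <- connectivity
  attr(out, "query_year") <- tsf$query_year
  attr(out, "n_long_unburnt_cells") <- sum(eligible)
  out
}

# Connected-component labelling of a logical matrix via igraph components.
label_patches <- function(eligible, connectivity = 8) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  idx <- which(eligible)
  lab <- matrix(NA_integer_, nr, nc)
  if (length(idx) == 0L) return(lab)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- eligible[j]
    from <- c(from, idx[ok][keep]); to <- c(to, j[keep])
  }
  vid <- match(seq_len(nr * nc), idx) # cell index -> vertex id
  g <- igraph::make_graph(edges = rbind(vid[from], vid[to]), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Annual fire-regime summary
#'
#' Tabulates, for every year of the record, the proportion of mask cells burnt
#' early, late, and in total (the union of the two seasonal masks, not their
#' sum), and — for years with at least five years of prior history — the mean
#' time since fire, the proportion of cells long unburnt (> `min_age` years),
#' and the mean long-unburnt patch size.
#'
#' @param stack a [fire_history_stack()].
#' @param min_age long-unburnt age threshold (years, default 5).
#' @param connectivity patch neighbour rule, 4 or 8.
#' @return data frame with columns `year`, `p_early`, `p_late`, `p_total`,
#'   `mean_tsf`, `p_long_unburnt`, `mean_patch_ha` (the last three `NA` during
#'   the five-year spin-up). Censored cells enter `mean_tsf` at the record
#'   length (a lower bound).
#' @export
summarize_regime <- function(stack, min_age = 5, connectivity = 8) {
  stopifnot(inherits(stack, "fire_history_stack"))
  years <- sort(unique(stack$years))
  msk <- stack$mask
  n_mask <- sum(msk)
  rows <- lapply(years, function(y) {
    sel_e <- which(stack$years == y & stack$seasons == "early")
    sel_l <- which(stack$years == y & stack$seasons == "late")
    e <- if (length(sel_e)) stack$masks[[sel_e[1]]] else matrix(FALSE, nrow(msk), ncol(msk))
    l <- if (length(sel_l)) stack$masks[[sel_l[1]]] else matrix(FALSE, nrow(msk), ncol(msk))
    p_early <- sum(e & msk) / n_mask
    p_late <- sum(l & msk) / n_mask
    p_total <- sum((e | l) & msk) / n_mask
    if (y - stack$first_year >= 5L) {
      tg <- time_since_fire(stack, y)
      mean_tsf <- mean(tg$tsf[msk])
      patches <- long_unburnt_patches(tg, min_age = min_age, connectivity = connectivity)
      p_lu <- attr(patches, "n_long_unburnt_cells") / n_mask
      mean_patch <- if (nrow(patches)) mean(patches$area_ha) else NA_real_
    } else {
      mean_tsf <- NA_real_; p_lu <- NA_real_; mean_patch <- NA_real_
    }
    data.frame(year = y, p_early = p_early, p_late = p_late, p_total = p_total,
               mean_tsf = mean_tsf, p_long_unburnt = p_lu, mean_patch_ha = mean_patch)
  })
  do.call(rbind, rows)
}

#' Map a fire history from seasonal composites
#'
#' End-to-end burn mapping: per-year seasonal dNBR (early: MAM -> JJA; late:
#' JJA -> SON), subtraction of the all-year mean seasonal dNBR (removing
#' static landscape features), thresholding at `cutoff`, and assembly into a
#' [fire_history_stack()].
#'
#' @param composites list of [seasonal_composite()] objects covering the same
#'   grid, three windows per year across two or more years.
#' @param mask logical analysis mask, or `NULL` for the full grid.
#' @param cutoff burn threshold in dNBR units (default 0.75).
#' @param apply_cutoff_to `"anomaly"` (default; threshold the mean-adjusted
#'   dNBR, per the stated pipeline order) or `"raw"` (threshold the raw dNBR).
#' @return a [fire_history_stack()].
#' @export
map_fire_history <- function(composites, mask = NULL, cutoff = 0.75,
                             apply_cutoff_to = c("anomaly", "raw")) {
  apply_cutoff_to <- match.arg(apply_cutoff_to)
  years <- vapply(composites, function(cp) cp$year, integer(1))
  windows <- vapply(composites, function(cp) cp$season_window, character(1))
  yrs <- sort(unique(years))
  if (length(yrs) < 2L) stop("burn mapping needs composites from at least 2 years", call. = FALSE)
  get_comp <- function(y, w) {
    i <- which(years == y & windows == w)
    if (length(i) != 1L) stop(sprintf("need exactly one %s composite for %d", w, y), call. = FALSE)
    composites[[i]]
  }
  dnbr <- list(early = list(), late = list())
  for (y in yrs) {
    dnbr$early[[as.character(y)]] <- seasonal_dnbr(get_comp(y, "MAM"), get_comp(y, "JJA"))
    dnbr$late[[as.character(y)]] <- seasonal_dnbr(get_comp(y, "JJA"), get_comp(y, "SON"))
  }
  masks <- list()
  for (season in c("early", "late")) {
    grids <- if (apply_cutoff_to == "anomaly") mean_adjust(dnbr[[season]]) else dnbr[[season]]
    masks <- c(masks, lapply(grids, threshold_burns, cutoff = cutoff))
  }
  fire_history_stack(masks, mask = mask, cell_size = composites[[1]]$cell_size)
}
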