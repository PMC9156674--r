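# Tucson decadal ring-width (.rwl) interchange: fixed-width series id
# (8 chars), decade rows, integer widths, terminator marking the series end.
# Two dialects are in circulation: widths in 0.01 mm ending in 999, and
# widths in 0.001 mm ending in -9999; the reader auto-detects per series.

#' Write ring-width series in Tucson decadal format
#'
#' Widths are written in 0.01 mm with the 999 terminator.
#'
#' @param rwl data frame of ring widths (mm): calendar years as row names,
#'   one column per series; `NA` outside a series' span.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path) {
  years <- as.integer(rownames(rwl))
  if (anyNA(years)) stop("`rwl` row names must be calendar years", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in names(rwl)) {
    w <- rwl[[s]]
    present <- which(!is.na(w))
    if (length(present) == 0L) next
    yrs <- years[present[1]:present[length(present)]]
    vals <- w[present[1]:present[length(present)]]
    if (anyNA(vals)) stop(sprintf("series '%s' has interior gaps", s), call. = FALSE)
    ints <- as.integer(round(vals * 100))
    ints <- c(ints, 999L) # terminator
    yrs <- c(yrs, max(yrs) + 1L)
    id <- formatC(substr(s, 1, 8), width = 8, flag = "-")
    i <- 1L
    while (i <= length(ints)) {
      y <- yrs[i]
      n_in_row <- min(10L - (y %% 10L), length(ints) - i + 1L)
      row_vals <- ints[i:(i + n_in_row - 1L)]
      line <- paste0(id, formatC(y, width = 4),
                     paste(formatC(row_vals, width = 6), collapse = ""))
      writeLines(line, con)
      i <- i + n_in_row
    }
  }
  invisible(path)
}

#' Read ring-width series from a Tucson decadal file
#'
#' Auto-detects the 999 (0.01 mm) versus -9999 (0.001 mm) terminator dialect
#' per series and reports which was found.
#'
#' @param path .rwl file.
#' @return data frame of ring widths in mm, years as row names, one column
#'   per series; attribute `dialect` records the detected terminator per
#'   series.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- trimws(substr(lines, 1, 8))
  yrs <- as.integer(substr(lines, 9, 12))
  if (anyNA(yrs)) stop("malformed Tucson file: bad decade year field", call. = FALSE)
  series_vals <- list(); series_years <- list(); dialect <- character(0)
  for (s in unique(ids)) {
    sel <- which(ids == s)
    vals <- integer(0); vyears <- integer(0)
    for (li in sel) {
      rest <- substring(lines[li], 13)
      v <- suppressWarnings(as.integer(
        substring(rest, seq(1, nchar(rest), 6), pmin(seq(6, nchar(rest) + 5, 6), nchar(rest)))))
      v <- v[!is.na(v)]
      vals <- c(vals, v)
      vyears <- c(vyears, yrs[li] + seq_along(v) - 1L)
    }
    if (any(vals == -9999L)) {
      stop_at <- which(vals == -9999L)[1]
      scale <- 1000
      dialect[s] <- "-9999"
    } else if (any(vals == 999L)) {
      stop_at <- which(vals == 999L)[1]
      scale <- 100
      dialect[s] <- "999"
    } else {
      stop_at <- length(vals) + 1L
      scale <- 100
      dialect[s] <- "none"
    }
    keep <- seq_len(stop_at - 1L)
    series_vals[[s]] <- vals[keep] / scale
    series_years[[s]] <- vyears[keep]
  }
  all_years <- seq(min(unlist(series_years)), max(unlist(series_years)))
  out <- data.frame(row.names = as.character(all_years))
  for (s in names(series_vals)) {
    col <- rep(NA_real_, length(all_years))
    col[match(series_years[[s]], all_years)] <- series_vals[[s]]
    out[[s]] <- col
  }
  attr(out, "dialect") <- dialect
  out
}
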