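# Independent oracles used across the suite: deliberately brute-force and
# structurally unrelated to the package implementations they check.

# Time since fire by per-cell backward scan over the mask stack.
oracle_tsf <- function(masks, years, query_year, first_year) {
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  tsf <- matrix(NA_real_, nr, nc)
  cens <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      burn_years <- years[vapply(seq_along(masks), function(k) {
        years[k] <= query_year && masks[[k]][i, j]
      }, logical(1))]
      if (length(burn_years)) {
        tsf[i, j] <- query_year - max(burn_years)
        cens[i, j] <- FALSE
      } else {
        tsf[i, j] <- query_year - first_year
      }
    }
  }
  list(tsf = tsf, censored = cens)
}

# Connected components by queue-based flood fill.
oracle_label <- function(eligible, connectivity) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  offsets <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8) {
    offsets <- rbind(offsets, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  lab <- matrix(NA_integer_, nr, nc)
  next_id <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!eligible[si, sj] || !is.na(lab[si, sj])) next
    next_id <- next_id + 1L
    queue <- list(c(si, sj)); lab[si, sj] <- next_id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offsets))) {
        r <- cur[1] + offsets[k, 1]; c <- cur[2] + offsets[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            eligible[r, c] && is.na(lab[r, c])) {
          lab[r, c] <- next_id
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  lab
}

# Check loss of a two-group quantile fit over a dense grid of candidate
# coefficients (group-A candidates for the intercept, group-B candidates for
# intercept + slope; the check loss separates over the two groups).
oracle_qr_min_loss <- function(yA, yB, tau) {
  cand <- function(y) sort(unique(c(y, (head(sort(y), -1) + tail(sort(y), -1)) / 2)))
  lossA <- min(vapply(cand(yA), function(b) check_loss(yA - b, tau), numeric(1)))
  lossB <- min(vapply(cand(yB), function(b) check_loss(yB - b, tau), numeric(1)))
  lossA + lossB
}

# Random burn-mask stack for oracle comparisons.
random_stack <- function(nr = 20, nc = 20, years = 1990:2005, p_burn = 0.04) {
  masks <- list()
  for (y in years) for (s in c("early", "late")) {
    m <- matrix(runif(nr * nc) < p_burn, nr, nc)
    attr(m, "year") <- y; attr(m, "season") <- s
    masks[[length(masks) + 1L]] <- m
  }
  fire_history_stack(masks, cell_size = 30)
}
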