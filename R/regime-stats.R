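# Pre/post-intervention comparison of annual fire-regime summaries.

#' Intervention scheme
#'
#' Encodes a site's fire-management commencement year and the five-year-lagged
#' threshold used for the long-unburnt variable (the long-unburnt class cannot
#' respond until the management regime is older than the age cutoff). The two
#' study sites are built in: management commenced in 2006 on the
#' Dukaladjarranj estate and in 2007 in Kakadu National Park, giving lagged
#' thresholds of 2011 and 2012 respectively. The threshold year itself counts
#' as post-intervention.
#'
#' @param site `"dukaladjarranj"`, `"kakadu"`, or `"custom"`.
#' @param threshold_year required when `site = "custom"`.
#' @return object of class `intervention_scheme` with fields `site`,
#'   `threshold_year`, `lagged_year` (always `threshold_year + 5`).
#' @export
intervention_scheme <- function(site = c("dukaladjarranj", "kakadu", "custom"),
                                threshold_year = NULL) {
  site <- match.arg(site)
  threshold_year <- switch(site,
    dukaladjarranj = 2006L,
    kakadu = 2007L,
    custom = {
      if (is.null(threshold_year)) stop("custom scheme needs `threshold_year`", call. = FALSE)
      as.integer(threshold_year)
    })
  structure(list(site = site, threshold_year = threshold_year,
                 lagged_year = threshold_year + 5L),
            class = "intervention_scheme")
}

# Variables whose period split uses the lagged threshold.
LAGGED_VARIABLES <- "p_long_unburnt"

#' Classify years into pre/post-intervention periods
#'
#' A year is post-intervention iff it is greater than or equal to the scheme's
#' threshold year; the proportion-long-unburnt variable uses the lagged
#' threshold (threshold + 5) instead.
#'
#' @param year vector of calendar years.
#' @param scheme an [intervention_scheme()].
#' @param variable variable name; `"p_long_unburnt"` triggers the lag.
#' @return factor with levels `pre`, `post`.
#' @export
classify_period <- function(year, scheme, variable = "p_total") {
  stopifnot(inherits(scheme, "intervention_scheme"))
  thr <- if (variable %in% LAGGED_VARIABLES) scheme$lagged_year else scheme$threshold_year
  factor(ifelse(year >= thr, "post", "pre"), levels = c("pre", "post"))
}

#' Arcsine square-root transform
#'
#' Variance-stabilizing transform for proportions, asin(sqrt(p)), mapping
#' \[0, 1\] onto \[0, pi/2\]. Strictly increasing; proportions exactly 0 or 1
#' are transformed as-is (no continuity correction).
#'
#' @param p proportions in \[0, 1\].
#' @return transformed values.
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Fit a two-period linear model to an annual regime variable
#'
#' Ordinary least squares of the (optionally transformed) annual value on a
#' two-level pre/post period indicator — algebraically identical to the
#' equal-variance two-sample t-test. The slope is the post-minus-pre effect on
#' the transformed scale.
#'
#' @param values annual values of the variable.
#' @param periods factor with levels `pre`, `post` (e.g. from
#'   [classify_period()]).
#' @param transform `"identity"`, `"log"` (mean patch sizes), or
#'   `"arcsine_sqrt"` (proportions).
#' @param variable optional variable name carried into the result.
#' @return object of class `period_model`: list with `variable`, `transform`,
#'   `mean_pre`, `mean_post` (transformed scale), `slope`, `se`, `t`, `p`,
#'   `n_pre`, `n_post`.
#' @export
fit_period_model <- function(values, periods,
                             transform = c("identity", "log", "arcsine_sqrt"),
                             variable = NA_character_) {
  transform <- match.arg(transform)
  periods <- factor(periods, levels = c("pre", "post"))
  keep <- !is.na(values) & !is.na(periods)
  values <- values[keep]; periods <- periods[keep]
  if (any(table(periods) < 2L)) {
    stop("each period needs at least 2 years of data", call. = FALSE)
  }
  tv <- switch(transform,
    identity = values,
    log = {
      if (any(values <= 0)) stop("log transform: nonpositive value in input", call. = FALSE)
      log(values)
    },
    arcsine_sqrt = arcsine_sqrt(values))
  if (any(!is.finite(tv))) stop("transformed values must be finite", call. = FALSE)
  # Closed-form two-group OLS (equal-variance t-test): robust to perfect fits
  # where summary.lm's numerics degrade.
  n1 <- sum(periods == "pre"); n2 <- sum(periods == "post")
  m1 <- mean(tv[periods == "pre"]); m2 <- mean(tv[periods == "post"])
  slope <- m2 - m1
  rss <- sum((tv[periods == "pre"] - m1)^2) + sum((tv[periods == "post"] - m2)^2)
  se <- sqrt(rss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  if (se == 0) {
    tstat <- if (slope == 0) 0 else sign(slope) * Inf
    pval <- if (slope == 0) 1 else 0
  } else {
    tstat <- slope / se
    pval <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  }
  structure(
    list(variable = variable, transform = transform,
         mean_pre = mean(tv[periods == "pre"]),
         mean_post = mean(tv[periods == "post"]),
         slope = slope, se = se, t = tstat, p = pval,
         n_pre = sum(periods == "pre"), n_post = sum(periods == "post")),
    class = "period_model"
  )
}

#' @export
print.period_model <- function(x, ...) {
  cat(sprintf("<period_model> %s [%s]: slope %.4g (se %.3g), t = %.3f, p = %.4g (n %d pre / %d post)\n",
              x$variable, x$transform, x$slope, x$se, x$t, x$p, x$n_pre, x$n_post))
  invisible(x)
}

# Transform applied to each regime-summary variable in the standard analysis.
REGIME_TRANSFORMS <- c(
  mean_tsf = "identity",
  mean_patch_ha = "log",
  p_total = "arcsine_sqrt",
  p_early = "arcsine_sqrt",
  p_late = "arcsine_sqrt",
  p_long_unburnt = "arcsine_sqrt"
)

#' Pre/post comparison of a full regime summary
#'
#' Runs [fit_period_model()] for every regime variable with its standard
#' transform (mean time since fire untransformed, mean patch size
#' log-transformed, proportions arcsine-square-root transformed) and the
#' scheme's period split (lagged for the long-unburnt proportion).
#'
#' @param summary_df output of [summarize_regime()].
#' @param scheme an [intervention_scheme()].
#' @return data frame: `variable`, `transform`, `slope`, `se`, `t`, `p`,
#'   `n_pre`, `n_post`.
#' @export
compare_regimes <- function(summary_df, scheme) {
  vars <- intersect(names(REGIME_TRANSFORMS), names(summary_df))
  rows <- lapply(vars, function(v) {
    keep <- !is.na(summary_df[[v]])
    if (REGIME_TRANSFORMS[[v]] == "log") keep <- keep & summary_df[[v]] > 0
    per <- classify_period(summary_df$year[keep], scheme, variable = v)
    fit <- fit_period_model(summary_df[[v]][keep], per,
                            transform = REGIME_TRANSFORMS[[v]], variable = v)
    data.frame(variable = v, transform = fit$transform, slope = fit$slope,
               se = fit$se, t = fit$t, p = fit$p,
               n_pre = fit$n_pre, n_post = fit$n_post)
  })
  do.call(rbind, rows)
}
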