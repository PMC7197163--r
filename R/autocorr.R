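# Serial-autocorrelation diagnostic on SSF deviance residuals and the
# thinning sensitivity analysis.

#' Per-animal deviance residual series
#'
#' @param fit an `ssf_fit` with stratum metadata (animal ids, timestamps).
#' @param fix_interval_h nominal fix interval (h), carried through for the
#'   lag-to-hours conversion in [select_lag()].
#' @return A `residual_series`: data frame animal_id, timestamp, residual,
#'   ordered by animal then time, plus the fix interval if supplied.
#' @export
deviance_residuals <- function(fit, fix_interval_h = NULL) {
  r <- stats::residuals(fit, type = "deviance")
  df <- data.frame(animal_id = fit$strata$animal_id, residual = r)
  if (!is.null(fit$strata$timestamp)) df$timestamp <- fit$strata$timestamp
  ord <- if (!is.null(df$timestamp)) order(df$animal_id, df$timestamp) else order(df$animal_id)
  structure(list(series = df[ord, , drop = FALSE], fix_interval_h = fix_interval_h),
            class = "residual_series")
}

#' Autocorrelation function of residuals, centered per animal
#'
#' The pooled residual series is centered by its per-animal means (the
#' fitted values of an intercept-only model with a random intercept per
#' individual, in the degenerate-shrinkage limit) and the sample ACF is
#' computed using only lag pairs within the same animal. Significance
#' bounds are the usual +/- 1.96/sqrt(n).
#'
#' @param rs a `residual_series` (or data frame with animal_id, residual).
#' @param max_lag maximum lag (default 20).
#' @param center "animal" (default) or "pooled" (grand mean only).
#' @return An `acf_series`: lag, acf, bound, n.
#' @export
residual_acf <- function(rs, max_lag = 20L, center = c("animal", "pooled")) {
  center <- match.arg(center)
  df <- if (inherits(rs, "residual_series")) rs$series else rs
  n <- nrow(df)
  if (n < 10L) stop("need at least 10 residuals")
  x <- df$residual
  x <- if (center == "animal") x - stats::ave(x, df$animal_id) else x - mean(x)
  if (stats::sd(x) == 0) stop("constant residual series; ACF undefined")
  denom <- sum(x^2)
  ids <- df$animal_id
  ac <- vapply(0:max_lag, function(L) {
    if (L == 0L) return(1)
    i <- seq_len(n - L)
    same <- ids[i] == ids[i + L]
    sum(x[i][same] * x[i + L][same]) / denom
  }, numeric(1))
  structure(list(lag = 0:max_lag, acf = ac, bound = 1.96 / sqrt(n), n = n,
                 fix_interval_h = if (inherits(rs, "residual_series")) rs$fix_interval_h),
            class = "acf_series")
}

#' @export
print.acf_series <- function(x, ...) {
  cat(sprintf("residual ACF (n = %d, bound +/- %.3g):\n", x$n, x$bound))
  print(round(stats::setNames(x$acf, x$lag), 3))
  invisible(x)
}

#' @export
plot.acf_series <- function(x, ...) {
  graphics::plot(x$lag, x$acf, type = "h", xlab = "lag (strata)", ylab = "ACF", ...)
  graphics::abline(h = c(-1, 1) * x$bound, lty = 2, col = "blue")
  graphics::abline(h = 0)
  invisible(x)
}

#' First lag at which autocorrelation is non-significant
#'
#' @param ac an `acf_series`; @param fix_interval_h species fix interval in
#'   hours for the lag-to-hours conversion (2 dingo / 4 cat); taken from
#'   the series if absent.
#' @return List: `lag` (smallest L >= 1 with |acf| below the bound, NA if
#'   censored at max_lag), `hours` = lag x fix interval, `censored`.
#' @export
select_lag <- function(ac, fix_interval_h = NULL) {
  fix_interval_h <- fix_interval_h %||% ac$fix_interval_h
  ok <- which(ac$lag >= 1L & abs(ac$acf) < ac$bound)
  if (!length(ok))
    return(list(lag = NA_integer_, hours = NA_real_, censored = TRUE))
  L <- ac$lag[ok[1L]]
  list(lag = L,
       hours = if (is.null(fix_interval_h)) NA_real_ else L * fix_interval_h,
       censored = FALSE)
}

#' Thin choice sets to a lag and refit
#'
#' Keeps every L-th stratum per animal (in time order, phase 0 by default),
#' refits the same model, and tabulates the coefficient and SE changes —
#' the sensitivity analysis for serial autocorrelation.
#'
#' @param data long choice-set data frame.
#' @param L thinning lag (>= 1).
#' @param fit the original `ssf_fit` (for the comparison columns).
#' @param formula,stratum passed to [fit_clogit()].
#' @param phase which residue class of strata to keep (0..L-1).
#' @return List: `fit` (thinned refit), `table` (term, beta_full, se_full,
#'   beta_thinned, se_thinned, delta_beta, delta_se), `n_strata_thinned`.
#' @export
thin_and_refit <- function(data, L, fit, formula = NULL, stratum = "stratum",
                           phase = 0L) {
  stopifnot(L >= 1L)
  if (is.null(formula))   # refit exactly the terms the original fit kept
    formula <- stats::reformulate(fit$terms, response = "used")
  used_rows <- which(data$used == 1)
  meta <- data.frame(stratum = data[[stratum]][used_rows],
                     animal_id = data$animal_id[used_rows],
                     timestamp = data$timestamp[used_rows])
  meta <- meta[order(meta$animal_id, meta$timestamp), , drop = FALSE]
  keep_strata <- unlist(lapply(split(meta$stratum, meta$animal_id), function(s)
    s[(seq_along(s) - 1L) %% L == phase]))
  sub <- data[data[[stratum]] %in% keep_strata, , drop = FALSE]
  n_thin <- length(unique(sub[[stratum]]))
  if (n_thin < 30L) warning("thinned data has fewer than 30 strata")
  refit <- fit_clogit(sub, formula, stratum)
  tab <- data.frame(term = names(fit$coefficients),
                    beta_full = unname(fit$coefficients),
                    se_full = unname(fit$se),
                    beta_thinned = unname(refit$coefficients[names(fit$coefficients)]),
                    se_thinned = unname(refit$se[names(fit$coefficients)]))
  tab$delta_beta <- tab$beta_thinned - tab$beta_full
  tab$delta_se <- tab$se_thinned - tab$se_full
  list(fit = refit, table = tab, n_strata_thinned = n_thin)
}
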