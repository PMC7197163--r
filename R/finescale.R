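# Third-order habitat selection: empirical movement distributions, control
# step generation, choice-set assembly, and conditional logistic regression
# (fixed effects and per-individual random slopes).

#' Empirical step-length and turning-angle distributions
#'
#' Pooled across all individuals of a species; these raw samples are the
#' proposal distributions for control steps.
#'
#' @param steps step table from [build_steps()] (rows of one species,
#'   possibly several animals bound together).
#' @param species species label carried through for bookkeeping.
#' @param min_steps minimum pooled steps (default 30).
#' @return A `move_dists`: `lengths` (m), `angles` (rad, turns only where
#'   defined), `species`.
#' @export
empirical_move_dists <- function(steps, species = NULL, min_steps = 30L) {
  if (nrow(steps) < min_steps)
    stop(sprintf("need at least %d pooled steps, got %d", min_steps, nrow(steps)))
  has_turn <- !is.na(steps$turn)
  structure(list(lengths = steps$length_m,
                 angles = steps$turn[has_turn],
                 pairs = cbind(length = steps$length_m[has_turn],
                               angle = steps$turn[has_turn]),
                 species = species, n_steps = nrow(steps)),
            class = "move_dists")
}

#' @export
print.move_dists <- function(x, ...) {
  cat(sprintf("move_dists (%s): %d steps\n", x$species %||% "?", x$n_steps))
  cat("  step length quantiles (m):\n")
  print(round(stats::quantile(x$lengths, c(.05, .25, .5, .75, .95)), 1))
  invisible(x)
}

#' Generate control steps for one choice set
#'
#' Each control resamples a (length, angle) pair independently from the
#' empirical marginals (or jointly, keeping observed pairs together) and
#' displaces the origin by the length at bearing previous-bearing + angle.
#' Without a previous bearing the absolute bearing is uniform. Endpoints
#' outside the mapped extent are redrawn.
#'
#' @param origin c(x, y) step origin (m).
#' @param prev_bearing bearing of the preceding step (rad) or NA.
#' @param dists a `move_dists`.
#' @param K number of controls (default 20).
#' @param extent optional c(xmin, xmax, ymin, ymax) to redraw against.
#' @param joint resample observed (length, angle) pairs jointly.
#' @param max_reject redraw limit per control.
#' @return K x 2 matrix of endpoints.
#' @export
generate_control_steps <- function(origin, prev_bearing, dists, K = 20L,
                                   extent = NULL, joint = FALSE, max_reject = 1000L) {
  if (K == 0L) return(matrix(numeric(0), 0L, 2L))
  draw <- function(m) {
    if (joint) {
      i <- sample.int(nrow(dists$pairs), m, replace = TRUE)
      len <- dists$pairs[i, "length"]
      ang <- dists$pairs[i, "angle"]
    } else {
      # index-based resampling: sample(x, ...) misbehaves on length-1 pools
      len <- dists$lengths[sample.int(length(dists$lengths), m, replace = TRUE)]
      ang <- dists$angles[sample.int(length(dists$angles), m, replace = TRUE)]
    }
    bear <- if (is.na(prev_bearing)) stats::runif(m, -pi, pi) else prev_bearing + ang
    cbind(origin[1L] + len * cos(bear), origin[2L] + len * sin(bear))
  }
  pts <- draw(K)
  if (!is.null(extent)) {
    tries <- 0L
    repeat {
      bad <- pts[, 1L] < extent[1L] | pts[, 1L] > extent[2L] |
             pts[, 2L] < extent[3L] | pts[, 2L] > extent[4L]
      if (!any(bad)) break
      tries <- tries + 1L
      if (tries > max_reject) stop("control endpoints keep falling outside the mapped extent")
      pts[bad, ] <- draw(sum(bad))
    }
  }
  pts
}

#' Assemble conditional-logistic choice sets
#'
#' One stratum per observed step: the used endpoint plus K control
#' endpoints drawn from the empirical movement distributions, each
#' attributed on the landscape and encoded with [design_matrix()] terms.
#'
#' @param steps step table from [build_steps()].
#' @param dists a `move_dists`; @param map a `landscape_map`;
#' @param K controls per stratum (default 20); @param seed RNG seed;
#' @param joint joint (length, angle) resampling (default marginal).
#' @return Long data frame: stratum, animal_id, timestamp, used (0/1),
#'   x, y, habitat attributes, design columns, and `veg_wood` (woodland
#'   indicator used as the random-slope covariate).
#' @export
build_choice_sets <- function(steps, dists, map, K = 20L, seed = 1L, joint = FALSE) {
  set.seed(seed)
  n <- nrow(steps)
  if (n == 0L) stop("no steps to build choice sets from")
  prev_bearing <- steps$bearing - steps$turn   # NA where no previous step
  e <- map$extent
  # inside-extent guard for used endpoints: attribution requires it
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ctrl <- generate_control_steps(c(steps$x0[i], steps$y0[i]), prev_bearing[i],
                                   dists, K = K, extent = e, joint = joint)
    rows[[i]] <- cbind(stratum = i, used = c(1, rep(0, K)),
                       x = c(steps$x1[i], ctrl[, 1L]),
                       y = c(steps$y1[i], ctrl[, 2L]))
  }
  long <- as.data.frame(do.call(rbind, rows))
  long$animal_id <- steps$animal_id[long$stratum]
  long$timestamp <- steps$t_end[long$stratum]
  attrs <- attribute_points(map, long$x, long$y)
  X <- design_matrix(attrs)
  out <- cbind(long[c("stratum", "animal_id", "timestamp", "used", "x", "y")],
               attrs, as.data.frame(X))
  out$veg_wood <- out$offroad_wood + out$onroad_wood
  out
}

ssf_terms_default <- c("onroad_grass", "offroad_wood", "onroad_wood",
                       "hydro", "cover_high", "cover_low")

# conditional log-likelihood, gradient, Hessian and fitted used-probabilities
clogit_core <- function(beta, X, y, sidx, nlev) {
  lp <- drop(X %*% beta)
  M <- vapply(split(lp, sidx), max, numeric(1))
  w <- exp(lp - M[sidx])
  denom <- drop(rowsum(w, sidx))
  p <- w / denom[sidx]
  ll <- sum(lp[y == 1]) - sum(M + log(denom))
  xbar <- rowsum(X * p, sidx)
  g <- drop(crossprod(X, y - p))
  H <- -(crossprod(X, X * p) - crossprod(xbar))
  list(ll = ll, g = g, H = H, p = p)
}

#' Fit a step-selection function by conditional logistic regression
#'
#' Maximizes the conditional log-likelihood
#' sum over strata of \[x_used' beta - log sum_j exp(x_j' beta)\]
#' by Newton iteration with step halving; standard errors come from the
#' observed information. This is the likelihood of a stratified Cox model
#' with one event per stratum, so coefficients are log odds ratios of a
#' feature being chosen relative to the reference habitat state
#' (off-road grassland, moderate cover).
#'
#' @param data long choice-set data frame (e.g. [build_choice_sets()]) or
#'   any data with a used indicator, stratum id and numeric covariates.
#' @param formula model formula such as `used ~ hydro + cover_high`; the
#'   intercept is ignored (it cancels within strata). Default: the six
#'   standard habitat terms.
#' @param stratum name of the stratum id column.
#' @param tol convergence tolerance on the gradient sup-norm.
#' @param max_iter Newton iteration cap.
#' @param drop_inestimable drop covariates with no within-stratum variation
#'   (with a message) instead of erroring; the dropped names are recorded
#'   in the fit.
#' @return An `ssf_fit` with coefficients, vcov, SEs, log-likelihoods,
#'   fitted used-probabilities per stratum and convergence info. Methods:
#'   print, summary, coef, vcov, logLik, confint, residuals, plot.
#' @export
fit_clogit <- function(data, formula = NULL, stratum = "stratum",
                       tol = 1e-8, max_iter = 50L, drop_inestimable = FALSE) {
  if (is.null(formula))
    formula <- stats::reformulate(ssf_terms_default, response = "used")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  s <- factor(data[[stratum]], levels = unique(data[[stratum]]))
  sidx <- as.integer(s)
  if (!all(tapply(y, sidx, sum) == 1L)) stop("each stratum must contain exactly one used record")
  # a covariate constant within every stratum is inestimable
  wg_var <- vapply(seq_len(ncol(X)), function(j) {
    mu <- stats::ave(X[, j], sidx)
    max(abs(X[, j] - mu))
  }, numeric(1))
  dropped <- character(0)
  if (any(wg_var < 1e-12)) {
    bad <- colnames(X)[wg_var < 1e-12]
    if (!drop_inestimable)
      stop("covariate(s) constant within all strata (inestimable): ",
           paste(bad, collapse = ", "))
    message("dropping inestimable covariate(s): ", paste(bad, collapse = ", "))
    dropped <- bad
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    if (ncol(X) == 0L) stop("no estimable covariates remain")
  }
  beta <- rep(0, ncol(X))
  st <- clogit_core(beta, X, y, sidx, nlevels(s))
  ll0 <- st$ll
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(st$H, -st$g), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix; model inestimable")
    lam <- 1
    repeat {
      cand <- beta + lam * step
      st2 <- clogit_core(cand, X, y, sidx, nlevels(s))
      if (is.finite(st2$ll) && st2$ll >= st$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) stop("step halving failed; gradient norm ", format(max(abs(st$g))))
    }
    beta <- cand; st <- st2
    if (max(abs(st$g)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("conditional logistic fit did not converge; gradient norm ",
         format(max(abs(st$g))))
  V <- solve(-st$H)
  se <- sqrt(diag(V))
  names(beta) <- rownames(V) <- colnames(V) <- names(se) <- colnames(X)
  p_used <- st$p[y == 1]    # one per stratum, in stratum order
  separation <- any(p_used > 1 - 1e-10) && any(abs(beta) > 15)
  if (separation) warning("possible separation: some strata predicted perfectly")
  meta <- data.frame(stratum = levels(s),
                     animal_id = if ("animal_id" %in% names(data))
                       data$animal_id[y == 1] else NA_character_)
  if ("timestamp" %in% names(data)) meta$timestamp <- data$timestamp[y == 1]
  structure(list(coefficients = beta, se = se, vcov = V,
                 loglik = st$ll, loglik_null = ll0,
                 n_strata = nlevels(s), n_alt = length(y) / nlevels(s),
                 p_used = p_used, strata = meta,
                 converged = converged, iterations = iter,
                 separation = separation, terms = colnames(X),
                 dropped = dropped),
            class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("step-selection fit: %d strata, logLik %.2f (null %.2f), %d Newton iterations\n",
              x$n_strata, x$loglik, x$loglik_null, x$iterations))
  print(round(cbind(beta = x$coefficients, se = x$se,
                    odds_ratio = exp(x$coefficients)), 4))
  invisible(x)
}

#' @export
summary.ssf_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(term = names(object$coefficients),
                    beta = object$coefficients, se = object$se,
                    odds_ratio = exp(object$coefficients),
                    ci_lo = exp(object$coefficients - 1.96 * object$se),
                    ci_hi = exp(object$coefficients + 1.96 * object$se),
                    z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  structure(list(table = tab, loglik = object$loglik, loglik_null = object$loglik_null,
                 n_strata = object$n_strata,
                 ranef_sd = object$ranef_sd, ranef_note = object$ranef_note),
            class = "summary.ssf_fit")
}

#' @export
print.summary.ssf_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic step-selection function (%d strata)\n", x$n_strata))
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("logLik %.2f, null (beta = 0) %.2f\n", x$loglik, x$loglik_null))
  if (!is.null(x$ranef_sd))
    cat(sprintf("random slope SD (vegetation, by individual): %.3g\n", x$ranef_sd))
  if (!is.null(x$ranef_note)) cat(x$ranef_note, "\n")
  invisible(x)
}

#' @export
coef.ssf_fit <- function(object, ...) object$coefficients

#' @export
vcov.ssf_fit <- function(object, ...) object$vcov

#' @export
logLik.ssf_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_strata, class = "logLik")
}

#' @export
confint.ssf_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Deviance residuals of a step-selection fit
#'
#' One residual per stratum from the one-event stratified-Cox equivalence:
#' with p the fitted probability of the used alternative, the martingale
#' residual is m = 1 - p and the deviance residual
#' sign(m) * sqrt(-2 * (m + log(p))).
#'
#' @param object an `ssf_fit`; @param type "deviance" or "martingale".
#' @param ... unused.
#' @return Numeric vector, one per stratum, in stratum order.
#' @export
residuals.ssf_fit <- function(object, type = c("deviance", "martingale"), ...) {
  type <- match.arg(type)
  p <- pmax(object$p_used, 1e-12)
  if (min(object$p_used) <= 0) warning("clipped zero fitted probabilities")
  m <- 1 - p
  if (type == "martingale") return(m)
  sign(m) * sqrt(-2 * (m + log(p)))
}

#' @export
plot.ssf_fit <- function(x, ...) {
  ci <- confint(x)
  k <- length(x$coefficients)
  graphics::plot(x$coefficients, seq_len(k), xlim = range(ci, 0), yaxt = "n",
                 xlab = "log odds ratio", ylab = "", pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = names(x$coefficients), las = 1)
  graphics::segments(ci[, 1L], seq_len(k), ci[, 2L], seq_len(k))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Conditional logistic fit with a per-individual random vegetation slope
#'
#' Adds Gaussian per-individual deviations on the vegetation (woodland)
#' slope, estimated by penalized conditional likelihood with the variance
#' chosen by Laplace-approximate profile likelihood. A per-individual
#' random intercept is part of the paper-faithful model statement, but an
#' individual indicator is constant within every stratum and therefore
#' cancels from the conditional likelihood; this is detected and reported
#' rather than estimated.
#'
#' @param data long choice-set data frame with an `animal_id` column.
#' @param formula fixed-effects formula (default: the six standard terms).
#' @param slope name of the random-slope covariate column (default
#'   `veg_wood`, the woodland indicator).
#' @param stratum stratum id column name.
#' @param sigma_grid log-scale search interval for the random-slope SD.
#' @return An `ssf_fit` with extra fields `ranef_sd` (estimated SD, 0 on
#'   the boundary), `ranef` (per-individual deviations) and `ranef_note`
#'   (the random-intercept cancellation diagnostic).
#' @export
fit_clogit_ranef <- function(data, formula = NULL, slope = "veg_wood",
                             stratum = "stratum",
                             sigma_grid = c(log(0.02), log(5))) {
  ids <- factor(data$animal_id[!duplicated(data[[stratum]])])
  if (nlevels(ids) < 2L) stop("random effects need at least 2 individuals")
  if (is.null(formula))
    formula <- stats::reformulate(ssf_terms_default, response = "used")
  y <- data[[all.vars(formula)[1L]]]
  Xf <- stats::model.matrix(formula, stats::model.frame(formula, data))
  Xf <- Xf[, colnames(Xf) != "(Intercept)", drop = FALSE]
  s <- factor(data[[stratum]], levels = unique(data[[stratum]]))
  sidx <- as.integer(s)
  grp <- factor(data$animal_id)
  G <- nlevels(grp)
  z <- data[[slope]]
  Zb <- stats::model.matrix(~ grp - 1) * z       # per-individual slope columns
  colnames(Zb) <- paste0("b.", levels(grp))
  X <- cbind(Xf, Zb)
  p_fix <- ncol(Xf)
  pen_idx <- p_fix + seq_len(G)
  # random intercept diagnostic: individual indicators are stratum-constant
  const_within <- all(stats::ave(as.numeric(grp), sidx,
                                 FUN = function(v) max(v) - min(v)) == 0)
  note <- if (const_within)
    "random intercept for individual cancels within conditional-logistic strata (not estimable); reported, not estimated"
  fit_at <- function(log_sigma) {
    sg2 <- exp(2 * log_sigma)
    beta <- rep(0, ncol(X))
    st <- clogit_core(beta, X, y, sidx, nlevels(s))
    pll <- st$ll - sum(beta[pen_idx]^2) / (2 * sg2)
    for (it in 1:50) {
      g <- st$g; g[pen_idx] <- g[pen_idx] - beta[pen_idx] / sg2
      H <- st$H; diag(H)[pen_idx] <- diag(H)[pen_idx] - 1 / sg2
      step <- solve(H, -g)
      lam <- 1
      repeat {
        cand <- beta + lam * step
        st2 <- clogit_core(cand, X, y, sidx, nlevels(s))
        pll2 <- st2$ll - sum(cand[pen_idx]^2) / (2 * sg2)
        if (is.finite(pll2) && pll2 >= pll - 1e-12) break
        lam <- lam / 2
        if (lam < 1e-9) break
      }
      conv <- max(abs(g)) < 1e-6 || abs(pll2 - pll) < 1e-10
      beta <- cand; st <- st2; pll <- pll2
      if (conv) break
    }
    Hp <- -st$H; diag(Hp)[pen_idx] <- diag(Hp)[pen_idx] + 1 / sg2
    Hb <- Hp[pen_idx, pen_idx, drop = FALSE]
    lap <- pll - G * log_sigma - 0.5 * determinant(Hb, logarithm = TRUE)$modulus
    list(lap = as.numeric(lap), beta = beta, Hp = Hp, ll = st$ll, p = st$p)
  }
  opt <- stats::optimize(function(ls) -fit_at(ls)$lap,
                         interval = sigma_grid, tol = 1e-3)
  log_sigma <- opt$minimum
  boundary <- log_sigma <= sigma_grid[1L] + 0.02
  if (boundary) {
    fx <- fit_clogit(data, formula, stratum)
    fx$ranef_sd <- 0
    fx$ranef <- stats::setNames(rep(0, G), levels(grp))
    fx$ranef_note <- paste0(note %||% "",
      if (!is.null(note)) "; " else "",
      "random-slope variance estimated on the boundary (0); fixed-effects fit returned")
    return(fx)
  }
  res <- fit_at(log_sigma)
  V <- solve(res$Hp)
  beta <- res$beta[seq_len(p_fix)]
  se <- sqrt(diag(V)[seq_len(p_fix)])
  names(beta) <- names(se) <- colnames(Xf)
  p_used <- res$p[y == 1]
  meta <- data.frame(stratum = levels(s), animal_id = data$animal_id[y == 1])
  if ("timestamp" %in% names(data)) meta$timestamp <- data$timestamp[y == 1]
  structure(list(coefficients = beta, se = se,
                 vcov = V[seq_len(p_fix), seq_len(p_fix), drop = FALSE],
                 loglik = res$ll, loglik_null = -sum(log(tabulate(sidx))),
                 n_strata = nlevels(s), n_alt = length(y) / nlevels(s),
                 p_used = p_used, strata = meta, converged = TRUE,
                 iterations = NA_integer_, separation = FALSE,
                 terms = colnames(Xf),
                 ranef_sd = exp(log_sigma),
                 ranef = stats::setNames(res$beta[pen_idx], levels(grp)),
                 ranef_note = note),
            class = "ssf_fit")
}

#' Solar elevation angle
#'
#' Low-precision solar position (adequate for day/night classification).
#'
#' @param time POSIXct in UTC; @param lat,lon site coordinates in degrees
#'   (negative latitude = southern hemisphere).
#' @return Elevation above the horizon in degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  d2r <- pi / 180
  n <- as.numeric(difftime(time, as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                           units = "days"))
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360 * d2r
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r
  eps <- (23.439 - 4e-7 * n) * d2r
  alpha <- atan2(cos(eps) * sin(lambda), cos(lambda)) / d2r
  delta <- asin(sin(eps) * sin(lambda))
  gmst <- (280.46061837 + 360.98564736629 * n) %% 360
  H <- ((gmst + lon - alpha + 180) %% 360 - 180) * d2r
  asin(sin(lat * d2r) * sin(delta) + cos(lat * d2r) * cos(delta) * cos(H)) / d2r
}

#' Fit the SSF separately on data subsets
#'
#' Diel subsets use the solar elevation at each stratum's used fix (above
#' the horizon = diurnal); sex subsets use a per-animal sex table. Subsets
#' with fewer than `min_strata` strata are skipped with a notice (e.g. too
#' few females collared).
#'
#' @param data long choice-set data frame with timestamps.
#' @param by "diel" or "sex".
#' @param sex_table named vector animal_id -> "M"/"F" (required for "sex").
#' @param lat,lon site coordinates for the solar calculation (defaults:
#'   26.23 deg S, 121.56 deg E).
#' @param min_strata skip threshold (default 30).
#' @param formula,stratum passed to [fit_clogit()].
#' @return Named list of `ssf_fit` objects; skipped subsets carry a
#'   character notice instead of a fit.
#' @export
subset_fits <- function(data, by = c("diel", "sex"), sex_table = NULL,
                        lat = -26.23, lon = 121.56, min_strata = 30L,
                        formula = NULL, stratum = "stratum") {
  by <- match.arg(by)
  used_rows <- data$used == 1
  lab_used <- if (by == "diel") {
    elev <- solar_elevation(data$timestamp[used_rows], lat, lon)
    ifelse(elev > 0, "diurnal", "nocturnal")
  } else {
    if (is.null(sex_table)) stop("sex_table required for sex subsets")
    unname(sex_table[as.character(data$animal_id[used_rows])])
  }
  lab <- lab_used[match(data[[stratum]], data[[stratum]][used_rows])]
  out <- list()
  for (lv in sort(unique(lab))) {
    sub <- data[lab == lv, , drop = FALSE]
    nst <- length(unique(sub[[stratum]]))
    out[[lv]] <- if (nst < min_strata) {
      sprintf("skipped: %d strata < %d minimum", nst, min_strata)
    } else fit_clogit(sub, formula, stratum)
  }
  out
}

#' Pairwise Pearson correlations of the design columns
#'
#' @param data long choice-set data frame.
#' @param cols design columns (default: the six standard terms).
#' @param threshold flag pairs with |r| above this (default 0.7; the study
#'   regime reports a maximum of 0.39).
#' @return List: `r` (correlation matrix), `flagged` (data frame of pairs
#'   above threshold), `zero_variance` (column names with undefined r).
#' @export
feature_correlations <- function(data, cols = ssf_terms_default, threshold = 0.7) {
  X <- as.matrix(data[cols])
  sds <- apply(X, 2L, stats::sd)
  zv <- colnames(X)[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  pairs <- which(upper.tri(r) & abs(r) > threshold & is.finite(r), arr.ind = TRUE)
  flagged <- data.frame(a = colnames(r)[pairs[, 1L]], b = colnames(r)[pairs[, 2L]],
                        r = r[pairs])
  list(r = r, flagged = flagged, zero_variance = zv)
}
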