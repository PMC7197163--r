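# GPS fix quality control: observation window clipping, speed and elevation
# filters, moving/resting classification and step construction.

#' Species screening presets
#'
#' Thresholds used to screen collar fixes: a single-step gallop speed, a
#' sustained (two-sided) trot speed, an elevation tolerance around the site
#' reference, the moving/resting displacement cutoff (from stationary-collar
#' error testing), the post-release discard and the analysis window length.
#'
#' @param species "dingo" or "cat".
#' @param window_end end of the analysis window (e.g. bait deployment date).
#' @return List of screening parameters. Defaults: dingo gallop 16 km/h,
#'   trot 8.75 km/h, cutoff 20 m, 2-h fixes; cat gallop 3.2 km/h, trot
#'   2.0 km/h, cutoff 35 m, 4-h fixes; both: elevation tolerance 100 m,
#'   24-h release discard, 70-day window.
#' @export
screening_params <- function(species = c("dingo", "cat"), window_end = NULL) {
  species <- match.arg(species)
  p <- switch(species,
    dingo = list(gallop_kmh = 16, trot_kmh = 8.75, move_threshold_m = 20, fix_interval_h = 2),
    cat = list(gallop_kmh = 3.2, trot_kmh = 2.0, move_threshold_m = 35, fix_interval_h = 4))
  c(p, list(species = species, elev_tolerance_m = 100, release_discard_h = 24,
            window_days = 70, window_end = window_end,
            step_tolerance_min = 15, speed_rule = "joint"))
}

#' Construct a GPS track
#'
#' @param fixes data frame with columns timestamp (POSIXct, UTC), x, y,
#'   elevation; one animal.
#' @param animal_id,species,sex metadata; species "dingo" or "cat".
#' @param fix_interval_h nominal fix schedule in hours (2 dingo / 4 cat).
#' @param release_time collar release time (POSIXct).
#' @return A `gps_track`: the fix table (time-ordered, strictly increasing)
#'   with a `status` column ("raw" until screened) and track metadata.
#' @export
gps_track <- function(fixes, animal_id, species = c("dingo", "cat"), sex = NA_character_,
                      fix_interval_h = NULL, release_time = NULL) {
  species <- match.arg(species)
  if (is.null(fix_interval_h)) fix_interval_h <- if (species == "dingo") 2 else 4
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  if (anyDuplicated(fixes$timestamp)) stop("fix timestamps must be strictly increasing")
  fixes$status <- if (is.null(fixes$status)) "raw" else fixes$status
  rownames(fixes) <- NULL
  structure(list(fixes = fixes, animal_id = animal_id, species = species, sex = sex,
                 fix_interval_h = fix_interval_h, release_time = release_time),
            class = "gps_track")
}

#' @export
print.gps_track <- function(x, ...) {
  cat(sprintf("gps_track %s (%s, %s): %d fixes, %g-h schedule\n", x$animal_id,
              x$species, x$sex, nrow(x$fixes), x$fix_interval_h))
  if (length(unique(x$fixes$status)) > 1L || x$fixes$status[1L] != "raw")
    print(table(x$fixes$status))
  invisible(x)
}

#' Retained (not removed) fixes of a track
#' @param track a `gps_track`.
#' @return The subset of the fix table not tagged with a removal status.
#' @export
retained_fixes <- function(track) {
  track$fixes[!startsWith(track$fixes$status, "removed"), , drop = FALSE]
}

#' Clip a track to the analysis window
#'
#' Retains fixes in \[max(release + release_discard, window_end - window_days),
#' window_end); the first post-release day and anything outside the window
#' (up to 70 days before the bait date by default) are tagged
#' `removed_window`.
#'
#' @param track a `gps_track`; @param params from [screening_params()]
#'   with `window_end` set.
#' @return The track with window removals tagged.
#' @export
clip_window <- function(track, params) {
  if (is.null(params$window_end)) stop("window_end must be set")
  lo <- params$window_end - params$window_days * 86400
  if (!is.null(track$release_time))
    lo <- max(lo, track$release_time + params$release_discard_h * 3600)
  t <- track$fixes$timestamp
  drop <- t < lo | t >= params$window_end
  track$fixes$status[drop & track$fixes$status == "raw"] <- "removed_window"
  if (all(startsWith(track$fixes$status, "removed")))
    warning("no fixes remain after window clipping for ", track$animal_id)
  track
}

step_speeds_kmh <- function(fx) {
  d <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  dt <- as.numeric(difftime(fx$timestamp[-1L], fx$timestamp[-nrow(fx)], units = "hours"))
  d / 1000 / dt
}

#' Remove implausibly fast fixes
#'
#' Iteratively removes a fix if the straight-line speed from the previous
#' retained fix exceeds the gallop speed, or (joint rule, default) the
#' speeds both into and out of the fix exceed the sustained trot speed.
#' Speeds are recomputed after each removal.
#'
#' @param track a `gps_track`; @param params from [screening_params()].
#'   `params$speed_rule` may be "joint" (default) or "gallop_then_trot"
#'   (gallop pass to convergence, then trot pass).
#' @return The track with speed removals tagged `removed_speed`.
#' @export
speed_filter <- function(track, params) {
  rule <- params$speed_rule %||% "joint"
  apply_pass <- function(track, use_gallop, use_trot) {
    repeat {
      fx <- retained_fixes(track)
      n <- nrow(fx)
      if (n < 2L) break
      sp <- step_speeds_kmh(fx)                 # sp[i]: speed into fix i+1
      bad <- rep(FALSE, n)
      if (use_gallop) bad[-1L] <- sp > params$gallop_kmh
      if (use_trot && n >= 3L) {
        mid <- 2:(n - 1L)
        bad[mid] <- bad[mid] | (sp[mid - 1L] > params$trot_kmh & sp[mid] > params$trot_kmh)
      }
      if (!any(bad)) break
      victim <- which(bad)[1L]
      idx <- as.integer(rownames(fx))[victim]
      track$fixes$status[idx] <- "removed_speed"
    }
    track
  }
  rownames(track$fixes) <- NULL
  if (rule == "joint") {
    track <- apply_pass(track, TRUE, TRUE)
  } else {
    track <- apply_pass(track, TRUE, FALSE)
    track <- apply_pass(track, FALSE, TRUE)
  }
  track
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove fixes with implausible elevation
#'
#' @param track a `gps_track`; @param ref_elev site reference elevation (m);
#' @param params from [screening_params()] (tolerance 100 m by default).
#' @return Track with removals tagged `removed_elev`; fixes with missing
#'   elevation are retained and counted in the report attribute.
#' @export
elevation_filter <- function(track, ref_elev, params) {
  stopifnot(is.finite(ref_elev))
  keepable <- track$fixes$status == "raw"
  dev <- abs(track$fixes$elevation - ref_elev)
  bad <- keepable & !is.na(dev) & dev > params$elev_tolerance_m
  track$fixes$status[bad] <- "removed_elev"
  attr(track, "n_missing_elev") <- sum(keepable & is.na(dev))
  track
}

#' Classify fixes as moving or resting
#'
#' A fix is "moving" when its displacement from the preceding retained fix
#' strictly exceeds the species movement cutoff (20 m dingo / 35 m cat,
#' from stationary-collar error rates), else "resting". The first retained
#' fix has no preceding fix and is labelled moving. Resting fixes are
#' excluded from step-selection analyses downstream.
#'
#' @param track a screened `gps_track`; @param params screening parameters.
#' @return Track with statuses "moving"/"resting" and attribute
#'   `prop_moving` (over fixes with a preceding fix).
#' @export
classify_movement <- function(track, params) {
  fx <- retained_fixes(track)
  if (nrow(fx) < 2L) {
    warning("track has < 2 retained fixes; no movement labels assigned")
    return(track)
  }
  d <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  lab <- c("moving", ifelse(d > params$move_threshold_m, "moving", "resting"))
  idx <- as.integer(rownames(fx))
  track$fixes$status[idx] <- lab
  attr(track, "prop_moving") <- mean(lab[-1L] == "moving")
  track
}

#' Full screening pass
#'
#' Applies the filters in their canonical order: window clip, speed filter,
#' elevation filter, movement classification. Idempotent: re-screening the
#' output changes nothing.
#'
#' @param track a `gps_track`; @param params from [screening_params()];
#' @param ref_elev site reference elevation (m).
#' @return Screened track with a `screening_report` attribute (counts per
#'   removal reason and proportion moving).
#' @export
screen_track <- function(track, params, ref_elev) {
  track$fixes$status[track$fixes$status %in% c("moving", "resting")] <- "raw"
  track <- clip_window(track, params)
  track <- speed_filter(track, params)
  track <- elevation_filter(track, ref_elev, params)
  track <- classify_movement(track, params)
  st <- track$fixes$status
  attr(track, "screening_report") <- data.frame(
    animal_id = track$animal_id, species = track$species,
    n_raw = length(st),
    n_removed_window = sum(st == "removed_window"),
    n_removed_speed = sum(st == "removed_speed"),
    n_removed_elev = sum(st == "removed_elev"),
    n_moving = sum(st == "moving"), n_resting = sum(st == "resting"),
    prop_moving = attr(track, "prop_moving") %||% NA_real_)
  track
}

#' Build movement steps from a classified track
#'
#' Consecutive moving fixes separated by exactly one nominal fix interval
#' (within the schedule tolerance) form steps; a turning angle is defined
#' only when the previous step ends where this one starts.
#'
#' @param track a `gps_track` after [classify_movement()].
#' @param tolerance_min schedule tolerance in minutes (default from params: 15).
#' @return Data frame: animal_id, t_start, t_end, x0, y0, x1, y1, length_m,
#'   bearing (rad), turn (rad in (-pi, pi], NA when undefined), dt_h.
#' @export
build_steps <- function(track, tolerance_min = 15) {
  fx <- track$fixes[track$fixes$status == "moving", , drop = FALSE]
  n <- nrow(fx)
  if (n < 2L)
    return(data.frame(animal_id = character(0), t_start = as.POSIXct(character(0), tz = "UTC"),
                      t_end = as.POSIXct(character(0), tz = "UTC"),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      length_m = numeric(0), bearing = numeric(0), turn = numeric(0),
                      dt_h = numeric(0)))
  dt <- as.numeric(difftime(fx$timestamp[-1L], fx$timestamp[-n], units = "hours"))
  ok <- abs(dt - track$fix_interval_h) <= tolerance_min / 60
  i <- which(ok)
  steps <- data.frame(animal_id = track$animal_id,
                      t_start = fx$timestamp[i], t_end = fx$timestamp[i + 1L],
                      x0 = fx$x[i], y0 = fx$y[i], x1 = fx$x[i + 1L], y1 = fx$y[i + 1L])
  steps$length_m <- sqrt((steps$x1 - steps$x0)^2 + (steps$y1 - steps$y0)^2)
  steps$bearing <- atan2(steps$y1 - steps$y0, steps$x1 - steps$x0)
  prev <- match(i - 1L, i)                 # previous step must be contiguous
  turn <- steps$bearing - steps$bearing[prev]
  turn <- ((turn + pi) %% (2 * pi)) - pi
  turn[!is.na(turn) & turn == -pi] <- pi   # angles live in (-pi, pi]
  steps$turn <- turn
  steps$dt_h <- dt[i]
  attr(steps, "n_gaps") <- sum(!ok)
  steps
}
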