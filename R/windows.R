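## Meal-centered window construction: imputation, geometry, exclusion and
## variable definitions. A window spans [-120, 0) minutes pre-meal (24 samples
## x 5 channels) through +210 minutes post-meal on the 5-minute CGM grid.

#' Window construction rules
#'
#' @param pre_min pre-meal span in minutes (fixed geometry: 24 samples).
#' @param post_max last post-meal horizon in minutes.
#' @param mediator_window closed interval (minutes relative to meal) over
#'   which bolus insulin is aggregated into the mediator.
#' @param min_separation minimum spacing between meals (minutes); closer
#'   pairs are excluded as overlapping.
#' @param horizons outcome horizons (minutes).
#' @param max_missing maximum number of missing glucose values tolerated in
#'   \[-pre_min, post_max\] after imputation (default 0: strictest reading).
#' @param artifact_jump glucose change (mg/dL per 5 min) flagged as a CGM
#'   artifact.
#' @param glucose_range physiologically plausible glucose range (mg/dL).
#' @param train_fraction chronological fraction of days assigned to training.
#' @param doses carbohydrate dose contrasts (grams) for anchors.
#' @return a list of class `window_rules`.
#' @export
window_rules <- function(pre_min = 120, post_max = 210,
                         mediator_window = c(-120, 60), min_separation = 90,
                         horizons = HORIZONS, max_missing = 0,
                         artifact_jump = 40, glucose_range = c(20, 600),
                         train_fraction = 0.65, doses = c(15, 30, 45)) {
  structure(list(pre_min = pre_min, post_max = post_max,
                 mediator_window = mediator_window, min_separation = min_separation,
                 horizons = as.integer(horizons), max_missing = max_missing,
                 artifact_jump = artifact_jump, glucose_range = glucose_range,
                 train_fraction = train_fraction, doses = doses),
            class = "window_rules")
}

#' Impute short CGM gaps by linear interpolation
#'
#' Runs of at most five consecutive missing readings are linearly
#' interpolated between the flanking observed values; runs of six or more
#' remain missing. Observed values are never changed, so the operation is
#' idempotent.
#'
#' @param cgm data frame with columns subject_id, time_min, glucose; times
#'   must lie on the 5-minute grid (missing rows are expanded to explicit
#'   `NA`s).
#' @param max_run longest gap (in readings) that is imputed.
#' @return list with `series` (imputed, full-grid data frame) and
#'   `gap_report` (one row per gap: subject_id, start_min, length, imputed).
#' @export
impute_gaps <- function(cgm, max_run = 5) {
  if (any(cgm$time_min %% GRID_MIN != 0))
    stopf("CGM timestamps are not on the %d-minute grid", GRID_MIN)
  out <- vector("list", 0L)
  gaps <- vector("list", 0L)
  for (sid in unique(cgm$subject_id)) {
    d <- cgm[cgm$subject_id == sid, ]
    if (anyDuplicated(d$time_min)) stopf("duplicate timestamps for subject %s", sid)
    grid <- seq(min(d$time_min), max(d$time_min), by = GRID_MIN)
    g <- rep(NA_real_, length(grid))
    g[match(d$time_min, grid)] <- d$glucose
    r <- rle(is.na(g))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      lo <- starts[k] - 1L
      hi <- ends[k] + 1L
      can <- len <= max_run && lo >= 1L && hi <= length(g)
      if (can) {
        g[starts[k]:ends[k]] <- g[lo] + (g[hi] - g[lo]) * seq_len(len) / (len + 1L)
      }
      gaps[[length(gaps) + 1L]] <- data.frame(
        subject_id = sid, start_min = grid[starts[k]], length = len,
        imputed = can, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(subject_id = sid, time_min = grid,
                                          glucose = g, stringsAsFactors = FALSE)
  }
  gap_report <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(subject_id = character(), start_min = integer(),
               length = integer(), imputed = logical())
  list(series = do.call(rbind, out), gap_report = gap_report)
}

#' Postprandial excursion from the meal-time baseline
#'
#' @param series full-grid glucose data frame for one subject (time_min,
#'   glucose).
#' @param meal_time meal time in minutes (on the grid).
#' @param horizons horizons in minutes.
#' @return named vector of Delta-G(t) = G(t) - G(0).
#' @export
compute_outcome <- function(series, meal_time, horizons = HORIZONS) {
  g <- series$glucose[match(meal_time + c(0L, horizons), series$time_min)]
  out <- g[-1] - g[1]
  names(out) <- paste0("dg_", horizons)
  out
}

#' Aggregate bolus insulin into the mediator
#'
#' Sums bolus units over the closed interval `window` (minutes relative to
#' the meal). No boluses means a mediator of exactly zero, a valid
#' observation.
#'
#' @param events event data frame (must contain bolus rows with `value`).
#' @param meal_time meal time in minutes.
#' @param window closed aggregation interval, default `c(-120, 60)`.
#' @return total bolus units (numeric scalar).
#' @export
aggregate_mediator <- function(events, meal_time, window = c(-120, 60)) {
  b <- events[events$event_type == "bolus", ]
  if (nrow(b) && any(b$value < 0)) stopf("negative bolus values in event log")
  sel <- b$time_min >= meal_time + window[1] & b$time_min <= meal_time + window[2]
  sum(b$value[sel])
}

channel_on_grid <- function(events, type, grid, locf = FALSE, fill = 0) {
  e <- events[events$event_type == type, ]
  v <- rep(NA_real_, length(grid))
  idx <- match(snap_to_grid(e$time_min), grid)
  ok <- !is.na(idx)
  v[idx[ok]] <- e$value[ok]
  if (locf) {
    obs <- !is.na(v)
    if (any(obs)) {
      filled <- cumsum(obs)
      v <- c(NA_real_, v[obs])[filled + 1L]
    }
  }
  v[is.na(v)] <- fill
  v
}

#' Build meal-centered analysis windows
#'
#' One candidate window per meal event. Candidates are excluded (with a
#' recorded reason) when the meal lies closer than `min_separation` minutes
#' to any other meal, when any glucose value in \[-120, +210\] is still
#' missing after imputation, when the window contains a CGM artifact
#' (implausible jump or out-of-range value), or when a bolus occurs strictly
#' after the mediator window but within the outcome span. Meals with missing
#' or non-positive carbohydrates are excluded rather than raising an error.
#'
#' @param cgm imputed full-grid CGM data frame (from [impute_gaps()]).
#' @param events event log data frame.
#' @param rules a [window_rules()] list.
#' @param subjects optional data frame (subject_id, cohort) supplying cohort
#'   labels; defaults to a single cohort `"all"`.
#' @return object of class `meal_windows`: list with `meta` (one row per kept
#'   window: window_id, subject_id, meal_time, meal_type, cohort, day, Z, M,
#'   G0, dg_60..dg_210), `pre` (kept-window array n x 24 x 5 with channels
#'   glucose, steps, basal, carbs, heart_rate), and `report` (an
#'   `exclusion_report`).
#' @export
build_windows <- function(cgm, events, rules = window_rules(), subjects = NULL) {
  n_pre <- rules$pre_min / GRID_MIN          # 24
  n_post <- rules$post_max / GRID_MIN        # 42
  channels <- c("glucose", "steps", "basal", "carbs", "heart_rate")
  meta_rows <- list()
  pre_mats <- list()
  excl <- list()

  for (sid in unique(cgm$subject_id)) {
    ser <- cgm[cgm$subject_id == sid, ]
    ev <- events[events$subject_id == sid, ]
    grid <- ser$time_min
    g <- ser$glucose
    meals <- ev[ev$event_type == "meal", ]
    if (!nrow(meals)) next
    meals$meal_time <- snap_to_grid(meals$time_min)
    meals <- meals[order(meals$meal_time), ]

    steps_g <- channel_on_grid(ev, "steps", grid)
    basal_g <- channel_on_grid(ev, "basal", grid, locf = TRUE)
    hr_g <- channel_on_grid(ev, "heart_rate", grid, locf = TRUE,
                            fill = stats::median(ev$value[ev$event_type == "heart_rate"],
                                                 na.rm = TRUE) %||% 72)
    hr_g[is.na(hr_g)] <- 72
    carbs_g <- rep(0, length(grid))
    mi <- match(meals$meal_time, grid)
    carbs_g[mi[!is.na(mi)]] <- meals$carbs[!is.na(mi)]
    boluses <- ev[ev$event_type == "bolus", ]
    if (nrow(boluses) && any(boluses$value < 0)) stopf("negative bolus values in event log")

    for (i in seq_len(nrow(meals))) {
      t0 <- meals$meal_time[i]
      reason <- "ok"
      carbs <- meals$carbs[i]
      others <- meals$meal_time[-i]
      if (is.na(carbs) || carbs <= 0) {
        reason <- "invalid_carbs"
      } else if (length(others) && any(abs(others - t0) < rules$min_separation)) {
        reason <- "overlap"
      } else {
        i0 <- match(t0, grid)
        idx <- if (is.na(i0)) NA else i0 + seq(-n_pre, n_post)
        if (anyNA(idx) || idx[1] < 1L || idx[length(idx)] > length(grid) ||
            sum(is.na(g[idx])) > rules$max_missing) {
          reason <- "missingness"
        } else {
          gw <- g[idx]
          jumps <- abs(diff(gw))
          if (any(jumps > rules$artifact_jump, na.rm = TRUE) ||
              any(gw < rules$glucose_range[1] | gw > rules$glucose_range[2], na.rm = TRUE)) {
            reason <- "artifact"
          } else if (nrow(boluses) &&
                     any(boluses$time_min > t0 + rules$mediator_window[2] &
                         boluses$time_min <= t0 + rules$post_max)) {
            reason <- "late_bolus"
          }
        }
      }
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = sid, meal_time = t0,
        meal_type = meals$meal_type[i] %||% NA_character_,
        kept = reason == "ok", reason = reason, stringsAsFactors = FALSE)
      if (reason != "ok") next

      i0 <- match(t0, grid)
      pre_idx <- i0 + seq(-n_pre, -1L)
      pm <- cbind(glucose = g[pre_idx], steps = steps_g[pre_idx],
                  basal = basal_g[pre_idx], carbs = carbs_g[pre_idx],
                  heart_rate = hr_g[pre_idx])
      dg <- compute_outcome(ser, t0, rules$horizons)
      M <- aggregate_mediator(ev, t0, rules$mediator_window)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        subject_id = sid, meal_time = t0, meal_type = meals$meal_type[i],
        day = t0 %/% DAY_MIN, Z = carbs, M = M, G0 = g[i0],
        t(dg), stringsAsFactors = FALSE)
      pre_mats[[length(pre_mats) + 1L]] <- pm
    }
  }

  report <- do.call(rbind, excl)
  rownames(report) <- NULL
  counts <- table(factor(report$reason,
                         levels = c("ok", "overlap", "missingness", "artifact",
                                    "late_bolus", "invalid_carbs")))
  n_kept <- length(meta_rows)
  meta <- if (n_kept) do.call(rbind, meta_rows) else NULL
  pre <- array(NA_real_, c(n_kept, n_pre, 5L),
               dimnames = list(NULL, NULL, channels))
  for (k in seq_len(n_kept)) pre[k, , ] <- pre_mats[[k]]
  if (n_kept) {
    meta$window_id <- seq_len(n_kept)
    cohorts <- if (is.null(subjects)) rep("all", n_kept) else
      subjects$cohort[match(meta$subject_id, subjects$subject_id)]
    meta$cohort <- cohorts
    rownames(meta) <- NULL
  }
  structure(list(meta = meta, pre = pre,
                 report = structure(list(windows = report, counts = counts),
                                    class = "exclusion_report")),
            class = "meal_windows")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Window exclusion report (candidates:", nrow(x$windows), ")\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.meal_windows <- function(x, ...) {
  n <- if (is.null(x$meta)) 0L else nrow(x$meta)
  cat(sprintf("meal_windows: %d kept of %d candidates\n", n, nrow(x$report$windows)))
  if (n && "split" %in% names(x$meta)) print(table(x$meta$split))
  invisible(x)
}

#' Chronological train/test split and channel standardization
#'
#' Per subject, the chronologically first `ceiling(train_fraction * n_days)`
#' distinct calendar days go to training, the remainder to test. Per-channel
#' mean/SD are computed on training windows only and applied to both splits.
#'
#' @param mw a `meal_windows` object.
#' @param train_fraction fraction of days assigned to training.
#' @return `mw` with `meta$split`, a standardized array `pre_std`, and a
#'   `scaler` element (per-channel mean/sd).
#' @export
split_and_standardize <- function(mw, train_fraction = 0.65) {
  meta <- mw$meta
  split <- rep("train", nrow(meta))
  for (sid in unique(meta$subject_id)) {
    sel <- meta$subject_id == sid
    days <- sort(unique(meta$day[sel]))
    if (length(days) < 2) {
      warnf("subject %s has < 2 distinct days; all windows assigned to train", sid)
      next
    }
    n_train <- ceiling(train_fraction * length(days))
    split[sel & !(meta$day %in% days[seq_len(n_train)])] <- "test"
  }
  meta$split <- split
  tr <- which(split == "train")
  mu <- apply(mw$pre[tr, , , drop = FALSE], 3, mean)
  sdv <- apply(mw$pre[tr, , , drop = FALSE], 3, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  pre_std <- mw$pre
  for (c in seq_len(dim(mw$pre)[3]))
    pre_std[, , c] <- (mw$pre[, , c] - mu[c]) / sdv[c]
  mw$meta <- meta
  mw$pre_std <- pre_std
  mw$scaler <- list(mean = mu, sd = sdv)
  mw
}

#' Meal-type treatment anchors and dose contrasts
#'
#' The anchor z0 for each meal type is the sample median of train-split
#' carbohydrates within that type (even counts: mean of the middle pair);
#' contrasts are (z0, z0 + dose).
#'
#' @param mw a split `meal_windows` object.
#' @param doses dose contrasts in grams.
#' @return data frame with meal_type, z0, dose_g, z1 and per-type train n.
#' @export
meal_type_anchors <- function(mw, doses = c(15, 30, 45)) {
  meta <- mw$meta
  tr <- meta[meta$split == "train", ]
  out <- list()
  for (mt in unique(meta$meal_type)) {
    z <- tr$Z[tr$meal_type == mt]
    if (!length(z)) {
      warnf("meal type %s has no training windows; stratum dropped", mt)
      next
    }
    z0 <- stats::median(z)
    out[[mt]] <- data.frame(meal_type = mt, z0 = z0, dose_g = doses,
                            z1 = z0 + doses, n_train = length(z),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write windows and the exclusion report as flat CSVs
#'
#' One row per kept window: metadata, Z, M, G(0), the six Delta-G columns and
#' the 120 flattened pre-matrix columns.
#'
#' @param mw a `meal_windows` object.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_windows <- function(mw, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- matrix(mw$pre, nrow = dim(mw$pre)[1])
  colnames(flat) <- paste0("pre_",
                           rep(dimnames(mw$pre)[[3]], each = dim(mw$pre)[2]), "_",
                           rep(seq_len(dim(mw$pre)[2]), times = dim(mw$pre)[3]))
  p1 <- file.path(dir, "windows.csv")
  p2 <- file.path(dir, "exclusions.csv")
  utils::write.csv(cbind(mw$meta, flat), p1, row.names = FALSE)
  utils::write.csv(mw$report$windows, p2, row.names = FALSE)
  invisible(c(windows = p1, exclusions = p2))
}
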