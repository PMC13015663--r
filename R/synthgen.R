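## Synthetic CGM cohort generator.
##
## The generator realizes the structural model the mediation analysis assumes:
## per-meal latent confounders U drive the pre-meal trajectory, the
## carbohydrate treatment Z, the (left-censored) bolus mediator M, and the
## postprandial excursion Delta-G at six horizons. Because the structural
## coefficients are known, oracle ACME/ADE/TE values are available by direct
## simulation of potential outcomes, which is what acceptance tests compare
## pipeline estimates against.

default_meal_types <- function() {
  data.frame(
    meal_type = c("breakfast", "lunch", "dinner", "snack"),
    carb_mean = c(46.5, 56.5, 62.8, 26.6),
    carb_sd   = c(40.4, 37.5, 44.0, 14.7),
    hour      = c(7.5, 12.0, 20.5, 16.25),
    prob      = c(0.80, 0.90, 0.80, 0.70),
    stringsAsFactors = FALSE
  )
}

default_outcome_coeffs <- function(conf_dim = 4) {
  ## horizon profile peaks at 120 min, mirroring postprandial kinetics
  shape <- c(0.5, 0.8, 1.0, 0.85, 0.7, 0.55)
  list(
    beta0 = c(25, 35, 40, 35, 28, 22),                 # mg/dL baseline excursion
    beta1 = c(0.23, 0.43, 0.49, 0.38, 0.39, 0.39),     # mg/dL per gram (direct)
    beta2 = -c(1.5, 3.0, 3.6, 2.7, 2.6, 2.1),          # mg/dL per unit insulin
    beta3 = outer(c(5, 4, -4, 3)[seq_len(conf_dim)], shape),  # confounder loadings
    sigma_y = c(12, 14, 16, 16, 15, 14),               # mg/dL residual SD
    kappa = 0                                          # scale-heterogeneity knob
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions: twelve subjects monitored for eight
#' weeks, four meal types with the reported carbohydrate moments, a bolus
#' mediator with a point mass at zero (~12-13% of meals), and horizon-varying
#' outcome coefficients peaking at 120 minutes.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param days_per_subject monitored days per subject.
#' @param meal_types data frame with columns `meal_type`, `carb_mean`,
#'   `carb_sd` (grams), `hour` (typical meal hour), `prob` (daily occurrence
#'   probability).
#' @param carb_floor lower truncation of carbohydrate grams (avoids
#'   non-physical near-zero meals).
#' @param conf_dim number of latent confounder factors per meal.
#' @param conf_to_carbs correlation between the treatment and the (unit
#'   variance) confounder index; controls confounding strength.
#' @param conf_signal_scale multiplier on the amplitude with which the
#'   confounders imprint on the pre-meal glucose / heart-rate channels
#'   (how visible the confounders are to the encoder).
#' @param mediator_coeffs list `alpha0` (intercept, units), `alpha1` (units
#'   per gram), `alpha2` (confounder loadings), `sigma_m` (latent SD, units).
#' @param outcome_coeffs list `beta0`, `beta1`, `beta2`, `beta3`, `sigma_y`
#'   per horizon, plus `kappa`: residual SD is multiplied by `(1 + kappa * Z)`
#'   so positive `kappa` creates treatment effects that grow with the outcome
#'   quantile.
#' @param subject_intercept_sd SD of the subject-level random intercept
#'   (mg/dL).
#' @param missingness list `gap_prob_per_day`, `max_gap` (CGM gap geometry).
#' @param late_bolus_prob probability that a meal receives an extra correction
#'   bolus after the mediator window (such windows are excluded downstream).
#' @param horizons outcome horizons in minutes; must be the canonical grid
#'   `c(60, 90, 120, 150, 180, 210)`.
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 12,
                             days_per_subject = 56,
                             meal_types = default_meal_types(),
                             carb_floor = 5,
                             conf_dim = 4,
                             conf_to_carbs = 0.35,
                             conf_signal_scale = 1,
                             mediator_coeffs = list(alpha0 = 0, alpha1 = 0.1,
                                                    alpha2 = rep(0.5, 4), sigma_m = 2),
                             outcome_coeffs = default_outcome_coeffs(conf_dim),
                             subject_intercept_sd = 8,
                             missingness = list(gap_prob_per_day = 0.25, max_gap = 10),
                             late_bolus_prob = 0.03,
                             horizons = HORIZONS,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    days_per_subject = as.integer(days_per_subject),
    meal_types = meal_types,
    carb_floor = carb_floor,
    conf_dim = as.integer(conf_dim),
    conf_to_carbs = conf_to_carbs,
    conf_signal_scale = conf_signal_scale,
    mediator_coeffs = mediator_coeffs,
    outcome_coeffs = outcome_coeffs,
    subject_intercept_sd = subject_intercept_sd,
    missingness = missingness,
    late_bolus_prob = late_bolus_prob,
    horizons = as.integer(horizons),
    meal_jitter_sd = 25,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 2) stopf("n_subjects must be >= 2, got %d", cfg$n_subjects)
  if (!identical(cfg$horizons, HORIZONS))
    stopf("horizons must equal {60, 90, 120, 150, 180, 210} minutes")
  mc <- cfg$mediator_coeffs
  oc <- cfg$outcome_coeffs
  sds <- c(cfg$meal_types$carb_sd, mc$sigma_m, oc$sigma_y, cfg$subject_intercept_sd)
  if (any(sds <= 0)) stopf("all SDs in the generator config must be > 0")
  if (length(mc$alpha2) != cfg$conf_dim)
    stopf("alpha2 must have length conf_dim = %d", cfg$conf_dim)
  if (!all(dim(oc$beta3) == c(cfg$conf_dim, 6)))
    stopf("beta3 must be a %d x 6 matrix", cfg$conf_dim)
  for (nm in c("beta0", "beta1", "beta2", "sigma_y"))
    if (length(oc[[nm]]) != 6) stopf("%s must have length 6", nm)
  frac <- schedule_overlap_fraction(cfg)
  if (frac > 0.25)
    stopf("meal schedule places %.0f%% of meals < 90 min apart; most windows would be excluded",
          100 * frac)
  invisible(cfg)
}

## expected fraction of meals closer than 90 min to a neighbour, by simulating
## the daily schedule (used only to reject degenerate configs)
schedule_overlap_fraction <- function(cfg, n_days = 200) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 999))
  n_close <- 0L
  n_tot <- 0L
  for (d in seq_len(n_days)) {
    tm <- simulate_day_schedule(cfg)$time
    if (length(tm) == 0) next
    tm <- sort(tm)
    n_tot <- n_tot + length(tm)
    if (length(tm) > 1) {
      gaps <- diff(tm)
      close <- c(gaps < 90, FALSE) | c(FALSE, gaps < 90)
      n_close <- n_close + sum(close)
    }
  }
  if (n_tot == 0) 0 else n_close / n_tot
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

simulate_day_schedule <- function(cfg) {
  mt <- cfg$meal_types
  occurs <- stats::runif(nrow(mt)) < mt$prob
  if (!any(occurs)) return(data.frame(meal_type = character(), time = integer()))
  tm <- snap_to_grid(mt$hour[occurs] * 60 + stats::rnorm(sum(occurs), 0, cfg$meal_jitter_sd))
  tm <- pmin(pmax(tm, 0L), DAY_MIN - GRID_MIN)
  data.frame(meal_type = mt$meal_type[occurs], time = tm, stringsAsFactors = FALSE)
}

## smooth pre-meal bump encoding the latent confounders:
##  U1 -> two-hour trend into the meal, U2 -> mid-window bulge,
##  U4 -> level offset over the whole window (cancels in Delta-G).
## U3 is carried by the heart-rate channel instead of glucose.
premeal_bump <- function(rel_min, U, scale = 1) {
  scale * (12 * U[1] * (-rel_min / 120) + 10 * U[2] * sin(pi * (-rel_min) / 120))
}

#' Generate a synthetic CGM cohort
#'
#' Produces a per-subject 5-minute glucose series with injected gaps, an event
#' log (meals, boluses, basal, heart rate, steps), and the per-meal latent
#' confounders (withheld from the analysis pipeline; exposed for testing).
#'
#' @param config a [generator_config()].
#' @return an object of class `synthetic_cohort`: a list with elements `cgm`
#'   (subject_id, time_min, glucose), `events` (subject_id, time_min,
#'   event_type, value, meal_type, carbs), `latents` (one row per meal with
#'   the confounder vector, treatment, mediator and structural outcomes),
#'   `subjects`, and `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  set.seed(derive_seed(cfg$seed, 1))
  mc <- cfg$mediator_coeffs
  oc <- cfg$outcome_coeffs
  h <- cfg$horizons
  a_dir <- rep(1 / sqrt(cfg$conf_dim), cfg$conf_dim)  # unit-norm loading of U on Z
  rho <- cfg$conf_to_carbs

  n_cohort1 <- ceiling(cfg$n_subjects / 2)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(cfg$n_subjects)),
    cohort = rep(c("2018", "2020"), c(n_cohort1, cfg$n_subjects - n_cohort1)),
    stringsAsFactors = FALSE
  )
  subjects$baseline <- 150 + ifelse(subjects$cohort == "2018", 5, -7) +
    stats::rnorm(cfg$n_subjects, 0, 12)
  subjects$b_subject <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_intercept_sd)

  n_grid_day <- DAY_MIN / GRID_MIN
  cgm_list <- vector("list", cfg$n_subjects)
  event_list <- vector("list", cfg$n_subjects)
  latent_list <- vector("list", cfg$n_subjects)
  mt_tab <- cfg$meal_types

  for (s in seq_len(cfg$n_subjects)) {
    n_grid <- n_grid_day * cfg$days_per_subject
    time_min <- seq(0L, by = GRID_MIN, length.out = n_grid)

    ## slow AR(1) physiological drift + measurement noise around baseline
    drift <- stats::filter(stats::rnorm(n_grid, 0, 6 * sqrt(1 - 0.97^2)), 0.97,
                           method = "recursive")
    glucose <- subjects$baseline[s] + as.numeric(drift) + stats::rnorm(n_grid, 0, 3)

    hr <- 72 + as.numeric(stats::filter(stats::rnorm(n_grid, 0, 4 * sqrt(1 - 0.9^2)),
                                        0.9, method = "recursive"))
    steps <- stats::rpois(n_grid, 1.2) * stats::rbinom(n_grid, 1, 0.3) * 25

    ## daily meal schedule
    meal_rows <- list()
    for (d in seq_len(cfg$days_per_subject)) {
      sch <- simulate_day_schedule(cfg)
      if (nrow(sch)) {
        sch$time <- sch$time + (d - 1L) * DAY_MIN
        meal_rows[[length(meal_rows) + 1L]] <- sch
      }
    }
    meals <- do.call(rbind, meal_rows)
    meals <- meals[order(meals$time), , drop = FALSE]
    n_meals <- nrow(meals)

    ## structural draws per meal
    U <- matrix(stats::rnorm(n_meals * cfg$conf_dim), n_meals, cfg$conf_dim)
    idx_type <- match(meals$meal_type, mt_tab$meal_type)
    z_shock <- rho * as.numeric(U %*% a_dir) +
      sqrt(1 - rho^2) * stats::rnorm(n_meals)
    Z <- pmax(cfg$carb_floor, mt_tab$carb_mean[idx_type] + mt_tab$carb_sd[idx_type] * z_shock)
    M_lat <- mc$alpha0 + mc$alpha1 * Z + as.numeric(U %*% mc$alpha2) +
      stats::rnorm(n_meals, 0, mc$sigma_m)
    M <- pmax(0, M_lat)
    eps_y <- matrix(stats::rnorm(n_meals * 6), n_meals, 6)
    dg <- matrix(0, n_meals, 6)
    for (j in 1:6) {
      dg[, j] <- oc$beta0[j] + oc$beta1[j] * Z + oc$beta2[j] * M +
        as.numeric(U %*% oc$beta3[, j]) + subjects$b_subject[s] +
        oc$sigma_y[j] * (1 + oc$kappa * Z) * eps_y[, j]
    }

    ## realize each meal as an additive bump on the glucose / HR series
    rel_pre <- seq(-120L, -GRID_MIN, by = GRID_MIN)
    rel_post <- seq(GRID_MIN, 210L, by = GRID_MIN)
    rel_decay <- seq(215L, 270L, by = GRID_MIN)
    for (i in seq_len(n_meals)) {
      t0 <- meals$time[i]
      i0 <- t0 / GRID_MIN + 1L
      lev <- cfg$conf_signal_scale * 15 * U[i, min(4, cfg$conf_dim)]
      pre <- premeal_bump(rel_pre, U[i, ], cfg$conf_signal_scale) + lev
      spl <- stats::splinefun(c(0, h), c(0, dg[i, ]), method = "monoH.FC")
      post <- spl(rel_post) + lev +
        ifelse(rel_post %in% h, 0, stats::rnorm(length(rel_post), 0, 2))
      end_val <- dg[i, 6] + lev
      decay <- end_val * (1 - (rel_decay - 210) / 60)
      bump <- c(pre, lev, post, decay)
      idx <- i0 + seq(-24L, length(bump) - 25L)
      ok <- idx >= 1L & idx <= n_grid
      glucose[idx[ok]] <- glucose[idx[ok]] + bump[ok]

      ## heart-rate carries U3 around the meal, plus a postprandial rise
      hr_idx <- i0 + seq(-24L, 12L)
      okh <- hr_idx >= 1L & hr_idx <= n_grid
      hr_bump <- c(rep(cfg$conf_signal_scale * 8 * U[i, min(3, cfg$conf_dim)], 25), rep(0, 12)) +
        c(rep(0, 25), rep(10, 12))
      hr[hr_idx[okh]] <- hr[hr_idx[okh]] + hr_bump[okh]
    }
    glucose <- pmin(598, pmax(22, glucose))

    ## CGM gaps: at most one per day, short lengths favoured
    miss <- rep(FALSE, n_grid)
    gp <- cfg$missingness$gap_prob_per_day
    mg <- cfg$missingness$max_gap
    for (d in seq_len(cfg$days_per_subject)) {
      if (stats::runif(1) < gp) {
        len <- sample.int(mg, 1, prob = 0.65^(seq_len(mg) - 1))
        start <- (d - 1L) * n_grid_day + sample.int(n_grid_day - len, 1)
        miss[start + seq_len(len) - 1L] <- TRUE
      }
    }
    glucose[miss] <- NA_real_

    sid <- subjects$subject_id[s]
    cgm_list[[s]] <- data.frame(subject_id = sid, time_min = time_min,
                                glucose = round(glucose, 1), stringsAsFactors = FALSE)

    ## event log
    ev <- list()
    ev$meal <- data.frame(subject_id = sid, time_min = meals$time, event_type = "meal",
                          value = round(Z, 1), meal_type = meals$meal_type,
                          carbs = round(Z, 1), stringsAsFactors = FALSE)
    has_bolus <- M > 0
    if (any(has_bolus)) {
      off <- sample(seq(-15L, 15L, by = GRID_MIN), sum(has_bolus), replace = TRUE)
      ev$bolus <- data.frame(subject_id = sid, time_min = meals$time[has_bolus] + off,
                             event_type = "bolus", value = round(M[has_bolus], 3),
                             meal_type = NA_character_, carbs = NA_real_,
                             stringsAsFactors = FALSE)
    }
    late <- stats::runif(n_meals) < cfg$late_bolus_prob
    if (any(late)) {
      off <- sample(seq(75L, 150L, by = GRID_MIN), sum(late), replace = TRUE)
      ev$late <- data.frame(subject_id = sid, time_min = meals$time[late] + off,
                            event_type = "bolus",
                            value = round(stats::runif(sum(late), 0.5, 2), 2),
                            meal_type = NA_character_, carbs = NA_real_,
                            stringsAsFactors = FALSE)
    }
    ev$basal <- data.frame(subject_id = sid,
                           time_min = (seq_len(cfg$days_per_subject) - 1L) * DAY_MIN,
                           event_type = "basal",
                           value = round(pmax(0.5, stats::rnorm(cfg$days_per_subject, 0.9, 0.1)), 2),
                           meal_type = NA_character_, carbs = NA_real_,
                           stringsAsFactors = FALSE)
    ev$hr <- data.frame(subject_id = sid, time_min = time_min, event_type = "heart_rate",
                        value = round(hr, 1), meal_type = NA_character_, carbs = NA_real_,
                        stringsAsFactors = FALSE)
    ev$steps <- data.frame(subject_id = sid, time_min = time_min, event_type = "steps",
                           value = steps, meal_type = NA_character_, carbs = NA_real_,
                           stringsAsFactors = FALSE)
    event_list[[s]] <- do.call(rbind, ev)

    lat <- data.frame(subject_id = sid, time_min = meals$time, meal_type = meals$meal_type,
                      stringsAsFactors = FALSE)
    colnames(U) <- paste0("U", seq_len(cfg$conf_dim))
    lat <- cbind(lat, U)
    lat$Z <- Z
    lat$M_latent <- M_lat
    lat$M <- M
    lat$b_subject <- subjects$b_subject[s]
    dgn <- dg
    colnames(dgn) <- paste0("dg_", h)
    latent_list[[s]] <- cbind(lat, dgn)
  }

  events <- do.call(rbind, event_list)
  events <- events[order(events$subject_id, events$time_min, events$event_type), ]
  rownames(events) <- NULL
  out <- list(cgm = do.call(rbind, cgm_list), events = events,
              latents = do.call(rbind, latent_list), subjects = subjects, config = cfg)
  rownames(out$cgm) <- NULL
  rownames(out$latents) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CGM cohort: %d subjects x %d days, %d meals, %d CGM readings (%.1f%% missing)\n",
              x$config$n_subjects, x$config$days_per_subject, nrow(x$latents),
              nrow(x$cgm), 100 * mean(is.na(x$cgm$glucose))))
  cat(sprintf("Zero-bolus meals: %.1f%%\n", 100 * mean(x$latents$M == 0)))
  invisible(x)
}

#' Draw meals directly from the structural model (no time series)
#'
#' Tabular draws of (meal type, confounders U, treatment Z, mediator M,
#' outcomes Delta-G) from the same structural equations that
#' [generate_cohort()] realizes as CGM series. Used by the simulation oracle
#' and by tests that isolate the statistical machinery from preprocessing.
#'
#' @param config a [generator_config()].
#' @param n number of meals.
#' @param seed integer seed.
#' @param n_subjects optional; if positive, meals are assigned round-robin to
#'   this many subjects and subject random intercepts are added.
#' @return data frame with columns meal_type, U*, Z, M, dg_60..dg_210 (and
#'   subject_id when `n_subjects > 0`).
#' @export
structural_sample <- function(config, n, seed = 1L, n_subjects = 0L) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 11) + as.integer(seed))
  mc <- cfg$mediator_coeffs
  oc <- cfg$outcome_coeffs
  mt <- cfg$meal_types
  a_dir <- rep(1 / sqrt(cfg$conf_dim), cfg$conf_dim)
  rho <- cfg$conf_to_carbs

  idx_type <- sample.int(nrow(mt), n, replace = TRUE, prob = mt$prob)
  U <- matrix(stats::rnorm(n * cfg$conf_dim), n, cfg$conf_dim)
  z_shock <- rho * as.numeric(U %*% a_dir) + sqrt(1 - rho^2) * stats::rnorm(n)
  Z <- pmax(cfg$carb_floor, mt$carb_mean[idx_type] + mt$carb_sd[idx_type] * z_shock)
  M <- pmax(0, mc$alpha0 + mc$alpha1 * Z + as.numeric(U %*% mc$alpha2) +
              stats::rnorm(n, 0, mc$sigma_m))
  b <- rep(0, n)
  sid <- NULL
  if (n_subjects > 0) {
    sid <- sprintf("S%02d", rep_len(seq_len(n_subjects), n))
    bs <- stats::rnorm(n_subjects, 0, cfg$subject_intercept_sd)
    b <- bs[rep_len(seq_len(n_subjects), n)]
  }
  dg <- matrix(0, n, 6)
  for (j in 1:6) {
    dg[, j] <- oc$beta0[j] + oc$beta1[j] * Z + oc$beta2[j] * M +
      as.numeric(U %*% oc$beta3[, j]) + b +
      oc$sigma_y[j] * (1 + oc$kappa * Z) * stats::rnorm(n)
  }
  colnames(dg) <- paste0("dg_", cfg$horizons)
  colnames(U) <- paste0("U", seq_len(cfg$conf_dim))
  out <- data.frame(meal_type = mt$meal_type[idx_type], stringsAsFactors = FALSE)
  if (!is.null(sid)) out$subject_id <- sid
  cbind(out, U, Z = Z, M = M, dg)
}

#' Oracle mediation effects implied by the generator
#'
#' Computes ground-truth ACME, ADE and TE per (horizon, dose) by brute-force
#' simulation of potential outcomes: draw confounders, set the treatment
#' anchors at the meal-type median, push both anchors through the censored
#' mediator model with common latent noise, and average the outcome-mean
#' contrasts. ACME and ADE are averaged over the two treatment anchors.
#'
#' @param config a [generator_config()].
#' @param dose numeric vector of carbohydrate dose contrasts (grams).
#' @param n_oracle Monte Carlo draws (>= 1e5).
#' @param seed integer seed.
#' @return data frame of class `synthetic_truth` with columns horizon_min,
#'   dose_g, acme, ade, te and their Monte Carlo standard errors.
#' @export
oracle_effects <- function(config, dose = c(15, 30, 45), n_oracle = 1e5, seed = 1L) {
  cfg <- config
  if (n_oracle < 1e5) stopf("n_oracle must be >= 1e5, got %g", n_oracle)
  set.seed(derive_seed(cfg$seed, 21) + as.integer(seed))
  mc <- cfg$mediator_coeffs
  oc <- cfg$outcome_coeffs
  mt <- cfg$meal_types
  n <- as.integer(n_oracle)

  ## meal-type mixture; anchor z0 at the meal-type median carbs
  idx_type <- sample.int(nrow(mt), n, replace = TRUE, prob = mt$prob)
  z0 <- pmax(cfg$carb_floor, mt$carb_mean[idx_type])  # median = mean (symmetric)
  U <- matrix(stats::rnorm(n * cfg$conf_dim), n, cfg$conf_dim)
  uM <- as.numeric(U %*% mc$alpha2)
  epsM <- stats::rnorm(n, 0, mc$sigma_m)  # common across anchors and doses

  rows <- list()
  for (d in dose) {
    z1 <- z0 + d
    M0 <- pmax(0, mc$alpha0 + mc$alpha1 * z0 + uM + epsM)
    M1 <- pmax(0, mc$alpha0 + mc$alpha1 * z1 + uM + epsM)
    for (j in seq_along(cfg$horizons)) {
      ## E[Y(z, m) | U] is linear; noise and subject intercepts are mean zero
      acme_i <- oc$beta2[j] * (M1 - M0)          # identical at both anchors
      ade_i <- rep(oc$beta1[j] * d, n)           # deterministic (no interaction)
      te_i <- acme_i + ade_i
      rows[[length(rows) + 1L]] <- data.frame(
        horizon_min = cfg$horizons[j], dose_g = d,
        acme = mean(acme_i), ade = mean(ade_i), te = mean(te_i),
        acme_se = stats::sd(acme_i) / sqrt(n),
        ade_se = stats::sd(ade_i) / sqrt(n),
        te_se = stats::sd(te_i) / sqrt(n))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synthetic_truth", "data.frame")
  out
}

#' Write a synthetic cohort as the tidy CSV pair
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths of `cgm.csv` and `events.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cgm <- cohort$cgm
  cgm$timestamp <- minutes_to_timestamp(cgm$time_min)
  ev <- cohort$events
  ev$timestamp <- minutes_to_timestamp(ev$time_min)
  p1 <- file.path(dir, "cgm.csv")
  p2 <- file.path(dir, "events.csv")
  utils::write.csv(cgm[, c("subject_id", "timestamp", "glucose")], p1, row.names = FALSE)
  utils::write.csv(ev[, c("subject_id", "timestamp", "event_type", "value", "meal_type", "carbs")],
                   p2, row.names = FALSE)
  invisible(c(cgm = p1, events = p2))
}

#' Read the tidy CSV pair back into cohort form
#'
#' @param cgm_path path to the CGM series CSV (subject, timestamp, glucose).
#' @param events_path path to the event log CSV.
#' @return a list with `cgm` and `events` data frames using integer
#'   `time_min` on the 5-minute grid.
#' @export
read_cohort <- function(cgm_path, events_path) {
  cgm <- utils::read.csv(cgm_path, stringsAsFactors = FALSE)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  cgm$time_min <- timestamp_to_minutes(cgm$timestamp)
  ev$time_min <- timestamp_to_minutes(ev$timestamp)
  list(cgm = cgm[, c("subject_id", "time_min", "glucose")],
       events = ev[, c("subject_id", "time_min", "event_type", "value", "meal_type", "carbs")])
}

#' Write oracle truth as a long CSV keyed by (horizon_min, dose_g, effect)
#'
#' @param truth a `synthetic_truth` data frame from [oracle_effects()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  long <- do.call(rbind, lapply(c("acme", "ade", "te"), function(e) {
    data.frame(horizon_min = truth$horizon_min, dose_g = truth$dose_g,
               effect = toupper(e), value = truth[[e]],
               mc_se = truth[[paste0(e, "_se")]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
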