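## Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

## a small cohort with windows, used by several module tests
small_windows <- function() {
  cached("small_windows", {
    cfg <- generator_config(n_subjects = 6, days_per_subject = 14, seed = 42)
    co <- generate_cohort(cfg)
    imp <- impute_gaps(co$cgm)
    mw <- build_windows(imp$series, co$events, subjects = co$subjects)
    mw <- split_and_standardize(mw)
    list(cfg = cfg, cohort = co, mw = mw)
  })
}

## tiny encoder configuration used by gradient and determinism tests
tiny_clae_config <- function(epochs = 2, ...) {
  clae_config(conv_filters = c(4, 6, 8), hidden_basis = 4,
              dropout = 0, input_noise_sd = 0, epochs = epochs, seed = 1, ...)
}

## a crafted single-subject series + event log with known exclusion outcome:
## 10 meals, one overlapping triple (2 overlap pairs -> 3 exclusions), one
## window with a 6-reading gap, one late bolus, 5 survivors
crafted_fixture <- function() {
  grid <- seq(0L, 4 * 1440L - 5L, by = 5L)
  set.seed(7)
  glucose <- 140 + 10 * sin(grid / 300) + rnorm(length(grid), 0, 2)
  ## meal times (minutes): days 0-3, all pairwise gaps >= 90 except the triple
  meal_times <- c(450, 720, 1100,               # day 0: isolated
                  1440 + c(450, 530, 610),      # day 1: chain, 80-min gaps
                  2880 + c(450, 900),           # day 2: isolated + gap window
                  4320 + c(450, 900))           # day 3: isolated + late bolus
  ## 6-reading gap inside the pre-window of the day-2 900 meal
  gap_idx <- match(2880 + 900 - 60, grid) + 0:5
  glucose[gap_idx] <- NA
  cgm <- data.frame(subject_id = "F01", time_min = grid, glucose = glucose)
  events <- data.frame(
    subject_id = "F01",
    time_min = c(meal_times, 4320 + 900 + 90),
    event_type = c(rep("meal", 10), "bolus"),
    value = c(rep(50, 10), 2),
    meal_type = c(rep(c("breakfast", "lunch", "dinner"), length.out = 10), NA),
    carbs = c(rep(50, 10), NA),
    stringsAsFactors = FALSE)
  list(cgm = cgm, events = events)
}
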