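test_that("short gaps are linearly interpolated, long gaps preserved", {
  cgm <- data.frame(subject_id = "A", time_min = seq(0, 95, 5),
                    glucose = c(100, NA, 110, rep(120, 5), NA, NA, NA, NA, NA, NA,
                                130, rep(125, 5)))
  out <- impute_gaps(cgm)
  g <- out$series$glucose
  expect_equal(g[2], 105)                       # linear midpoint
  expect_true(all(is.na(g[9:14])))              # run of exactly 6 stays missing
  expect_equal(out$gap_report$length, c(1, 6))
  expect_equal(out$gap_report$imputed, c(TRUE, FALSE))
  ## idempotence and identity
  again <- impute_gaps(out$series)
  expect_identical(again$series$glucose, g)
  full <- data.frame(subject_id = "A", time_min = seq(0, 45, 5), glucose = 100:109)
  expect_identical(impute_gaps(full)$series$glucose, as.numeric(100:109))
  bad <- data.frame(subject_id = "A", time_min = c(0, 5, 12), glucose = 1:3)
  expect_error(impute_gaps(bad), "grid")
})

test_that("crafted fixture yields exactly 5 surviving windows with expected reasons", {
  fx <- crafted_fixture()
  imp <- impute_gaps(fx$cgm)
  mw <- build_windows(imp$series, fx$events)
  counts <- mw$report$counts
  expect_equal(unname(counts[["ok"]]), 5)
  expect_equal(unname(counts[["overlap"]]), 3)
  expect_equal(unname(counts[["missingness"]]), 1)
  expect_equal(unname(counts[["late_bolus"]]), 1)
  expect_equal(unname(counts[["artifact"]]), 0)
  expect_equal(sum(counts), nrow(mw$report$windows))     # reasons partition
  expect_equal(dim(mw$pre), c(5L, 24L, 5L))
  ## rerunning is byte-identical
  mw2 <- build_windows(imp$series, fx$events)
  expect_identical(mw$report$windows, mw2$report$windows)
  expect_identical(mw$meta, mw2$meta)
})

test_that("zero/missing carbs and artifacts are excluded with reasons, not errors", {
  fx <- crafted_fixture()
  ev <- fx$events
  ev$carbs[1] <- 0
  ev$carbs[2] <- NA
  imp <- impute_gaps(fx$cgm)
  mw <- build_windows(imp$series, ev)
  expect_equal(unname(mw$report$counts[["invalid_carbs"]]), 2)
  ## a 60 mg/dL jump inside a kept window flags an artifact
  cg <- imp$series
  i <- match(1100 + 60, cg$time_min)
  cg$glucose[i] <- cg$glucose[i] + 60
  mw2 <- build_windows(cg, fx$events)
  expect_equal(unname(mw2$report$counts[["artifact"]]), 1)
  expect_error(
    aggregate_mediator(data.frame(subject_id = "A", time_min = 0,
                                  event_type = "bolus", value = -1),
                       meal_time = 0),
    "negative")
})

test_that("outcome and mediator definitions follow the window conventions", {
  ser <- data.frame(subject_id = "A",
                    time_min = seq(0, 400, 5),
                    glucose = 150)
  ser$glucose[ser$time_min == 120 + 120] <- 185   # meal at 120
  dg <- compute_outcome(ser, meal_time = 120)
  expect_equal(unname(dg["dg_120"]), 35)
  expect_equal(unname(dg["dg_60"]), 0)
  flat <- compute_outcome(data.frame(subject_id = "A", time_min = seq(0, 400, 5),
                                     glucose = 150), 120)
  expect_true(all(flat == 0))
  ser2 <- ser
  ser2$glucose <- 180
  ser2$glucose[ser2$time_min == 180] <- 160
  expect_equal(unname(compute_outcome(ser2, 120)["dg_60"]), -20)

  ev <- data.frame(subject_id = "A",
                   time_min = c(90, 135, 240, 0),
                   event_type = "bolus",
                   value = c(2, 3, 1.5, 4))
  expect_equal(aggregate_mediator(ev, meal_time = 120), 2 + 3 + 4)  # -120 closed
  expect_equal(aggregate_mediator(ev[3, ], meal_time = 120), 0)     # after +60
})

test_that("chronological split and train-only standardization behave", {
  mw <- small_windows()$mw
  meta <- mw$meta
  for (sid in unique(meta$subject_id)) {
    d <- meta[meta$subject_id == sid, ]
    days <- sort(unique(d$day))
    n_train_days <- ceiling(0.65 * length(days))
    expect_setequal(unique(d$day[d$split == "train"]), days[seq_len(n_train_days)])
    expect_true(all(d$day[d$split == "test"] > max(days[seq_len(n_train_days)])))
  }
  ## 20 distinct days -> 13 train days
  expect_equal(ceiling(0.65 * 20), 13)
  tr <- meta$split == "train"
  for (ch in 1:5) {
    v <- as.numeric(mw$pre_std[tr, , ch])
    if (sd(v) == 0) next   # a channel can be degenerate (no events in-window)
    expect_lt(abs(mean(v)), 1e-8)
    expect_equal(sd(v), 1, tolerance = 1e-6)
  }
  ## single-day subject goes wholly to train, with a warning
  fx <- crafted_fixture()
  one <- fx$cgm[fx$cgm$time_min < 1440, ]
  mw1 <- build_windows(impute_gaps(one)$series,
                       fx$events[fx$events$time_min < 1200, ])
  expect_warning(s1 <- split_and_standardize(mw1), "train")
  expect_true(all(s1$meta$split == "train"))
})

test_that("meal-type anchors use train medians and the stated dose contrasts", {
  mw <- small_windows()$mw
  fake <- mw
  fake$meta <- data.frame(
    subject_id = "A", meal_type = rep(c("dinner", "lunch"), c(3, 2)),
    Z = c(40, 60, 80, 40, 80), split = "train")
  an <- meal_type_anchors(fake, doses = c(15, 30, 45))
  expect_equal(an$z0[an$meal_type == "dinner"], rep(60, 3))
  expect_equal(an$z1[an$meal_type == "dinner"], c(75, 90, 105))
  expect_equal(an$z0[an$meal_type == "lunch"], rep(60, 3))  # even-count median
  an2 <- meal_type_anchors(mw)
  expect_gt(length(unique(an2$z0)), 1)  # types with different carbs differ
})

test_that("windows CSV export is flat and complete", {
  mw <- small_windows()$mw
  dir <- withr::local_tempdir()
  paths <- write_windows(mw, dir)
  wide <- read.csv(paths["windows"])
  expect_equal(nrow(wide), nrow(mw$meta))
  expect_equal(sum(grepl("^pre_", names(wide))), 120)
  expect_true(all(c("Z", "M", "G0", paste0("dg_", c(60, 90, 120, 150, 180, 210)))
                  %in% names(wide)))
  rep <- read.csv(paths["exclusions"])
  expect_equal(nrow(rep), nrow(mw$report$windows))
})
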