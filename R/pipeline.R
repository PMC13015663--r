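## End-to-end orchestration: generate or ingest a cohort, build windows,
## train the encoder, reduce to principal components, estimate balancing
## weights, run the stratified mediation analysis, and report. Train/test
## separation is enforced: the encoder, PCA, channel standardization and
## treatment anchors are fitted on the training split only; weights and
## mediation models are fitted on the held-out test split.

#' Pipeline configuration
#'
#' @param input mode, `"synthetic"` (default) or `"csv"`.
#' @param generator a [generator_config()] (synthetic mode).
#' @param cgm_path,events_path,subjects_path input CSVs (csv mode;
#'   `subjects_path` is optional and supplies cohort labels).
#' @param encoder a [clae_config()].
#' @param rules a [window_rules()].
#' @param k_model,k_balance principal components used in the mediation
#'   models (default 3; `"auto"` selects at 90% explained variance) / in
#'   the weighting model.
#' @param strata,horizons,doses,models,n_sims mediation settings (see
#'   [run_stratified()]).
#' @param min_stratum_n smallest analyzable stratum.
#' @param seed global seed; all stage seeds derive from it.
#' @param output_dir optional directory: when set, [run_pipeline()] writes
#'   the windows, exclusion report, embeddings, weights, balance report,
#'   mediation table and run manifest as CSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "csv"),
                            generator = generator_config(),
                            cgm_path = NULL, events_path = NULL,
                            subjects_path = NULL,
                            encoder = clae_config(),
                            rules = window_rules(),
                            k_model = 3, k_balance = 6,
                            strata = c("pooled", "breakfast", "lunch",
                                       "dinner", "snack"),
                            horizons = HORIZONS, doses = c(15, 30, 45),
                            models = c("mixed", "q25", "q50", "q75"),
                            n_sims = 1000, min_stratum_n = 30,
                            seed = 1L, output_dir = NULL) {
  input <- match.arg(input)
  if (input == "csv" && (is.null(cgm_path) || is.null(events_path)))
    stopf("csv mode requires cgm_path and events_path")
  structure(list(input = input, generator = generator, cgm_path = cgm_path,
                 events_path = events_path, subjects_path = subjects_path,
                 encoder = encoder, rules = rules, k_model = k_model,
                 k_balance = k_balance, strata = strata, horizons = horizons,
                 doses = doses, models = models, n_sims = n_sims,
                 min_stratum_n = min_stratum_n, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full mediation pipeline
#'
#' Stage order: ingest/generate, impute, window, split + standardize, train
#' encoder (train split), encode all windows, PCA (train embeddings),
#' entropy-balancing weights (test split), stratified quasi-Bayesian
#' mediation (test split), report. Any stage failure halts the run with the
#' stage named.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `windows`, `model`,
#'   `embeddings`, `pca`, `weights`, `anchors`, `mediation` (the result
#'   table) and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  manifest <- list(seed = cfg$seed, started = format(Sys.time()),
                   r_version = R.version.string)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  dat <- stage("ingest", {
    if (cfg$input == "synthetic") {
      gen <- cfg$generator
      gen$seed <- derive_seed(cfg$seed, 1)
      co <- generate_cohort(gen)
      list(cgm = co$cgm, events = co$events, subjects = co$subjects, cohort = co)
    } else {
      co <- read_cohort(cfg$cgm_path, cfg$events_path)
      co$subjects <- if (!is.null(cfg$subjects_path))
        utils::read.csv(cfg$subjects_path, stringsAsFactors = FALSE) else NULL
      co
    }
  })

  imp <- stage("impute", impute_gaps(dat$cgm))
  mw <- stage("window", {
    mw <- build_windows(imp$series, dat$events, cfg$rules, dat$subjects)
    split_and_standardize(mw, cfg$rules$train_fraction)
  })
  manifest$n_candidates <- nrow(mw$report$windows)
  manifest$n_kept <- nrow(mw$meta)
  manifest$exclusions <- as.list(mw$report$counts)

  enc_cfg <- cfg$encoder
  enc_cfg$seed <- derive_seed(cfg$seed, 2)
  model <- stage("train-encoder", clae_train(mw, enc_cfg))
  emb <- stage("encode", clae_encode(mw, model))
  manifest$encoder_hash <- emb$provenance$config_hash

  tr <- mw$meta$split == "train"
  pca <- stage("pca", fit_pca(emb$phi[tr, , drop = FALSE],
                              k_model = cfg$k_model, k_balance = cfg$k_balance))
  te <- !tr
  meta_te <- mw$meta[te, ]
  pcs_te <- pca_transform(pca, emb$phi[te, , drop = FALSE])

  weights <- stage("balance", {
    covs <- cbind(pcs_te[, seq_len(pca$k_balance), drop = FALSE],
                  G0 = meta_te$G0)
    if (length(unique(meta_te$cohort)) > 1)
      covs <- cbind(covs, cohort = as.numeric(factor(meta_te$cohort)))
    estimate_weights(meta_te$Z, covs)
  })
  manifest$n_eff <- weights$diagnostics$n_eff
  manifest$balance_reduction_pct <- weights$diagnostics$pct_reduction

  anchors <- stage("anchors", meal_type_anchors(mw, cfg$doses))
  mediation <- stage("mediate", run_stratified(
    mw, pcs_te[, seq_len(pca$k_model), drop = FALSE], weights$w, anchors,
    strata = cfg$strata, horizons = cfg$horizons, doses = cfg$doses,
    models = cfg$models, n_sims = cfg$n_sims,
    seed = derive_seed(cfg$seed, 3), min_stratum_n = cfg$min_stratum_n))
  manifest$n_mediation_rows <- nrow(mediation)
  manifest$finished <- format(Sys.time())

  out <- structure(list(windows = mw, model = model, embeddings = emb,
                        pca = pca, weights = weights, anchors = anchors,
                        mediation = mediation, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$output_dir)) write_pipeline_result(out, cfg$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result: %d/%d windows kept; n_eff %.1f; %d mediation rows\n",
              m$n_kept, m$n_candidates, m$n_eff, m$n_mediation_rows))
  invisible(x)
}

#' Write all pipeline outputs as CSVs
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_windows(result$windows, dir)
  utils::write.csv(data.frame(result$embeddings$phi,
                              split = result$embeddings$split),
                   file.path(dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(weight = result$weights$w),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  balance_report(result$weights, file.path(dir, "balance_report.csv"))
  utils::write.csv(result$mediation, file.path(dir, "mediation.csv"),
                   row.names = FALSE)
  writeLines(paste(names(result$manifest),
                   vapply(result$manifest, function(v)
                     paste(format(unlist(v)), collapse = " "), ""),
                   sep = ": "),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Summary table of mediation effects at one horizon and dose
#'
#' Pivots the long mediation table into a (stratum x model) summary with
#' ADE / ACME / TE estimates, p-values and a significance flag.
#'
#' @param mediation mediation table from [run_stratified()] or
#'   `pipeline_result$mediation`.
#' @param horizon horizon in minutes.
#' @param dose dose contrast in grams.
#' @return data frame with one row per (stratum, model).
#' @export
report_summary <- function(mediation, horizon = 120, dose = 30) {
  d <- mediation[mediation$horizon_min == horizon & mediation$dose_g == dose, ]
  if (!nrow(d)) stopf("no mediation rows at horizon %d, dose %d", horizon, dose)
  rows <- list()
  for (st in unique(d$stratum)) for (md in unique(d$model[d$stratum == st])) {
    dd <- d[d$stratum == st & d$model == md, ]
    get <- function(eff, col) dd[dd$effect == eff, col][1]
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = st, model = md, tau = dd$tau[1],
      ade = get("ADE", "estimate"), ade_p = format_p(get("ADE", "p")),
      acme = get("ACME", "estimate"), acme_p = format_p(get("ACME", "p")),
      total = get("TE", "estimate"), total_p = format_p(get("TE", "p")),
      significant = get("TE", "p") < 0.05,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long per-horizon effect table
#'
#' @param mediation mediation table.
#' @param stratum stratum to report.
#' @param model outcome model to report.
#' @return data frame keyed by (horizon, dose, effect) with formatted
#'   p-values and a significance flag.
#' @export
report_horizons <- function(mediation, stratum = "pooled", model = "mixed") {
  d <- mediation[mediation$stratum == stratum & mediation$model == model, ]
  d <- d[order(d$horizon_min, d$dose_g, d$effect), ]
  d$p_fmt <- format_p(d$p)
  d$significant <- d$p < 0.05
  rownames(d) <- NULL
  d
}

#' Plot effect trajectories across the postprandial window
#'
#' Draws ACME / ADE / TE point estimates and intervals against the horizon
#' for one stratum, model and dose. Requires ggplot2.
#'
#' @param mediation mediation table.
#' @param stratum,model,dose which cell to draw.
#' @return a ggplot object.
#' @export
plot_effects <- function(mediation, stratum = "pooled", model = "mixed",
                         dose = 30) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_effects requires ggplot2")
  d <- mediation[mediation$stratum == stratum & mediation$model == model &
                   mediation$dose_g == dose, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$horizon_min, y = .data$estimate,
                                  colour = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                                      fill = .data$effect),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minutes post-meal", y = "effect (mg/dL)",
                  title = sprintf("%s, %s, +%g g", stratum, model, dose)) +
    ggplot2::theme_minimal()
}
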