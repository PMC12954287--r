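# Cohort-level experiment: train KB (and optionally the fully supervised
# reference) ensembles on a phantom cohort, evaluate held-out exams under
# plane-availability scenarios, and aggregate segmentation quality,
# volumetric error and volume agreement statistics.

#' Evaluate a fitted ensemble on one phantom exam
#'
#' Predicts the whole-gland mask, resamples the fine ground-truth mask onto
#' the exam's axial grid, and computes Dice, average surface distance, the
#' predicted volume, the ellipsoid-formula reference volume (from the
#' analytic ground-truth diameters, independent of the segmentation under
#' test) and signed relative volume differences against both the
#' ellipsoid-formula and the analytic true volume.
#'
#' @param ens fitted [mpkb_fit()] ensemble.
#' @param case one `list(exam, truth)` element of [make_cohort()].
#' @param scenario views at inference (see [predict.mpkb()]).
#' @return One-row data frame.
#' @export
evaluate_case <- function(ens, case, scenario = "full") {
  exam <- case$exam
  truth <- case$truth
  pred <- predict(ens, exam, scenario = scenario)
  ref <- resample_to_reference(truth$mask3d, exam$views$axial$spacing)
  if (!identical(dim(ref$data), dim(pred$data))) {
    stopf("ground-truth grid does not match the axial grid for '%s'", exam$id)
  }
  pv_pred <- mask_volume(pred)
  d <- truth$ellipsoid_diameters
  pv_ref <- ellipsoid_formula_volume(d[1], d[2], d[3])
  data.frame(
    id = exam$id,
    dsc = dsc(pred, ref),
    asd = if (sum(pred$data) > 0) asd(pred, ref) else NA_real_,
    pv_pred = pv_pred, pv_ref = pv_ref, pv_true = truth$true_volume,
    rvd = rvd(pv_pred, pv_ref),
    rvd_true = rvd(pv_pred, truth$true_volume),
    row.names = NULL)
}

#' Run the full phantom experiment
#'
#' Splits the cohort into training and held-out test exams, fits the
#' requested model variants by cross-validation on the training split, and
#' evaluates every test exam under every scenario. Aggregates per-case
#' metrics, volume agreement against the ellipsoid-formula reference (ICC
#' with interpretation band, Bland-Altman limits), and paired comparisons:
#' KB versus the fully supervised reference within each scenario, and
#' multi-planar versus axial-only within each model.
#'
#' @param cohort list of `list(exam, truth)` from [make_cohort()].
#' @param cfg an [mpkb_config()].
#' @param scenarios named list of view sets (default full and axial-only).
#' @param seed run seed (split, training and batching all derive from it).
#' @param models character subset of `c("kb", "baseline")`.
#' @param n_test number of held-out test exams (default 20% of the cohort,
#'   at least 2).
#' @return Object of class `mpkb_experiment` with elements `per_case`,
#'   `agreement`, `comparisons`, `fits`, `test_ids`.
#' @export
run_experiment <- function(cohort, cfg = mpkb_config(),
                           scenarios = list(full = c("axial", "sagittal", "coronal"),
                                            axial_only = "axial"),
                           seed = cfg$seed, models = c("kb", "baseline"),
                           n_test = NULL) {
  if (length(cohort) == 0) stopf("empty cohort")
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stopf("'scenarios' must be a named list")
  }
  n <- length(cohort)
  if (is.null(n_test)) n_test <- max(2L, round(0.2 * n))
  if (n_test >= n) stopf("'n_test' must leave training exams")
  test_idx <- with_seed(sub_seed(seed, "split"), sort(sample(n, n_test)))
  train_cases <- cohort[-test_idx]
  test_cases <- cohort[test_idx]

  fits <- list()
  for (mt in models) {
    fits[[mt]] <- mpkb_fit(lapply(train_cases, `[[`, "exam"), cfg,
                           seed = sub_seed(seed, paste0("fit_", mt)),
                           model_type = mt)
  }

  per_case <- list()
  for (mt in models) {
    for (sc in names(scenarios)) {
      rows <- lapply(test_cases, function(case) {
        cbind(model = mt, scenario = sc,
              evaluate_case(fits[[mt]], case, scenarios[[sc]]))
      })
      per_case[[paste(mt, sc)]] <- do.call(rbind, rows)
    }
  }
  per_case <- do.call(rbind, c(per_case, list(make.row.names = FALSE)))

  agreement <- do.call(rbind, lapply(split(per_case,
                                           per_case[c("model", "scenario")]),
                                     agreement_row))
  rownames(agreement) <- NULL

  comparisons <- experiment_comparisons(per_case, models, names(scenarios))

  structure(list(per_case = per_case, agreement = agreement,
                 comparisons = comparisons, fits = fits,
                 test_ids = vapply(test_cases, function(ct) ct$exam$id,
                                   character(1)),
                 cfg = cfg, seed = seed),
            class = "mpkb_experiment")
}

agreement_row <- function(df) {
  ic <- tryCatch(icc_agreement(df$pv_pred, df$pv_ref), error = function(e) NULL)
  ba <- tryCatch(bland_altman(df$pv_pred, df$pv_ref), error = function(e) NULL)
  data.frame(
    model = df$model[1], scenario = df$scenario[1], n = nrow(df),
    dsc_mean = mean(df$dsc), dsc_sd = sd(df$dsc),
    asd_mean = mean(df$asd, na.rm = TRUE),
    rvd_mean = mean(df$rvd), rvd_true_mean = mean(df$rvd_true),
    icc = if (is.null(ic)) NA_real_ else ic$icc,
    icc_lo = if (is.null(ic)) NA_real_ else ic$ci[1],
    icc_hi = if (is.null(ic)) NA_real_ else ic$ci[2],
    icc_category = if (is.null(ic)) NA_character_ else ic$category,
    ba_mean_diff = if (is.null(ba)) NA_real_ else ba$mean_diff,
    ba_loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
    ba_loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
    row.names = NULL)
}

experiment_comparisons <- function(per_case, models, scenario_names) {
  rows <- list()
  cmp <- function(label, x, y) {
    # degenerate (all-equal) differences are encoded in test_used, so the
    # per-call warning is redundant at cohort level
    pc <- tryCatch(suppressWarnings(paired_compare(x, y)),
                   error = function(e) NULL)
    if (is.null(pc)) return(NULL)
    data.frame(comparison = label, p_value = pc$p_value,
               test_used = pc$test_used, row.names = NULL)
  }
  for (metric in c("dsc", "rvd")) {
    if (length(models) == 2) {
      for (sc in scenario_names) {
        a <- per_case[per_case$model == "kb" & per_case$scenario == sc, ]
        b <- per_case[per_case$model == "baseline" & per_case$scenario == sc, ]
        b <- b[match(a$id, b$id), ]
        rows[[length(rows) + 1L]] <-
          cmp(sprintf("%s: kb vs baseline (%s)", metric, sc),
              a[[metric]], b[[metric]])
      }
    }
    if (length(scenario_names) >= 2) {
      for (mt in models) {
        a <- per_case[per_case$model == mt &
                        per_case$scenario == scenario_names[1], ]
        b <- per_case[per_case$model == mt &
                        per_case$scenario == scenario_names[2], ]
        b <- b[match(a$id, b$id), ]
        rows[[length(rows) + 1L]] <-
          cmp(sprintf("%s: %s vs %s (%s)", metric, scenario_names[1],
                      scenario_names[2], mt),
              a[[metric]], b[[metric]])
      }
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(), p_value = numeric(),
               test_used = character())
}

#' @export
print.mpkb_experiment <- function(x, ...) {
  cat(sprintf("<mpkb_experiment> %d test exams, models: %s\n",
              length(x$test_ids), paste(names(x$fits), collapse = ", ")))
  cols <- c("model", "scenario", "dsc_mean", "asd_mean", "rvd_true_mean",
            "icc", "icc_category")
  print(x$agreement[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write experiment tables to CSV
#'
#' Emits `per_case.csv` (one row per exam, scenario and model),
#' `agreement.csv` (cohort summaries with ICC and Bland-Altman limits) and
#' `comparisons.csv` (paired-test p-values).
#'
#' @param x an `mpkb_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_csv <- function(x, dir) {
  stopifnot(inherits(x, "mpkb_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$per_case, file.path(dir, "per_case.csv"), row.names = FALSE)
  write.csv(x$agreement, file.path(dir, "agreement.csv"), row.names = FALSE)
  write.csv(x$comparisons, file.path(dir, "comparisons.csv"), row.names = FALSE)
  invisible(dir)
}
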