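# Training loop, cross-validation bookkeeping and ensemble prediction.

test_that("zero-epoch training returns the initialized model", {
  co <- tiny_cohort(2, seed = 61)
  cfg <- tiny_cfg(epochs = 0L)
  m <- train_fold(lapply(co, `[[`, "exam"), cfg, fold_idx = 1, seed = 3)
  cfg_init <- cfg
  cfg_init$seed <- mpkbseg:::sub_seed(3, "fold1_init")
  expect_identical(m$params, build_model(cfg_init)$params)
  expect_null(m$history)
})

test_that("training is deterministic and decreases the dice term", {
  co <- tiny_cohort(5, seed = 62)
  exams <- lapply(co, `[[`, "exam")
  cfg <- tiny_cfg(epochs = 6L)
  m1 <- train_fold(exams, cfg, fold_idx = 1, seed = 11)
  m2 <- train_fold(exams, cfg, fold_idx = 1, seed = 11)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$history$dice_term[6], m1$history$dice_term[1])
  # contrastive terms are tracked for both orthogonal views
  expect_true(all(is.finite(m1$history$contrastive_ax_sag)))
})

test_that("kb training never touches sagittal or coronal masks", {
  co <- tiny_cohort(2, seed = 63)
  prep <- mpkbseg:::prepare_exam(co[[1]]$exam, "kb")
  expect_false(any(grepl("_mask", names(prep))))
  expect_true("mask" %in% names(prep))          # axial supervision only
  # the baseline schema does include the per-view masks
  prep_b <- mpkbseg:::prepare_exam(co[[1]]$exam, "baseline")
  expect_true(all(c("sagittal_mask", "coronal_mask") %in% names(prep_b)))
  # and an exam without an axial mask is rejected by name
  broken <- co[[2]]$exam
  broken$mask <- NULL
  expect_error(mpkbseg:::prepare_exam(broken, "kb"), broken$id)
})

test_that("fold assignment partitions exams reproducibly", {
  ids <- sprintf("e%02d", 1:10)
  f <- mpkbseg:::fold_assignments(ids, 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))               # 10 exams, 5 folds -> 2 each
  # membership depends on the id set, not on input order
  f2 <- mpkbseg:::fold_assignments(rev(ids), 5, seed = 4)
  expect_identical(f[ids], f2[ids])
  co <- tiny_cohort(3, seed = 64)
  expect_error(mpkb_fit(lapply(co, `[[`, "exam"), tiny_cfg(folds = 5L)),
               "at least 5")
})

test_that("cross-validated fit trains one member per fold", {
  tr <- tiny_trained()
  fit <- tr$fit
  expect_s3_class(fit, "mpkb")
  expect_length(fit$members, fit$cfg$folds)
  expect_equal(sort(unique(fit$fold_assignments)), seq_len(fit$cfg$folds))
  out <- capture.output(print(fit))
  expect_true(any(grepl("kb model", out)))
})

test_that("ensembling five identical members equals a single member", {
  tr <- tiny_trained()
  one <- tr$fit
  member <- one$members[[1]]
  single <- structure(list(members = list(member), cfg = one$cfg,
                           model_type = "kb"), class = "mpkb")
  five <- structure(list(members = rep(list(member), 5), cfg = one$cfg,
                         model_type = "mpkb"), class = "mpkb")
  exam <- tr$cohort[[1]]$exam
  p1 <- predict(single, exam, scenario = "full")
  p5 <- predict(five, exam, scenario = "full")
  expect_equal(p5$data, p1$data)
})

test_that("axial-only prediction ignores context views entirely", {
  tr <- tiny_trained()
  exam <- tr$cohort[[2]]$exam
  p_ax <- predict(tr$fit, exam, scenario = "axial_only")
  stripped <- exam
  stripped$views <- exam$views["axial"]
  p_stripped <- predict(tr$fit, stripped, scenario = "axial_only")
  expect_identical(p_ax$data, p_stripped$data)
  expect_equal(dim(p_ax$data), dim(exam$mask$data))
  expect_error(predict(tr$fit, stripped, scenario = "full"), "lacks")
  expect_error(predict(tr$fit, exam, scenario = c("sagittal")), "axial")
})

test_that("short training improves held-out segmentation over initialization", {
  tr <- tiny_trained()
  held <- tiny_cohort(2, seed = 99)[[1]]
  ref <- resample_to_reference(held$truth$mask3d,
                               held$exam$views$axial$spacing)
  trained_dsc <- dsc(predict(tr$fit, held$exam, "full"), ref)
  cfg0 <- tr$fit$cfg
  cfg0$epochs <- 0L
  init <- mpkb_fit(lapply(tr$cohort, `[[`, "exam"), cfg0, seed = 7)
  init_dsc <- dsc(predict(init, held$exam, "full"), ref)
  expect_gt(trained_dsc, init_dsc)
})

test_that("the fully supervised baseline trains with per-view masks", {
  co <- tiny_cohort(4, seed = 65)
  exams <- lapply(co, `[[`, "exam")
  m <- train_fold(exams, tiny_cfg(epochs = 5L), fold_idx = 1, seed = 13,
                  model_type = "baseline")
  expect_equal(m$model_type, "baseline")
  expect_lt(mean(m$history$dice_term[4:5]), m$history$dice_term[1])
  # lambda forced to zero: no contrastive contribution in the history
  expect_true(all(is.na(m$history$contrastive_ax_sag)))
  # context views without masks cannot feed the baseline
  broken <- co[[1]]$exam
  broken$view_masks <- list()
  expect_error(train_fold(list(broken), tiny_cfg(epochs = 1L),
                          fold_idx = 1, seed = 13, model_type = "baseline"),
               "sagittal")
})
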