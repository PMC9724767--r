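test_that("the stratified split preserves class proportions and is a partition", {
  ids <- sprintf("s%02d", 1:40)
  labels <- rep(c("pos", "neg"), c(8, 32))
  cfg <- train_config(seed = 7)
  sp <- split_train_test(ids, labels, cfg)
  expect_equal(sum(sp$test_ids %in% ids[1:8]), 2L)    # 25% of 8
  expect_equal(sum(sp$test_ids %in% ids[9:40]), 8L)   # 25% of 32
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  sp2 <- split_train_test(ids, labels, cfg)
  expect_identical(sp, sp2)
  expect_error(split_train_test(c("a", "b", "c"), c("x", "x", "y"),
                                train_config()), "fewer than 2")
})

test_that("band assignment reproduces the three-band rule with inclusive boundaries", {
  expect_identical(assign_band(c(0.20, 0.40, 0.60)),
                   c("control", "inconclusive", "pathogenic"))
  expect_identical(assign_band(c(0.25, 0.50)),
                   c("inconclusive", "inconclusive"))
  expect_error(assign_band(1.2), "\\[0, 1\\]")
  expect_error(assign_band(-0.1), "\\[0, 1\\]")
  # every score maps to exactly one band
  grid <- seq(0, 1, by = 0.001)
  bands <- assign_band(grid)
  expect_true(all(bands %in% c("control", "inconclusive", "pathogenic")))
  expect_equal(length(bands), length(grid))
})

test_that("training on a separable planted cohort is perfect, deterministic and calibrated", {
  sim <- simulate_cohort(cohort_config(n_probes = 600,
                                       n_signature_probes = 30,
                                       delta_beta = 0.3, n_cases = 16,
                                       n_controls = 80, n_reference = 0,
                                       seed = 12))
  sig <- sim$truth$signature_probe_ids
  labels <- sim$sheet$group
  cfg <- train_config(seed = 4)
  model <- suppressWarnings(
    train_classifier(sim$beta[sig, ], labels, cfg, positive = "case"))
  expect_s3_class(model, "episvm")
  expect_equal(model$provenance$test_accuracy, 1.0)
  model2 <- suppressWarnings(
    train_classifier(sim$beta[sig, ], labels, cfg, positive = "case"))
  expect_identical(model$weights, model2$weights)
  expect_identical(model$nu, model2$nu)

  # score monotone in margin; calibration stays inside [0, 1]
  marg <- predict(model, sim$beta, type = "margin")
  score <- predict(model, sim$beta, type = "score")
  expect_identical(order(marg), order(score))
  expect_true(all(score >= 0 & score <= 1))
  expect_gt(max(score[labels == "case"]), max(score[labels != "case"]))

  # cases score as pathogenic, controls as control band
  band <- predict(model, sim$beta, type = "band")
  expect_true(all(band[labels == "case"] == "pathogenic"))
  expect_gt(mean(band[labels != "case"] == "control"), 0.95)
})

test_that("permuted labels drive CV accuracy to the majority-class rate", {
  sim <- simulate_cohort(cohort_config(n_probes = 300,
                                       n_signature_probes = 20,
                                       delta_beta = 0.25, n_cases = 12,
                                       n_controls = 48, n_reference = 0,
                                       n_age_probes = 50, n_sex_probes = 50,
                                       seed = 9))
  sig <- sim$truth$signature_probe_ids
  majority <- 48 / 60
  accs <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    perm <- sample(sim$sheet$group)
    model <- suppressWarnings(
      train_classifier(sim$beta[sig, ], perm, train_config(seed = s),
                       positive = "case"))
    accs[s] <- max(model$provenance$cv_accuracy, na.rm = TRUE)
  }
  expect_lt(abs(mean(accs) - majority), 0.15)
})

test_that("scoring validates probes and missing values; model JSON round trips", {
  sim <- small_cohort(seed = 6)
  sig <- sim$truth$signature_probe_ids
  model <- suppressWarnings(
    train_classifier(sim$beta[sig, ], sim$sheet$group, train_config(seed = 2),
                     positive = "case"))
  expect_error(predict(model, sim$beta[-(1:2000), , drop = FALSE]),
               "lacks signature probe")
  holed <- sim$beta; holed[sig[1], 3] <- NA
  expect_error(predict(model, holed), "impute")

  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(score_samples(back, sim$beta), score_samples(model, sim$beta),
               tolerance = 1e-12)
  expect_identical(back$probe_ids, model$probe_ids)
})

test_that("infeasible nu values are skipped and an all-infeasible grid errors", {
  sim <- simulate_cohort(cohort_config(n_probes = 200,
                                       n_signature_probes = 10,
                                       delta_beta = 0.3, n_cases = 6,
                                       n_controls = 94, n_reference = 0,
                                       n_age_probes = 0, n_sex_probes = 0,
                                       seed = 3))
  sig <- sim$truth$signature_probe_ids
  expect_warning(
    model <- train_classifier(sim$beta[sig, ], sim$sheet$group,
                              train_config(nu_grid = c(0.05, 0.8), seed = 1),
                              positive = "case"),
    "infeasible")
  expect_equal(model$nu, 0.05)
  expect_error(suppressWarnings(
    train_classifier(sim$beta[sig, ], sim$sheet$group,
                     train_config(nu_grid = c(0.9, 0.95), seed = 1),
                     positive = "case")),
    "no feasible nu")
})
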