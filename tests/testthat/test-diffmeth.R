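# --- estimate_prior ----------------------------------------------------

test_that("equal variances give an infinite-df prior at the common value", {
  prior <- estimate_prior(rep(2.5, 50), df_residual = 10)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 2.5)
  expect_error(estimate_prior(rep(0, 50), 10), "zero")
  expect_error(estimate_prior(c(1, 2), 10), "at least 10")
  expect_error(estimate_prior(c(rep(1, 10), -1), 10), "nonnegative")
})

test_that("the prior matches an independent numeric solution of the moment equations", {
  s2 <- 1:10
  fit <- estimate_prior(s2, df_residual = 8)
  ora <- prior_oracle(s2, 8)
  expect_equal(fit$d0, ora$d0, tolerance = 1e-6)
  expect_equal(fit$s0_sq, ora$s0_sq, tolerance = 1e-6)

  # cross-check against limma's F-distribution fit on simulated variances
  set.seed(7)
  sig2 <- 4 * 2 / stats::rchisq(20000, 4)
  s2 <- sig2 * stats::rchisq(20000, 12) / 12
  fit2 <- estimate_prior(s2, 12)
  lf <- limma::fitFDist(s2, df1 = 12)
  expect_equal(fit2$d0, lf$df2, tolerance = 0.05)
  expect_equal(fit2$s0_sq, lf$scale, tolerance = 0.02)
})

# --- moderated_t -------------------------------------------------------

test_that("moderated t reduces to the pooled two-sample t when d0 = 0", {
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "ebayes_prior")
  set.seed(3)
  for (i in 1:100) {
    x <- stats::rnorm(sample(3:9, 1)); y <- stats::rnorm(sample(3:9, 1), 0.3)
    res <- moderated_t(x, y, prior0)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$t_moderated, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t handles symmetry, equal means and degenerate variance", {
  prior <- structure(list(d0 = 4, s0_sq = 1), class = "ebayes_prior")
  res <- moderated_t(c(1, 2, 3), c(1, 2, 3), prior)
  expect_equal(res$t_moderated, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$delta, 0)

  # equal group means, different spread: t = 0, p = 1
  res2 <- moderated_t(c(0, 2), c(0.5, 1.5), prior)
  expect_equal(res2$t_moderated, 0)
  expect_equal(res2$p_value, 1)

  # zero posterior variance with nonzero difference: p = 0 + warning
  prior00 <- structure(list(d0 = 0, s0_sq = 1), class = "ebayes_prior")
  expect_warning(res3 <- moderated_t(c(1, 1), c(0, 0), prior00),
                 "zero posterior variance")
  expect_equal(res3$p_value, 0)
  expect_error(moderated_t(1, c(1, 2), prior), "at least 2")
})

test_that("an infinite-df prior uses the normal reference distribution", {
  prior <- structure(list(d0 = Inf, s0_sq = 1), class = "ebayes_prior")
  res <- moderated_t(c(1, 2, 3), c(3, 4, 5), prior)
  se <- sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t_moderated, -2 / se)
  expect_equal(res$p_value, 2 * stats::pnorm(-abs(-2 / se)))
})

# --- bh_adjust ---------------------------------------------------------

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), rep(0.05, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  p <- stats::runif(6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in seq_len(nrow(perms))) {
    pp <- p[perms[i, ]]
    expect_equal(bh_adjust(pp), bh_oracle(pp))
  }
})

# --- select_probes / prune_correlated ----------------------------------

test_that("probe selection filters, ranks by |t|*|delta| and breaks ties by id", {
  stats_df <- data.frame(
    probe_id = c("p4", "p1", "p2", "p3", "p5"),
    delta_beta = c(0.2, 0.2, 0.2, 0.05, 0.4),
    t_moderated = c(5, 5, 8, 9, 3),
    p_value = c(1e-4, 1e-4, 1e-5, 1e-6, 0.5),
    p_adjusted = c(1e-3, 1e-3, 1e-4, 1e-5, 0.9),
    stringsAsFactors = FALSE)
  out <- select_probes(stats_df, select_config())
  # p5 fails alpha, p3 fails effect size; p2 scores 1.6, p1/p4 tie at 1.0
  expect_identical(out$probe_id, c("p2", "p1", "p4"))
  expect_identical(out$rank, 1:3)
  expect_true(all(out$probe_id %in% stats_df$probe_id))

  none <- select_probes(stats_df[5, ], select_config())
  expect_equal(nrow(none), 0L)

  capped <- select_probes(stats_df, select_config(max_probes = 2))
  expect_equal(nrow(capped), 2L)
})

test_that("correlation pruning keeps the greedy-maximal independent set", {
  # duplicated probe rows: only the higher-ranked copy survives
  m <- random_beta(3, 12, seed = 1)
  m["cg0000002", ] <- m["cg0000001", ]
  sel <- data.frame(probe_id = rownames(m), delta_beta = 0.2,
                    t_moderated = c(5, 4, 3), p_value = 1e-4,
                    p_adjusted = 1e-3, rank = 1:3, stringsAsFactors = FALSE)
  out <- prune_correlated(sel, m, 0.9)
  expect_identical(out$probe_id, c("cg0000001", "cg0000003"))
  expect_identical(out$rank, 1:2)

  # mutually uncorrelated probes pass through unchanged
  m2 <- random_beta(5, 200, seed = 2)
  sel2 <- data.frame(probe_id = rownames(m2), delta_beta = 0.2,
                     t_moderated = 5:1, p_value = 1e-4, p_adjusted = 1e-3,
                     rank = 1:5, stringsAsFactors = FALSE)
  expect_identical(prune_correlated(sel2, m2, 0.9)$probe_id, rownames(m2))

  # shared-latent-factor construction vs brute-force greedy oracle
  set.seed(5)
  n <- 40
  latent <- stats::rnorm(n)
  load <- c(1, 0.97, 0.2, 0.95, 0.1)
  X <- sapply(load, function(l) l * latent + sqrt(1 - l^2) * stats::rnorm(n))
  B <- (X - min(X)) / diff(range(X))
  m3 <- t(B); rownames(m3) <- sprintf("cg%07d", 1:5)
  colnames(m3) <- sprintf("s%03d", 1:n)
  sel3 <- data.frame(probe_id = rownames(m3), delta_beta = 0.2,
                     t_moderated = 9:5, p_value = 1e-4, p_adjusted = 1e-3,
                     rank = 1:5, stringsAsFactors = FALSE)
  out3 <- prune_correlated(sel3, m3, 0.9)
  expect_identical(out3$probe_id,
                   rownames(m3)[prune_oracle(stats::cor(t(m3)), 0.9)])

  # zero-variance probe: warned, treated as uncorrelated, kept-eligible
  m4 <- m2; m4[2, ] <- 0.4
  expect_warning(out4 <- prune_correlated(sel2, m4, 0.9), "zero variance")
  expect_true("cg0000002" %in% out4$probe_id)
})

test_that("group-centred pruning ignores correlation induced by the group effect", {
  set.seed(9)
  n1 <- 8; n0 <- 24
  grp <- rep(c(1, 0), c(n1, n0))
  # two probes sharing only the case shift; independent noise
  x1 <- 0.3 * grp + 0.1 + stats::rnorm(n1 + n0, 0, 0.02)
  x2 <- 0.3 * grp + 0.2 + stats::rnorm(n1 + n0, 0, 0.02)
  m <- rbind(cg1 = pmin(pmax(x1, 0), 1), cg2 = pmin(pmax(x2, 0), 1))
  colnames(m) <- sprintf("s%03d", seq_len(n1 + n0))
  sel <- data.frame(probe_id = c("cg1", "cg2"), delta_beta = 0.3,
                    t_moderated = c(9, 8), p_value = 1e-6, p_adjusted = 1e-5,
                    rank = 1:2, stringsAsFactors = FALSE)
  expect_gt(abs(stats::cor(m[1, ], m[2, ])), 0.9)      # raw r above threshold
  raw <- prune_correlated(sel, m, 0.9)
  expect_equal(nrow(raw), 1L)                           # raw pruning drops one
  centred <- prune_correlated(sel, m, 0.9,
                              groups = ifelse(grp == 1, "case", "control"))
  expect_equal(nrow(centred), 2L)                       # centred keeps both
})

# --- derive_signature --------------------------------------------------

test_that("signature derivation recovers a planted signature and is deterministic", {
  sim <- small_cohort(seed = 3)
  cases <- case_ids_of(sim)
  controls <- control_ids_of(sim)[1:24]
  sig1 <- derive_signature(sim$beta, sim$sheet, cases, controls)
  sig2 <- derive_signature(sim$beta, sim$sheet, cases, controls)
  expect_identical(sig1$probes, sig2$probes)

  truth <- sim$truth$signature_probe_ids
  sens <- mean(truth %in% sig1$probes$probe_id)
  prec <- mean(sig1$probes$probe_id %in% truth)
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
  expect_identical(sig1$probes$rank, seq_len(nrow(sig1$probes)))
  expect_false(anyDuplicated(sig1$probes$probe_id) > 0)
  cn <- sig1$provenance$counts
  expect_true(all(c("probes_in", "qc_pass", "significant", "effect_filtered",
                    "pruned") %in% names(cn)))
  expect_true(cn["pruned"] <= cn["effect_filtered"])

  expect_error(derive_signature(sim$beta, sim$sheet, cases, cases[1:2]),
               "overlap")
  expect_error(derive_signature(sim$beta, sim$sheet, c(cases, "ghost"),
                                controls), "ghost")
})

test_that("a null cohort yields an empty signature", {
  sim <- simulate_cohort(cohort_config(n_probes = 1000,
                                       n_signature_probes = 40,
                                       delta_beta = 0, n_controls = 40,
                                       n_reference = 0, seed = 21))
  sig <- derive_signature(sim$beta, sim$sheet, case_ids_of(sim),
                          control_ids_of(sim)[1:24])
  expect_equal(nrow(sig$probes), 0L)
})

test_that("signature TSV round trip preserves the probe table", {
  sim <- small_cohort(seed = 3)
  sig <- derive_signature(sim$beta, sim$sheet, case_ids_of(sim),
                          control_ids_of(sim)[1:24])
  path <- withr::local_tempfile(fileext = ".tsv")
  prov <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path, prov)
  back <- read_signature(path)
  expect_identical(back$probe_id, sig$probes$probe_id)
  expect_equal(back$delta_beta, sig$probes$delta_beta, tolerance = 1e-12)
  expect_true(file.exists(prov))
})
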