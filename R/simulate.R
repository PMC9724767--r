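#' Synthetic methylation cohort configuration
#'
#' Defines a cohort with the structure an episignature analysis assumes: a
#' small case group carrying a planted probe signature, a matched-control
#' pool, and a larger reference background of healthy and other-disorder
#' samples, with age, sex and (optional) batch nuisance effects. Baseline
#' probe means are drawn from a three-component mixture (low/intermediate/
#' high methylation); all noise and nuisance effects act on the log2 logit
#' (M-value) scale so emitted beta values stay in \[0, 1\] and show the
#' heteroskedastic variance profile typical of array data.
#'
#' @param n_probes Number of probes. Default 20000.
#' @param n_signature_probes Planted signature size. Default 175.
#' @param delta_beta Target case-minus-control mean beta difference on
#'   planted probes (magnitude used; each probe gets a random hyper/hypo
#'   direction). Default 0.2.
#' @param n_cases,n_controls,n_reference Group sizes: cases, healthy-control
#'   pool, other-disorder reference background. Defaults 8 / 200 / 100.
#' @param age_range Two-element numeric, years. Default c(10, 80).
#' @param sex_ratio Fraction female. Default 0.5.
#' @param noise_sd Per-cell noise SD on the M-value scale. Default 0.4.
#' @param n_age_probes,age_slope Probes with linear age drift and its slope
#'   (M-value units per year, about the age-range midpoint). Defaults 500,
#'   0.02.
#' @param n_sex_probes,sex_shift Sex-affected probes and the F-minus-M shift
#'   (M-value units). Defaults 500, 1.
#' @param batch_shift Batch-2 shift (M-value units) applied to a 10% probe
#'   subset; 0 disables batch structure. Default 0.
#' @param mixture_weights,mixture_means Baseline mean mixture (weights over
#'   low/intermediate/high components and their centres).
#' @param seed Integer seed; the output is fully determined by it.
#' @return A list of class \code{cohort_config}.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_probes = 20000, n_signature_probes = 175,
                          delta_beta = 0.2, n_cases = 8, n_controls = 200,
                          n_reference = 100, age_range = c(10, 80),
                          sex_ratio = 0.5, noise_sd = 0.4,
                          n_age_probes = 500, age_slope = 0.02,
                          n_sex_probes = 500, sex_shift = 1,
                          batch_shift = 0,
                          mixture_weights = c(0.35, 0.30, 0.35),
                          mixture_means = c(0.1, 0.5, 0.9),
                          seed = 1) {
  stopifnot(n_signature_probes <= n_probes, n_age_probes <= n_probes,
            n_sex_probes <= n_probes, sex_ratio >= 0, sex_ratio <= 1,
            noise_sd > 0, n_probes >= 1, n_cases >= 0, n_controls >= 0,
            n_reference >= 0, abs(delta_beta) <= 1,
            length(age_range) == 2, age_range[1] >= 0,
            age_range[2] >= age_range[1],
            length(mixture_weights) == 3, all(mixture_weights >= 0),
            length(mixture_means) == 3)
  structure(list(n_probes = n_probes, n_signature_probes = n_signature_probes,
                 delta_beta = delta_beta, n_cases = n_cases,
                 n_controls = n_controls, n_reference = n_reference,
                 age_range = age_range, sex_ratio = sex_ratio,
                 noise_sd = noise_sd, n_age_probes = n_age_probes,
                 age_slope = age_slope, n_sex_probes = n_sex_probes,
                 sex_shift = sex_shift, batch_shift = batch_shift,
                 mixture_weights = mixture_weights,
                 mixture_means = mixture_means, seed = as.integer(seed)),
            class = "cohort_config")
}

# Clip bounds for planted case means on the beta scale.
.plant_clip <- c(0.02, 0.98)

# Child seeds drawn in fixed order from the master seed, so each generator
# component has its own stream regardless of configuration.
.child_seeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a methylation cohort with a planted episignature
#'
#' Generates a beta matrix (probes x samples), sample sheet, and the planted
#' ground truth. Baseline probe means come from the configured mixture with
#' small jitter; each cell gets Gaussian noise on the M-value scale; case
#' samples have signature probes shifted so the expected case-minus-control
#' beta difference equals \code{delta_beta} (solved per probe on the logit
#' scale, clipped into \[0.02, 0.98\]); age, sex and batch effects are
#' applied to their designated probe sets for all samples.
#'
#' @param config A [cohort_config()].
#' @param signature_probe_ids Optional explicit probe ids to plant the case
#'   signature on (overrides the seeded random choice); must be a subset of
#'   the generated probe ids \code{cg0000001..}.
#' @return A list of class \code{methyl_cohort}: \code{beta} (matrix),
#'   \code{sheet} (data.frame with groups \code{case}, \code{control},
#'   \code{reference}), and \code{truth} — planted signature/age/sex/batch
#'   probe ids, per-probe signature shifts, baseline M-value means, and any
#'   clip warnings.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            signature_probe_ids = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cs <- .child_seeds(config$seed)
  probe_ids <- sprintf("cg%07d", seq_len(config$n_probes))

  # 1. baseline means
  set.seed(cs[1])
  comp <- sample.int(3L, config$n_probes, replace = TRUE,
                     prob = config$mixture_weights / sum(config$mixture_weights))
  mu_beta <- config$mixture_means[comp] +
    stats::rnorm(config$n_probes, 0, 0.02)
  mu_beta <- pmin(pmax(mu_beta, 0.01), 0.99)
  mu_m <- logit_clip(mu_beta, 0.01)
  names(mu_m) <- probe_ids

  # 2. probe roles
  set.seed(cs[2])
  if (is.null(signature_probe_ids)) {
    sig_ids <- sort(sample(probe_ids, config$n_signature_probes))
  } else {
    if (!all(signature_probe_ids %in% probe_ids))
      stop("signature_probe_ids must be a subset of the generated probe ids")
    sig_ids <- signature_probe_ids
  }
  age_ids <- sort(sample(probe_ids, config$n_age_probes))
  sex_ids <- sort(sample(probe_ids, config$n_sex_probes))
  batch_ids <- if (config$batch_shift != 0)
    sort(sample(probe_ids, max(1L, round(0.1 * config$n_probes)))) else character(0)

  # 3. planted case shift, solved per probe on the logit scale
  set.seed(cs[3])
  d <- abs(config$delta_beta)
  sgn <- sample(c(-1, 1), length(sig_ids), replace = TRUE)
  base <- mu_beta[match(sig_ids, probe_ids)]
  target <- pmin(pmax(base + sgn * d, .plant_clip[1]), .plant_clip[2])
  short <- abs(target - base) < d - 1e-12
  sgn[short] <- -sgn[short]
  target <- pmin(pmax(base + sgn * d, .plant_clip[1]), .plant_clip[2])
  clip_warn <- sum(abs(target - base) < d - 1e-12)
  shift_m <- logit_clip(target, 0.01) - logit_clip(base, 0.01)
  names(shift_m) <- sig_ids

  # 4. sample metadata
  set.seed(cs[4])
  n <- config$n_cases + config$n_controls + config$n_reference
  sheet <- data.frame(
    sample_id = c(sprintf("case_%03d", seq_len(config$n_cases)),
                  sprintf("control_%03d", seq_len(config$n_controls)),
                  sprintf("reference_%03d", seq_len(config$n_reference))),
    group = rep(c("case", "control", "reference"),
                c(config$n_cases, config$n_controls, config$n_reference)),
    age = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"),
    stringsAsFactors = FALSE)
  if (config$batch_shift != 0)
    sheet$batch <- sample(c("b1", "b2"), n, replace = TRUE)

  # 5. signal + noise on the M-value scale
  set.seed(cs[5])
  M <- matrix(mu_m, config$n_probes, n,
              dimnames = list(probe_ids, sheet$sample_id))
  case_cols <- which(sheet$group == "case")
  if (length(case_cols) && length(sig_ids) && d > 0)
    M[sig_ids, case_cols] <- M[sig_ids, case_cols] + shift_m
  if (length(age_ids) && config$age_slope != 0) {
    centred_age <- sheet$age - mean(config$age_range)
    M[age_ids, ] <- M[age_ids, ] +
      outer(rep(config$age_slope, length(age_ids)), centred_age)
  }
  if (length(sex_ids) && config$sex_shift != 0) {
    f_cols <- which(sheet$sex == "F")
    M[sex_ids, f_cols] <- M[sex_ids, f_cols] + config$sex_shift
  }
  if (length(batch_ids)) {
    b2 <- which(sheet$batch == "b2")
    M[batch_ids, b2] <- M[batch_ids, b2] + config$batch_shift
  }
  M <- M + matrix(stats::rnorm(length(M), 0, config$noise_sd),
                  nrow(M), ncol(M))
  beta <- m_to_beta(M)

  truth <- list(signature_probe_ids = sig_ids,
                signature_shift_m = shift_m,
                age_probe_ids = age_ids, sex_probe_ids = sex_ids,
                batch_probe_ids = batch_ids,
                baseline_m = mu_m, config = config,
                clip_warnings = clip_warn)
  if (clip_warn > 0)
    warning(clip_warn, " planted probe(s) could not reach the full ",
            "delta_beta within [", .plant_clip[1], ", ", .plant_clip[2],
            "]; shift clipped (recorded in truth$clip_warnings)")
  structure(list(beta = beta, sheet = sheet, truth = truth),
            class = "methyl_cohort")
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic methylation cohort\n")
  cat(sprintf("  %d probes x %d samples (%d case / %d control / %d reference)\n",
              nrow(x$beta), ncol(x$beta), cfg$n_cases, cfg$n_controls,
              cfg$n_reference))
  cat(sprintf("  planted signature: %d probes, |delta beta| = %g\n",
              length(x$truth$signature_probe_ids), abs(cfg$delta_beta)))
  cat(sprintf("  nuisance: %d age probes, %d sex probes, batch %s; seed %d\n",
              length(x$truth$age_probe_ids), length(x$truth$sex_probe_ids),
              if (cfg$batch_shift != 0) "on" else "off", cfg$seed))
  invisible(x)
}

#' Simulate additional samples on an existing cohort's baseline
#'
#' Draws new samples from the same per-probe baseline and nuisance structure
#' as a simulated cohort, optionally carrying either the cohort's planted
#' signature (with identical per-probe shifts, i.e. genuine carriers of the
#' same episignature) or a newly planted signature on a different probe set.
#' Used to create held-out carriers, carriers of a disjoint signature, and
#' extra controls for classifier experiments.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n Number of samples to generate.
#' @param seed Integer seed for this draw.
#' @param group Group label for the new samples (also the sample-id prefix).
#' @param signature One of \code{"planted"} (carry the cohort's signature),
#'   \code{"none"} (plain background samples), or a character vector of
#'   probe ids on which to plant a new signature.
#' @param delta_beta Effect magnitude for a newly planted signature; defaults
#'   to the cohort's configured value.
#' @return A list with \code{beta} (probes x n), \code{sheet}, and
#'   \code{truth} (probe ids and shifts planted in these samples, if any).
#' @export
simulate_carriers <- function(cohort, n, seed, group = "query",
                              signature = "planted", delta_beta = NULL) {
  stopifnot(inherits(cohort, "methyl_cohort"), n >= 1)
  cfg <- cohort$truth$config
  probe_ids <- names(cohort$truth$baseline_m)
  cs <- .child_seeds(seed, 3L)

  if (identical(signature, "planted")) {
    sig_ids <- cohort$truth$signature_probe_ids
    shift_m <- cohort$truth$signature_shift_m
  } else if (identical(signature, "none")) {
    sig_ids <- character(0); shift_m <- numeric(0)
  } else {
    if (!all(signature %in% probe_ids))
      stop("signature probe ids not present in the cohort")
    sig_ids <- signature
    d <- abs(if (is.null(delta_beta)) cfg$delta_beta else delta_beta)
    set.seed(cs[1])
    sgn <- sample(c(-1, 1), length(sig_ids), replace = TRUE)
    base <- m_to_beta(cohort$truth$baseline_m[sig_ids])
    target <- pmin(pmax(base + sgn * d, .plant_clip[1]), .plant_clip[2])
    short <- abs(target - base) < d - 1e-12
    sgn[short] <- -sgn[short]
    target <- pmin(pmax(base + sgn * d, .plant_clip[1]), .plant_clip[2])
    shift_m <- logit_clip(target, 0.01) - logit_clip(base, 0.01)
    names(shift_m) <- sig_ids
  }

  set.seed(cs[2])
  sheet <- data.frame(
    sample_id = sprintf("%s_%03d", group, seq_len(n)),
    group = group,
    age = round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 1),
    sex = ifelse(stats::runif(n) < cfg$sex_ratio, "F", "M"),
    stringsAsFactors = FALSE)

  set.seed(cs[3])
  M <- matrix(cohort$truth$baseline_m, length(probe_ids), n,
              dimnames = list(probe_ids, sheet$sample_id))
  if (length(sig_ids)) M[sig_ids, ] <- M[sig_ids, ] + shift_m
  age_ids <- cohort$truth$age_probe_ids
  if (length(age_ids) && cfg$age_slope != 0)
    M[age_ids, ] <- M[age_ids, ] +
      outer(rep(cfg$age_slope, length(age_ids)),
            sheet$age - mean(cfg$age_range))
  sex_ids <- cohort$truth$sex_probe_ids
  if (length(sex_ids) && cfg$sex_shift != 0) {
    f_cols <- which(sheet$sex == "F")
    M[sex_ids, f_cols] <- M[sex_ids, f_cols] + cfg$sex_shift
  }
  M <- M + matrix(stats::rnorm(length(M), 0, cfg$noise_sd), nrow(M), ncol(M))
  list(beta = m_to_beta(M), sheet = sheet,
       truth = list(signature_probe_ids = sig_ids,
                    signature_shift_m = shift_m))
}
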