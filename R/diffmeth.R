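#' Estimate an empirical-Bayes variance prior
#'
#' Fits a scaled inverse chi-square prior to per-probe residual variances by
#' the method of moments on the log-variance scale. Writing the sampling
#' model as s2 ~ s0_sq * F(df_residual, d0), the mean and variance of
#' log(s2) identify (d0, s0_sq) through digamma/trigamma functions; d0 is
#' obtained by inverting the trigamma equation numerically. When the
#' observed spread of log variances does not exceed what chi-square sampling
#' alone explains, d0 = Inf and s0_sq is the common variance.
#'
#' @param sample_variances Per-probe residual variances (length >= 10).
#' @param df_residual Residual degrees of freedom of each variance
#'   (n1 + n2 - 2 for a two-group comparison).
#' @return A list of class \code{ebayes_prior} with \code{d0} (prior degrees
#'   of freedom, possibly \code{Inf}) and \code{s0_sq} (prior variance).
#' @export
estimate_prior <- function(sample_variances, df_residual) {
  s2 <- sample_variances
  if (length(s2) < 10) stop("need at least 10 variances to estimate a prior")
  if (df_residual < 1) stop("df_residual must be >= 1")
  if (any(s2 < 0)) stop("variances must be nonnegative")
  pos <- s2 > 0
  if (!any(pos)) stop("all variances are zero; degenerate data")
  if (!all(pos)) {
    warning(sum(!pos), " zero variance(s) excluded from prior estimation")
    s2 <- s2[pos]
    if (length(s2) < 10) stop("fewer than 10 positive variances")
  }
  z <- log(s2)
  mean_z <- mean(z)
  var_z <- stats::var(z)
  excess <- var_z - trigamma(df_residual / 2)
  bias_df <- digamma(df_residual / 2) - log(df_residual / 2)
  if (var_z < 1e-12) {
    # variances numerically identical: no dispersion at all, take them at
    # face value rather than bias-correcting for chi-square sampling
    return(structure(list(d0 = Inf, s0_sq = exp(mean_z)),
                     class = "ebayes_prior"))
  }
  if (excess <= trigamma(1e7 / 2)) {   # indistinguishable from no dispersion
    d0 <- Inf
    s0_sq <- exp(mean_z - bias_df)
  } else {
    half_d0 <- stats::uniroot(function(x) trigamma(x) - excess,
                              lower = 1e-8, upper = 1e7 / 2,
                              tol = 1e-12)$root
    d0 <- 2 * half_d0
    s0_sq <- exp(mean_z - bias_df + digamma(half_d0) - log(half_d0))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("Empirical-Bayes variance prior: d0 = %s, s0^2 = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-statistic for one probe
#'
#' Pooled within-group variance with d_g = n1 + n2 - 2 degrees of freedom is
#' shrunk toward the prior: \code{s_tilde^2 = (d0 s0^2 + d_g s_g^2) /
#' (d0 + d_g)}; the statistic is the mean difference divided by
#' \code{s_tilde * sqrt(1/n1 + 1/n2)} and is referred to a t distribution on
#' d0 + d_g degrees of freedom (standard normal when d0 is infinite). With
#' d0 = 0 this is the ordinary pooled two-sample t-test.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each),
#'   typically M-values for one probe.
#' @param prior An [estimate_prior()] result (or list with \code{d0},
#'   \code{s0_sq}).
#' @return A list: \code{t_moderated}, \code{p_value} (two-sided),
#'   \code{delta} (case minus control mean on the input scale), and
#'   \code{zero_variance} flag. A zero posterior variance with a nonzero
#'   mean difference yields p = 0 and a warning flag rather than an error.
#' @export
moderated_t <- function(case_values, control_values, prior) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  dg <- n1 + n2 - 2
  sg2 <- ((n1 - 1) * stats::var(case_values) +
          (n2 - 1) * stats::var(control_values)) / dg
  out <- .moderated_from_moments(mean(case_values) - mean(control_values),
                                 sg2, n1, n2, prior)
  if (out$zero_variance)
    warning("zero posterior variance; p-value set to 0")
  out
}

# Vectorised core shared by moderated_t and derive_signature.
.moderated_from_moments <- function(diff, sg2, n1, n2, prior) {
  dg <- n1 + n2 - 2
  d0 <- prior$d0; s0 <- prior$s0_sq
  post <- if (is.finite(d0)) (d0 * s0 + dg * sg2) / (d0 + dg)
          else rep(s0, length(sg2))
  se <- sqrt(post * (1 / n1 + 1 / n2))
  zero <- se == 0
  t <- ifelse(zero, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  df_total <- d0 + dg          # pt handles df = Inf as the normal limit
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[zero & diff != 0] <- 0
  p[zero & diff == 0] <- 1
  list(t_moderated = t, p_value = p, delta = diff,
       zero_variance = if (length(t) == 1L) zero[1] else zero)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Probe-selection configuration
#'
#' @param alpha BH-adjusted significance threshold. Default 0.01.
#' @param min_abs_delta_beta Minimum absolute case-control mean beta
#'   difference. Default 0.10.
#' @param max_probes Cap on the ranked list before pruning. Default 1000.
#' @param prune_r Absolute Pearson correlation threshold above which a
#'   lower-ranked probe is discarded. Default 0.90.
#' @return A list of class \code{select_config}.
#' @export
select_config <- function(alpha = 0.01, min_abs_delta_beta = 0.10,
                          max_probes = 1000, prune_r = 0.90) {
  stopifnot(alpha > 0, alpha < 1, min_abs_delta_beta >= 0,
            min_abs_delta_beta <= 1, max_probes >= 1, prune_r > 0,
            prune_r <= 1)
  structure(list(alpha = alpha, min_abs_delta_beta = min_abs_delta_beta,
                 max_probes = max_probes, prune_r = prune_r),
            class = "select_config")
}

#' Filter and rank candidate probes
#'
#' Keeps probes with \code{p_adjusted < alpha} and \code{|delta_beta| >=
#' min_abs_delta_beta}, ranks them by \code{|t_moderated| * |delta_beta|}
#' (descending, ties broken by probe id), and truncates to
#' \code{max_probes}.
#'
#' @param stats Data.frame with columns \code{probe_id}, \code{delta_beta},
#'   \code{t_moderated}, \code{p_value}, \code{p_adjusted}.
#' @param cfg A [select_config()].
#' @return The qualifying rows, ordered, with a \code{rank} column
#'   (1-based, contiguous). May be empty.
#' @export
select_probes <- function(stats, cfg = select_config()) {
  stopifnot(inherits(cfg, "select_config"),
            all(c("probe_id", "delta_beta", "t_moderated", "p_value",
                  "p_adjusted") %in% names(stats)))
  keep <- stats$p_adjusted < cfg$alpha &
    abs(stats$delta_beta) >= cfg$min_abs_delta_beta
  out <- stats[keep, , drop = FALSE]
  if (nrow(out)) {
    score <- abs(out$t_moderated) * abs(out$delta_beta)
    out <- out[order(-score, out$probe_id), , drop = FALSE]
    out <- utils::head(out, cfg$max_probes)
    out$rank <- seq_len(nrow(out))
  } else {
    out$rank <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Prune correlated probes from a ranked list
#'
#' Greedy top-down pruning: a probe is kept iff its absolute Pearson
#' correlation (beta scale, across the supplied samples) with every
#' already-kept probe is below \code{prune_r}. When \code{groups} is given,
#' values are centred within group first, so the correlation measures
#' probe-probe dependence (co-methylation) net of the shared group effect
#' rather than the group effect itself. Probes with zero variance are
#' treated as correlation 0 (kept-eligible) with a warning.
#'
#' @param selected Ranked probe data.frame from [select_probes()].
#' @param m Beta matrix over the training samples, covering all selected
#'   probes.
#' @param prune_r Absolute correlation threshold in (0, 1\].
#' @param groups Optional per-sample group labels (same order as
#'   \code{colnames(m)}) for within-group centring.
#' @return The kept rows, with ranks renumbered contiguously from 1.
#' @export
prune_correlated <- function(selected, m, prune_r = 0.90, groups = NULL) {
  stopifnot(prune_r > 0, prune_r <= 1)
  if (!nrow(selected)) return(selected)
  missing_p <- setdiff(selected$probe_id, rownames(m))
  if (length(missing_p))
    stop("selected probe(s) absent from matrix: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  X <- t(m[selected$probe_id, , drop = FALSE])
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(m))
    for (g in unique(groups)) {
      rows <- groups == g
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                         colMeans(X[rows, , drop = FALSE]))
    }
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " probe(s) with zero variance in training ",
            "samples; treated as uncorrelated")
  kept <- integer(0)
  for (i in seq_len(ncol(X))) {
    if (length(kept) && sds[i] > 0) {
      comparable <- kept[sds[kept] > 0]
      if (length(comparable)) {
        r <- abs(stats::cor(X[, i], X[, comparable, drop = FALSE]))
        if (any(r >= prune_r)) next
      }
    }
    kept <- c(kept, i)
  }
  out <- selected[kept, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Derive a methylation episignature from cases and controls
#'
#' The full differential-methylation path: control-based median imputation
#' and probe QC, M-value transform, empirical-Bayes variance prior,
#' per-probe moderated t-statistics (effect sizes on the beta scale),
#' Benjamini-Hochberg correction, significance/effect filtering and
#' ranking, and greedy correlation pruning (within-group centred) to an
#' independent probe set.
#'
#' @param m Beta matrix covering cases and controls.
#' @param sheet Sample sheet covering at least those samples.
#' @param case_ids,control_ids Disjoint sample id vectors present in
#'   \code{m}.
#' @param cfg A [select_config()].
#' @param qc A [qc_config()].
#' @param manifest Optional probe manifest for sex-chromosome filtering.
#' @return An object of class \code{episignature}: \code{probes} (ranked
#'   data.frame of probe_id, delta_beta, t_moderated, p_value, p_adjusted,
#'   rank), \code{prior}, and \code{provenance} (ids, configs, counts at
#'   each stage, warnings).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_probes = 800,
#'   n_signature_probes = 20, n_controls = 40, n_reference = 0, seed = 7))
#' sig <- derive_signature(sim$beta, sim$sheet,
#'   case_ids = sim$sheet$sample_id[sim$sheet$group == "case"],
#'   control_ids = sim$sheet$sample_id[sim$sheet$group == "control"])
#' print(sig)
#' @export
derive_signature <- function(m, sheet, case_ids, control_ids,
                             cfg = select_config(), qc = qc_config(),
                             manifest = NULL) {
  validate_beta_matrix(m)
  validate_sample_sheet(sheet)
  stopifnot(inherits(cfg, "select_config"), inherits(qc, "qc_config"))
  ids <- c(case_ids, control_ids)
  if (length(intersect(case_ids, control_ids)))
    stop("case and control ids overlap")
  absent <- setdiff(ids, colnames(m))
  if (length(absent))
    stop("sample id(s) absent from matrix: ", paste(absent, collapse = ", "))
  if (length(case_ids) < 2 || length(control_ids) < 2)
    stop("need at least 2 cases and 2 controls")
  warnings <- character(0)
  train <- m[, ids, drop = FALSE]

  qcres <- qc_filter(train, qc, manifest)
  train <- qcres$matrix
  if (!nrow(train)) stop("diffmeth: no probes survive QC")
  train <- withCallingHandlers(
    impute_missing(train, control_ids),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  M <- beta_to_m(train, qc$epsilon)

  ci <- match(case_ids, colnames(M)); oi <- match(control_ids, colnames(M))
  n1 <- length(ci); n2 <- length(oi)
  mean1 <- rowMeans(M[, ci, drop = FALSE])
  mean0 <- rowMeans(M[, oi, drop = FALSE])
  v1 <- rowSums((M[, ci, drop = FALSE] - mean1)^2) / (n1 - 1)
  v0 <- rowSums((M[, oi, drop = FALSE] - mean0)^2) / (n2 - 1)
  dg <- n1 + n2 - 2
  sg2 <- ((n1 - 1) * v1 + (n2 - 1) * v0) / dg

  prior <- withCallingHandlers(
    estimate_prior(sg2, dg),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  mod <- .moderated_from_moments(mean1 - mean0, sg2, n1, n2, prior)
  if (any(mod$zero_variance))
    warnings <- c(warnings, paste0(sum(mod$zero_variance),
                                   " probe(s) with zero posterior variance"))
  delta_beta <- rowMeans(train[, ci, drop = FALSE]) -
    rowMeans(train[, oi, drop = FALSE])
  stats_df <- data.frame(probe_id = rownames(train),
                         delta_beta = unname(delta_beta),
                         t_moderated = unname(mod$t_moderated),
                         p_value = unname(mod$p_value),
                         p_adjusted = bh_adjust(unname(mod$p_value)),
                         stringsAsFactors = FALSE)

  selected <- select_probes(stats_df, cfg)
  groups <- ifelse(colnames(train) %in% case_ids, "case", "control")
  pruned <- withCallingHandlers(
    prune_correlated(selected, train, cfg$prune_r, groups = groups),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  counts <- c(probes_in = nrow(m), qc_pass = nrow(train),
              significant = sum(stats_df$p_adjusted < cfg$alpha),
              effect_filtered = nrow(selected), pruned = nrow(pruned))
  structure(list(probes = pruned, prior = prior,
                 provenance = list(case_ids = case_ids,
                                   control_ids = control_ids,
                                   select_config = unclass(cfg),
                                   qc_config = unclass(qc),
                                   qc_removed = qcres$report,
                                   counts = counts,
                                   warnings = warnings)),
            class = "episignature")
}

#' @export
print.episignature <- function(x, ...) {
  cn <- x$provenance$counts
  cat("Methylation episignature\n")
  cat(sprintf("  %d probes (from %d input, %d post-QC, %d significant, %d after effect filter)\n",
              nrow(x$probes), cn["probes_in"], cn["qc_pass"],
              cn["significant"], cn["effect_filtered"]))
  cat(sprintf("  groups: %d cases vs %d controls; prior d0 = %s, s0^2 = %.4g\n",
              length(x$provenance$case_ids), length(x$provenance$control_ids),
              format(x$prior$d0), x$prior$s0_sq))
  if (nrow(x$probes)) {
    cat("  top probes:\n")
    print(utils::head(x$probes, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.episignature <- function(object, ...) {
  p <- object$probes
  res <- list(n_probes = nrow(p),
              counts = object$provenance$counts,
              prior = object$prior,
              delta_beta_range = if (nrow(p)) range(p$delta_beta) else c(NA, NA),
              n_hyper = sum(p$delta_beta > 0), n_hypo = sum(p$delta_beta < 0),
              warnings = object$provenance$warnings)
  class(res) <- "summary.episignature"
  res
}

#' @export
print.summary.episignature <- function(x, ...) {
  cat(sprintf("Episignature of %d probes (%d hyper-, %d hypomethylated in cases)\n",
              x$n_probes, x$n_hyper, x$n_hypo))
  cat("  stage counts: ", paste(names(x$counts), x$counts, sep = "=",
                                collapse = ", "), "\n")
  if (x$n_probes)
    cat(sprintf("  delta beta range: [%.3f, %.3f]\n",
                x$delta_beta_range[1], x$delta_beta_range[2]))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.episignature <- function(x, ...) x$probes

#' Volcano plot of an episignature derivation
#'
#' Plots per-probe effect size against significance for the retained probes.
#'
#' @param x An \code{episignature}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.episignature <- function(x, ...) {
  p <- x$probes
  if (!nrow(p)) {
    graphics::plot.new()
    graphics::title(main = "Empty episignature")
    return(invisible(x))
  }
  lp <- -log10(pmax(p$p_value, 1e-300))
  graphics::plot(p$delta_beta, lp, xlab = expression(Delta * beta),
                 ylab = expression(-log[10] ~ p), pch = 19,
                 col = ifelse(p$delta_beta > 0, "firebrick", "navy"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write an episignature probe table to TSV
#'
#' Columns: probe_id, delta_beta, t_moderated, p_value, p_adjusted, rank.
#' Provenance is written alongside as JSON when \code{provenance_path} is
#' given.
#'
#' @param sig An \code{episignature} (or its probe data.frame).
#' @param path Output TSV path.
#' @param provenance_path Optional JSON path for the provenance record.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(sig, path, provenance_path = NULL) {
  probes <- if (inherits(sig, "episignature")) sig$probes else sig
  cols <- c("probe_id", "delta_beta", "t_moderated", "p_value",
            "p_adjusted", "rank")
  stopifnot(all(cols %in% names(probes)))
  out <- probes[, cols]
  for (col in c("delta_beta", "t_moderated", "p_value", "p_adjusted"))
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(provenance_path) && inherits(sig, "episignature"))
    jsonlite::write_json(
      list(prior = unclass(sig$prior),
           provenance = sig$provenance[setdiff(names(sig$provenance),
                                               "qc_removed")]),
      provenance_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an episignature probe table written by [write_signature()]
#' @param path TSV path.
#' @return A probe data.frame ordered by rank.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cols <- c("probe_id", "delta_beta", "t_moderated", "p_value",
            "p_adjusted", "rank")
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols))
    stop("signature file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dat[order(dat$rank), cols]
}
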