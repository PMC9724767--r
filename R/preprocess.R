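#' Clamped log2 logit of a beta value
#'
#' Maps a methylation fraction to the M-value scale:
#' \code{log2(b / (1 - b))} after clamping \code{b} into
#' \code{[epsilon, 1 - epsilon]}. The clamp keeps fully (un)methylated
#' probes finite.
#'
#' @param beta Numeric vector/matrix of values in \[0, 1\] (NA allowed).
#' @param epsilon Clamp bound, in (0, 0.5). Default 0.01.
#' @return Object of the same shape on the M-value (log2 odds) scale.
#' @examples
#' logit_clip(0.5)            # 0
#' logit_clip(0.8)            # 2 = log2(4)
#' @export
logit_clip <- function(beta, epsilon = 0.01) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be a single number in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert a beta matrix to M-values
#'
#' Elementwise [logit_clip()]; probe/sample ids and missing cells are
#' preserved. Statistics downstream are computed on this scale, effect
#' sizes on the beta scale.
#'
#' @param m Beta matrix (probes x samples).
#' @param epsilon Clamp bound passed to [logit_clip()].
#' @return Numeric matrix of M-values with the same dimnames.
#' @export
beta_to_m <- function(m, epsilon = 0.01) {
  validate_beta_matrix(m)
  out <- logit_clip(m, epsilon)
  dimnames(out) <- dimnames(m)
  out
}

#' Convert M-values back to beta values
#' @param m Matrix or vector on the M-value scale.
#' @return Values mapped through the inverse logit \code{2^m / (1 + 2^m)}.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Probe-QC configuration
#'
#' @param max_missing_fraction Drop probes whose missing fraction exceeds
#'   this. Default 0.05.
#' @param drop_zero_variance Drop probes constant across samples. Default TRUE.
#' @param drop_sex_chromosomes Drop X/Y probes (requires a manifest).
#'   Default FALSE.
#' @param epsilon Logit clamp used downstream. Default 0.01.
#' @return A list of class \code{qc_config}.
#' @export
qc_config <- function(max_missing_fraction = 0.05, drop_zero_variance = TRUE,
                      drop_sex_chromosomes = FALSE, epsilon = 0.01) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            is.logical(drop_zero_variance), is.logical(drop_sex_chromosomes),
            epsilon > 0, epsilon < 0.5)
  structure(list(max_missing_fraction = max_missing_fraction,
                 drop_zero_variance = drop_zero_variance,
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 epsilon = epsilon),
            class = "qc_config")
}

#' Filter probes by QC rules
#'
#' Removes probes with too many missing values, zero-variance probes, and
#' (optionally) sex-chromosome probes. Samples are never removed. The
#' operation is idempotent.
#'
#' @param m Beta matrix.
#' @param cfg A [qc_config()].
#' @param manifest Optional probe manifest data.frame (\code{probe_id},
#'   \code{chromosome}); required when \code{drop_sex_chromosomes} is TRUE
#'   and must cover every probe.
#' @return A list with \code{matrix} (the filtered beta matrix) and
#'   \code{report}, a data.frame of removed probes with a \code{reason}
#'   column (\code{missing_fraction}, \code{zero_variance},
#'   \code{sex_chromosome}).
#' @export
qc_filter <- function(m, cfg = qc_config(), manifest = NULL) {
  validate_beta_matrix(m)
  stopifnot(inherits(cfg, "qc_config"))
  removed <- character(0); reason <- character(0)
  miss <- rowMeans(is.na(m))
  drop_miss <- miss > cfg$max_missing_fraction
  if (cfg$drop_sex_chromosomes) {
    if (is.null(manifest))
      stop("drop_sex_chromosomes requires a probe manifest")
    idx <- match(rownames(m), manifest$probe_id)
    if (anyNA(idx))
      stop("manifest does not cover probe '",
           rownames(m)[which(is.na(idx))[1]], "'")
    sexchr <- manifest$chromosome[idx] %in% c("X", "Y", "chrX", "chrY")
  } else sexchr <- rep(FALSE, nrow(m))
  if (cfg$drop_zero_variance) {
    v <- apply(m, 1, stats::var, na.rm = TRUE)
    zerovar <- !is.na(v) & v == 0
    # a probe with a single non-missing value has undefined variance; keep
    zerovar[is.na(v)] <- FALSE
  } else zerovar <- rep(FALSE, nrow(m))
  # report one reason per probe, in rule order
  for (i in which(drop_miss | zerovar | sexchr)) {
    removed <- c(removed, rownames(m)[i])
    reason <- c(reason, if (drop_miss[i]) "missing_fraction"
                else if (zerovar[i]) "zero_variance" else "sex_chromosome")
  }
  keep <- !(drop_miss | zerovar | sexchr)
  list(matrix = m[keep, , drop = FALSE],
       report = data.frame(probe_id = removed, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Impute missing beta values from reference samples
#'
#' Each missing cell is replaced by the median of its probe over the
#' reference samples (typically controls, so that case signal never leaks
#' into imputed values). Deterministic.
#'
#' @param m Beta matrix.
#' @param reference_sample_ids Sample ids used to compute per-probe medians;
#'   every probe must have at least one non-missing reference value.
#' @return The beta matrix with no missing values.
#' @export
impute_missing <- function(m, reference_sample_ids) {
  validate_beta_matrix(m)
  missing_ref <- setdiff(reference_sample_ids, colnames(m))
  if (length(missing_ref))
    stop("reference sample(s) not in matrix: ",
         paste(missing_ref, collapse = ", "))
  if (!anyNA(m)) return(m)
  ref <- m[, reference_sample_ids, drop = FALSE]
  med <- apply(ref, 1, stats::median, na.rm = TRUE)
  if (anyNA(med))
    stop("probe '", rownames(m)[which(is.na(med))[1]],
         "' has no non-missing value among reference samples")
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- med[idx[, 1]]
  m
}
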