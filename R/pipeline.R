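# Deterministic hash of a configuration object (canonical JSON -> md5).
.hash_config <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Accept an episignature object, probe data.frame, or probe id vector.
.signature_probe_ids <- function(signature) {
  if (inherits(signature, "episignature")) signature$probes$probe_id
  else if (is.data.frame(signature)) signature$probe_id
  else as.character(signature)
}

#' Stage A: score query samples against an existing episignature
#'
#' The first analysis step for a new case series: their methylation
#' profiles are placed in the context of an established episignature by
#' (i) computing calibrated classifier scores and three-band calls and
#' (ii) embedding the queries together with the reference cohort by
#' classical MDS on Euclidean distances over the signature probes. The
#' reference signature and model are never modified.
#'
#' @param query_beta Beta matrix of the query samples.
#' @param reference_beta Beta matrix of the reference cohort (same probe
#'   universe).
#' @param reference_sheet Sample sheet for the reference cohort.
#' @param signature The reference episignature (\code{episignature},
#'   probe data.frame, or probe id vector).
#' @param model The trained \code{episvm} for that signature.
#' @param thr [band_thresholds()] for the calls.
#' @param k MDS dimensions. Default 2.
#' @param out_dir Optional directory; when given, writes
#'   \code{classification.json}, \code{embedding.tsv} and
#'   \code{metrics.json}.
#' @return A list of class \code{stage_a_report}: \code{calls} (sample_id,
#'   score, band), \code{embedding}, \code{metrics}, \code{provenance}.
#' @export
run_stage_a <- function(query_beta, reference_beta, reference_sheet,
                        signature, model, thr = band_thresholds(), k = 2,
                        out_dir = NULL) {
  validate_beta_matrix(query_beta)
  validate_beta_matrix(reference_beta)
  check_samples_match(reference_beta, reference_sheet)
  probe_ids <- .signature_probe_ids(signature)
  if (!length(probe_ids)) stop("reference signature is empty")
  clash <- intersect(colnames(query_beta), colnames(reference_beta))
  if (length(clash))
    stop("query and reference share sample id(s): ",
         paste(utils::head(clash, 5), collapse = ", "))
  missing_q <- setdiff(probe_ids, rownames(query_beta))
  missing_r <- setdiff(probe_ids, rownames(reference_beta))
  if (length(missing_q) || length(missing_r))
    stop("signature probes absent; query lacks ", length(missing_q),
         ", reference lacks ", length(missing_r))

  score <- score_samples(model, query_beta)
  calls <- data.frame(sample_id = names(score), score = unname(score),
                      band = unname(assign_band(score, thr)),
                      stringsAsFactors = FALSE)

  combined <- cbind(reference_beta[probe_ids, , drop = FALSE],
                    query_beta[probe_ids, , drop = FALSE])
  emb <- classical_mds(euclidean_distances(combined), k = k)
  sheet_ord <- reference_sheet[match(colnames(reference_beta),
                                     reference_sheet$sample_id), ]
  labels <- c(sheet_ord$group, rep("query", ncol(query_beta)))
  metrics <- separation_metrics(emb, labels)

  report <- structure(
    list(calls = calls, embedding = emb, metrics = metrics,
         provenance = list(
           n_signature_probes = length(probe_ids),
           nu = model$nu, k = k,
           thresholds = unclass(thr),
           config_hash = .hash_config(list(probes = probe_ids,
                                           nu = model$nu, k = k,
                                           thr = unclass(thr))))),
    class = "stage_a_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_classification_report(calls, file.path(out_dir, "classification.json"))
    write_embedding(emb, file.path(out_dir, "embedding.tsv"))
    jsonlite::write_json(
      list(mean_silhouette = metrics$mean_silhouette,
           group_silhouette = as.list(metrics$group_silhouette),
           centroid_spread_ratio = metrics$centroid_spread_ratio,
           provenance = report$provenance),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.stage_a_report <- function(x, ...) {
  cat("Stage A report: query samples vs reference episignature\n")
  cat(sprintf("  %d query samples; bands: %s\n", nrow(x$calls),
              paste(names(table(x$calls$band)), table(x$calls$band),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  mean silhouette across groups: %.3f\n",
              x$metrics$mean_silhouette))
  invisible(x)
}

#' Stage B: derive and validate a new episignature
#'
#' The second analysis step: starting from a case series and a control
#' pool, selects age- and sex-matched controls (unless explicit control ids
#' are given), derives the differential-methylation signature, validates it
#' by MDS of cases + matched controls + background cohort restricted to the
#' signature probes with cluster-separation metrics, and optionally trains
#' an episignature classifier on the result. All randomness (matching
#' tie-breaks, train/test split, CV folds) is funnelled through
#' \code{seed}; two runs with identical inputs, configuration and seed
#' write byte-identical outputs.
#'
#' @param beta Beta matrix covering all samples involved.
#' @param sheet Sample sheet covering the matrix columns.
#' @param case_ids Case sample ids (order defines matching priority).
#' @param control_ids Optional explicit control ids; when \code{NULL},
#'   controls are matched from \code{pool_ids}.
#' @param pool_ids Candidate control pool; default: samples with group
#'   \code{"control"} that are not cases.
#' @param background_ids Validation background; default: all samples that
#'   are neither cases nor selected controls.
#' @param match_cfg,select_cfg,qc_cfg,train_cfg Stage configurations.
#' @param train Train a classifier on the derived signature. Default FALSE.
#' @param thr Band thresholds recorded with a trained classifier.
#' @param k MDS dimensions. Default 2.
#' @param seed Integer master seed.
#' @param out_dir Optional output directory; writes \code{signature.tsv},
#'   \code{signature_provenance.json}, \code{match_table.tsv},
#'   \code{embedding.tsv}, \code{metrics.json}, \code{report.json} and,
#'   when trained, \code{model.json}.
#' @return A list of class \code{stage_b_report}: \code{signature},
#'   \code{match_table}, \code{embedding}, \code{metrics}, \code{model}
#'   (or NULL), \code{provenance}.
#' @export
run_stage_b <- function(beta, sheet, case_ids, control_ids = NULL,
                        pool_ids = NULL, background_ids = NULL,
                        match_cfg = match_config(),
                        select_cfg = select_config(), qc_cfg = qc_config(),
                        train = FALSE, train_cfg = train_config(),
                        thr = band_thresholds(), k = 2, seed = 1,
                        out_dir = NULL) {
  validate_beta_matrix(beta)
  validate_sample_sheet(sheet)
  absent <- setdiff(case_ids, colnames(beta))
  if (length(absent))
    stop("case id(s) absent from matrix: ", paste(absent, collapse = ", "))
  cs <- .child_seeds(seed, 2L)

  match_table <- NULL
  if (is.null(control_ids)) {
    if (is.null(pool_ids))
      pool_ids <- setdiff(sheet$sample_id[sheet$group == "control"], case_ids)
    mc <- match_cfg; mc$seed <- cs[1]
    matched <- select_matched_controls(
      sheet[match(case_ids, sheet$sample_id), , drop = FALSE],
      sheet[match(pool_ids, sheet$sample_id), , drop = FALSE], mc)
    control_ids <- matched$control_ids
    match_table <- matched$match_table
  }
  if (is.null(background_ids))
    background_ids <- setdiff(colnames(beta), c(case_ids, control_ids))

  signature <- derive_signature(beta, sheet, case_ids, control_ids,
                                cfg = select_cfg, qc = qc_cfg)

  embedding <- NULL; metrics <- NULL; model <- NULL
  if (nrow(signature$probes)) {
    ids <- c(case_ids, control_ids, background_ids)
    sub <- beta[signature$probes$probe_id, ids, drop = FALSE]
    if (anyNA(sub))
      sub <- impute_missing(sub, control_ids)
    embedding <- classical_mds(euclidean_distances(sub), k = k)
    labels <- ifelse(ids %in% case_ids, "case", "non_case")
    metrics <- separation_metrics(embedding, labels)
    if (train) {
      # the classifier is trained on the derivation cohort (cases + matched
      # controls): the balanced design keeps the nu grid feasible, and the
      # model is then applicable to background/query samples
      tc <- train_cfg; tc$seed <- cs[2]
      tr_ids <- c(case_ids, control_ids)
      model_labels <- ifelse(tr_ids %in% case_ids, "case", "other")
      model <- train_classifier(sub[, tr_ids, drop = FALSE], model_labels,
                                tc, positive = "case")
    }
  }

  config_hash <- .hash_config(list(select = unclass(select_cfg),
                                   qc = unclass(qc_cfg),
                                   match = unclass(match_cfg),
                                   train = if (train) unclass(train_cfg),
                                   k = k, seed = seed))
  report <- structure(
    list(signature = signature, match_table = match_table,
         embedding = embedding, metrics = metrics, model = model,
         provenance = list(seed = seed, config_hash = config_hash,
                           case_ids = case_ids, control_ids = control_ids,
                           n_background = length(background_ids),
                           counts = signature$provenance$counts,
                           empty_signature = nrow(signature$probes) == 0)),
    class = "stage_b_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature(signature, file.path(out_dir, "signature.tsv"),
                    file.path(out_dir, "signature_provenance.json"))
    if (!is.null(match_table))
      utils::write.table(match_table, file.path(out_dir, "match_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(embedding)) {
      write_embedding(embedding, file.path(out_dir, "embedding.tsv"))
      jsonlite::write_json(
        list(mean_silhouette = metrics$mean_silhouette,
             group_silhouette = as.list(metrics$group_silhouette),
             centroid_spread_ratio = metrics$centroid_spread_ratio),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }
    if (!is.null(model))
      write_classifier(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash,
           n_signature_probes = nrow(signature$probes),
           counts = as.list(signature$provenance$counts),
           empty_signature = nrow(signature$probes) == 0,
           mean_silhouette = if (!is.null(metrics)) metrics$mean_silhouette,
           message = if (nrow(signature$probes) == 0)
             "no probes passed selection; signature is empty"),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.stage_b_report <- function(x, ...) {
  cat("Stage B report: episignature derivation and validation\n")
  cat(sprintf("  signature: %d probes (%s)\n", nrow(x$signature$probes),
              if (x$provenance$empty_signature) "EMPTY" else "derived"))
  if (!is.null(x$metrics))
    cat(sprintf("  case vs rest mean silhouette: %.3f (centroid/spread %.2f)\n",
                x$metrics$mean_silhouette, x$metrics$centroid_spread_ratio))
  if (!is.null(x$model))
    cat(sprintf("  classifier: nu = %g, test accuracy %.3f\n", x$model$nu,
                x$model$provenance$test_accuracy))
  invisible(x)
}
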