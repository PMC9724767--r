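#' Classifier training configuration
#'
#' @param test_fraction Held-out test fraction. Default 0.25.
#' @param cv_folds Cross-validation folds on the training portion.
#'   Default 5.
#' @param nu_grid Candidate nu values for the nu-parameterised SVM, each in
#'   (0, 1). Default c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50).
#' @param seed Integer seed controlling the split and folds.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(test_fraction = 0.25, cv_folds = 5,
                         nu_grid = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50),
                         seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            all(nu_grid > 0), all(nu_grid < 1), length(nu_grid) >= 1)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 nu_grid = sort(nu_grid), seed = as.integer(seed)),
            class = "train_config")
}

#' Score band thresholds
#'
#' Classifier scores below \code{control_below} are called \code{control},
#' scores above \code{pathogenic_above} are called \code{pathogenic}, and
#' everything in between (boundaries included) is \code{inconclusive}.
#'
#' @param control_below Lower threshold. Default 0.25.
#' @param pathogenic_above Upper threshold. Default 0.5.
#' @return A list of class \code{band_thresholds}.
#' @export
band_thresholds <- function(control_below = 0.25, pathogenic_above = 0.5) {
  stopifnot(control_below > 0, control_below < pathogenic_above,
            pathogenic_above < 1)
  structure(list(control_below = control_below,
                 pathogenic_above = pathogenic_above),
            class = "band_thresholds")
}

#' Assign the three-band call from a classifier score
#'
#' @param score Numeric vector of scores in \[0, 1\].
#' @param thr A [band_thresholds()].
#' @return Character vector over \code{control}, \code{inconclusive},
#'   \code{pathogenic}.
#' @examples
#' assign_band(c(0.20, 0.40, 0.60))  # control, inconclusive, pathogenic
#' assign_band(c(0.25, 0.50))        # both inconclusive
#' @export
assign_band <- function(score, thr = band_thresholds()) {
  stopifnot(inherits(thr, "band_thresholds"))
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]")
  ifelse(score < thr$control_below, "control",
         ifelse(score > thr$pathogenic_above, "pathogenic", "inconclusive"))
}

#' Stratified train/test split
#'
#' Splits sample ids into disjoint, exhaustive train and test sets,
#' preserving class proportions to the nearest integer; deterministic given
#' the seed.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Class labels, same length (each class needs >= 2 samples).
#' @param cfg A [train_config()].
#' @return A list with \code{train_ids} and \code{test_ids}.
#' @export
split_train_test <- function(sample_ids, labels, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"),
            length(sample_ids) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 2))
    stop("class '", names(tab)[which(tab < 2)[1]], "' has fewer than 2 samples")
  set.seed(cfg$seed)
  test <- character(0)
  for (cl in names(tab)) {
    ids <- sample_ids[labels == cl]
    n_test <- round(length(ids) * cfg$test_fraction)
    n_test <- max(1L, min(n_test, length(ids) - 1L))
    test <- c(test, sample(ids, n_test))
  }
  list(train_ids = setdiff(sample_ids, test), test_ids = test)
}

# Stratified fold assignment; returns integer folds named by sample id.
.stratified_folds <- function(sample_ids, labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(sample_ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  names(fold) <- sample_ids
  fold
}

# Fit a linear nu-SVM and return an oriented (weights, offset) pair such
# that positive samples have larger margins. Returns NULL if nu infeasible.
.fit_linear_nusvm <- function(X, y, nu) {
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "nu-classification", kernel = "linear",
               nu = nu, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  marg <- drop(X %*% w) + b
  if (mean(marg[y == "pos"]) < mean(marg[y == "neg"])) {
    w <- -w; b <- -b
  }
  list(weights = w, offset = b)
}

# Platt-style sigmoid calibration of margins to [0, 1], with the slope
# constrained nonnegative so the score is monotone in the margin.
.fit_platt <- function(margins, is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  t_target <- ifelse(is_pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- exp(par[1]) * margins + par[2]
    -sum(t_target * stats::plogis(z, log.p = TRUE) +
         (1 - t_target) * stats::plogis(-z, log.p = TRUE))
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 500))
  list(slope = exp(opt$par[1]), intercept = opt$par[2])
}

#' Train a calibrated linear nu-SVM episignature classifier
#'
#' Splits the samples into a stratified training portion (default 75%) and
#' held-out test portion (25%), runs stratified k-fold cross-validation on
#' the training portion over the nu grid, picks the nu with the best mean
#' CV accuracy (ties to the smallest nu), refits on the full training
#' portion, and fits a monotone Platt-style sigmoid mapping out-of-fold
#' decision margins to \[0, 1\] scores. Held-out test accuracy is recorded
#' in the provenance. nu values infeasible for the class balance are
#' skipped with a warning.
#'
#' @param m Beta matrix restricted to the signature probes (probes x
#'   samples), no missing values.
#' @param labels Per-sample labels, in \code{colnames(m)} order.
#' @param cfg A [train_config()].
#' @param positive Label value treated as episignature-positive; all other
#'   labels are negative. Default \code{"case"}.
#' @return Object of class \code{episvm}: \code{probe_ids},
#'   \code{weights}, \code{offset}, \code{calibration} (slope, intercept),
#'   \code{nu}, and \code{provenance} (seed, split ids, CV accuracy per nu,
#'   skipped nu values, test accuracy).
#' @export
train_classifier <- function(m, labels, cfg = train_config(),
                             positive = "case") {
  validate_beta_matrix(m)
  stopifnot(inherits(cfg, "train_config"), length(labels) == ncol(m))
  if (nrow(m) == 0) stop("signature is empty; nothing to train on")
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  y_all <- factor(ifelse(labels == positive, "pos", "neg"),
                  levels = c("neg", "pos"))
  if (nlevels(droplevels(y_all)) < 2)
    stop("both classes must be present (positive label '", positive, "')")
  ids <- colnames(m)

  split <- split_train_test(ids, as.character(y_all), cfg)
  tr <- split$train_ids
  X <- t(m); rownames(X) <- ids
  y_tr <- y_all[match(tr, ids)]
  fold <- .stratified_folds(tr, as.character(y_tr), cfg$cv_folds,
                            cfg$seed + 1L)

  cv_acc <- rep(NA_real_, length(cfg$nu_grid))
  names(cv_acc) <- cfg$nu_grid
  oof <- vector("list", length(cfg$nu_grid))
  for (j in seq_along(cfg$nu_grid)) {
    nu <- cfg$nu_grid[j]
    acc <- numeric(0); marg <- numeric(0); pos <- logical(0); ok <- TRUE
    for (kf in seq_len(cfg$cv_folds)) {
      in_f <- tr[fold != kf]; out_f <- tr[fold == kf]
      fit <- .fit_linear_nusvm(X[in_f, , drop = FALSE],
                               droplevels(y_all[match(in_f, ids)]), nu)
      if (is.null(fit)) { ok <- FALSE; break }
      mo <- drop(X[out_f, , drop = FALSE] %*% fit$weights) + fit$offset
      pred <- ifelse(mo > 0, "pos", "neg")
      acc <- c(acc, mean(pred == as.character(y_all[match(out_f, ids)])))
      marg <- c(marg, mo)
      pos <- c(pos, y_all[match(out_f, ids)] == "pos")
    }
    if (!ok) next
    cv_acc[j] <- mean(acc)
    oof[[j]] <- list(margins = marg, is_pos = pos)
  }
  skipped <- cfg$nu_grid[is.na(cv_acc)]
  if (length(skipped))
    warning("nu value(s) infeasible for this class balance, skipped: ",
            paste(skipped, collapse = ", "))
  if (all(is.na(cv_acc)))
    stop("no feasible nu in the grid for this class balance")
  best <- which(cv_acc == max(cv_acc, na.rm = TRUE))[1]  # grid sorted: smallest nu wins ties
  nu <- cfg$nu_grid[best]

  fit <- .fit_linear_nusvm(X[tr, , drop = FALSE], droplevels(y_tr), nu)
  if (is.null(fit)) stop("refit at selected nu failed unexpectedly")
  cal <- .fit_platt(oof[[best]]$margins, oof[[best]]$is_pos)

  model <- structure(list(probe_ids = rownames(m),
                          weights = stats::setNames(fit$weights, rownames(m)),
                          offset = fit$offset,
                          calibration = cal, nu = nu,
                          provenance = list(seed = cfg$seed,
                                            train_ids = tr,
                                            test_ids = split$test_ids,
                                            cv_accuracy = cv_acc,
                                            skipped_nu = skipped,
                                            positive = positive)),
                     class = "episvm")
  te <- split$test_ids
  test_marg <- drop(X[te, , drop = FALSE] %*% model$weights) + model$offset
  model$provenance$test_accuracy <-
    mean(ifelse(test_marg > 0, "pos", "neg") ==
           as.character(y_all[match(te, ids)]))
  model
}

#' @export
print.episvm <- function(x, ...) {
  cat("Linear nu-SVM episignature classifier\n")
  cat(sprintf("  %d signature probes; nu = %g (CV accuracy %.3f); test accuracy %.3f\n",
              length(x$probe_ids), x$nu,
              max(x$provenance$cv_accuracy, na.rm = TRUE),
              x$provenance$test_accuracy))
  cat(sprintf("  calibration: score = plogis(%.4g * margin + %.4g)\n",
              x$calibration$slope, x$calibration$intercept))
  invisible(x)
}

#' Score samples with an episignature classifier
#'
#' The decision margin of each sample over the signature probes is mapped
#' through the model's monotone sigmoid calibration to a score in \[0, 1\].
#'
#' @param model An [train_classifier()] result.
#' @param m Beta matrix containing all signature probes (extra probes are
#'   ignored); signature values must not be missing.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
score_samples <- function(model, m) {
  predict(model, m, type = "score")
}

#' Predict method for episignature classifiers
#'
#' @param object An \code{episvm} model.
#' @param m Beta matrix containing the signature probes.
#' @param type \code{"score"} (calibrated \[0, 1\]), \code{"band"}
#'   (three-band call), or \code{"margin"} (raw decision value).
#' @param thr Band thresholds used when \code{type = "band"}.
#' @param ... Ignored.
#' @return Named vector of scores, bands, or margins.
#' @export
predict.episvm <- function(object, m, type = c("score", "band", "margin"),
                           thr = band_thresholds(), ...) {
  type <- match.arg(type)
  validate_beta_matrix(m)
  missing_p <- setdiff(object$probe_ids, rownames(m))
  if (length(missing_p))
    stop("matrix lacks signature probe(s): ",
         paste(utils::head(missing_p, 5), collapse = ", "),
         if (length(missing_p) > 5) sprintf(" (and %d more)",
                                            length(missing_p) - 5) else "")
  sub <- m[object$probe_ids, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- colnames(sub)[colSums(is.na(sub)) > 0]
    stop("missing signature values for sample(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; run impute_missing() first")
  }
  marg <- drop(crossprod(sub, object$weights)) + object$offset
  names(marg) <- colnames(sub)
  if (type == "margin") return(marg)
  score <- stats::plogis(object$calibration$slope * marg +
                           object$calibration$intercept)
  if (type == "score") return(score)
  stats::setNames(assign_band(score, thr), names(score))
}

#' Write an episignature classifier to JSON
#' @param model An \code{episvm}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "episvm"))
  payload <- list(probe_ids = model$probe_ids,
                  weights = unname(model$weights),
                  offset = model$offset,
                  calibration = model$calibration,
                  nu = model$nu,
                  provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an episignature classifier written by [write_classifier()]
#' @param path JSON path.
#' @return An \code{episvm} model.
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) stop("classifier file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(probe_ids = payload$probe_ids,
                 weights = stats::setNames(payload$weights,
                                           payload$probe_ids),
                 offset = payload$offset,
                 calibration = as.list(payload$calibration),
                 nu = payload$nu,
                 provenance = as.list(payload$provenance)),
            class = "episvm")
}
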