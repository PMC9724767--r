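#' Read a beta-value matrix from TSV
#'
#' Beta matrices are stored probes x samples as tab-separated text: a header
#' row whose first field is \code{probe_id} followed by sample identifiers,
#' then one row per probe. Missing values are written as \code{NA}. All
#' values are validated to lie in \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (probes x samples) with probe ids as rownames and
#'   sample ids as colnames.
#' @seealso [write_beta_matrix()], [read_sample_sheet()]
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("beta matrix file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] != "probe_id")
    stop("malformed beta matrix header: first column must be 'probe_id' in ", path)
  dat <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = c("character"),
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = character(0))
  probe_ids <- dat[[1]]
  if (nrow(dat) == 0L) {
    vals <- matrix(numeric(0), 0L, ncol(dat) - 1L,
                   dimnames = list(character(0), names(dat)[-1]))
  } else if (ncol(dat) >= 2L) {
    vals <- vapply(dat[-1], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(dat)))
    vals <- matrix(vals, nrow = nrow(dat),
                   dimnames = list(probe_ids, names(dat)[-1]))
    bad_parse <- which(is.na(vals) & !(as.matrix(dat[-1]) %in% c("NA", "")),
                       arr.ind = TRUE)
    if (nrow(bad_parse))
      stop("non-numeric value at probe '", probe_ids[bad_parse[1, 1]],
           "', sample '", colnames(vals)[bad_parse[1, 2]], "' in ", path)
  } else {
    vals <- matrix(numeric(0), nrow = nrow(dat), ncol = 0,
                   dimnames = list(probe_ids, character(0)))
  }
  validate_beta_matrix(vals)
  vals
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with 15 significant digits so that a write/read round
#' trip preserves them to at least 12 significant digits; missing cells are
#' written as \code{NA}.
#'
#' @param m A validated beta matrix (see [read_beta_matrix()] for the layout).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    if (ncol(m)) {
      body <- matrix(formatC(m, digits = 15, format = "g"), nrow = nrow(m))
      body[is.na(m)] <- "NA"
      lines <- paste(rownames(m), apply(body, 1, paste, collapse = "\t"),
                     sep = "\t")
    } else {
      lines <- rownames(m)
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Validate a beta matrix
#'
#' Checks the container invariants: a numeric matrix with unique, non-empty
#' probe and sample identifiers and all non-missing values in \[0, 1\].
#' Errors name the offending probe/sample.
#'
#' @param m Matrix to validate.
#' @return The matrix, invisibly, if valid.
#' @export
validate_beta_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("beta matrix must be a numeric matrix")
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyNA(rownames(m)) ||
                      any(rownames(m) == "")))
    stop("beta matrix must have non-empty probe ids as rownames")
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyNA(colnames(m)) || any(colnames(m) == "")))
    stop("beta matrix must have non-empty sample ids as colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe id: ", rownames(m)[duplicated(rownames(m))][1])
  if (ncol(m) > 0 && anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1])
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("beta value outside [0,1] at probe '", rownames(m)[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "' (value ",
         m[bad[1, 1], bad[1, 2]], ")")
  invisible(m)
}

#' Read a sample sheet from CSV
#'
#' Requires columns \code{sample_id}, \code{group}, \code{age}, \code{sex};
#' \code{batch} and any extra columns are preserved but ignored by the
#' pipeline. \code{sex} must be \code{F} or \code{M}; \code{age} must be a
#' nonnegative number.
#'
#' @param path Path to a CSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet file not found: ", path)
  dat <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  validate_sample_sheet(dat)
  dat$age <- as.numeric(dat$age)
  dat
}

#' Write a sample sheet to CSV
#' @param sheet A validated sample sheet data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#' @param sheet Data.frame to validate.
#' @return The sheet, invisibly, if valid.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!is.data.frame(sheet)) stop("sample sheet must be a data.frame")
  for (col in c("sample_id", "group", "age", "sex"))
    if (!col %in% names(sheet))
      stop("sample sheet missing required column '", col, "'")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1])
  age <- suppressWarnings(as.numeric(sheet$age))
  if (anyNA(age) || any(age < 0)) {
    i <- which(is.na(age) | age < 0)[1]
    stop("invalid age for sample '", sheet$sample_id[i], "': ", sheet$age[i])
  }
  bad_sex <- !sheet$sex %in% c("F", "M")
  if (any(bad_sex))
    stop("sex must be 'F' or 'M'; sample '",
         sheet$sample_id[which(bad_sex)[1]], "' has '",
         sheet$sex[which(bad_sex)[1]], "'")
  if (any(is.na(sheet$group) | sheet$group == ""))
    stop("empty group label for sample '",
         sheet$sample_id[which(is.na(sheet$group) | sheet$group == "")[1]], "'")
  invisible(sheet)
}

#' Cross-check a beta matrix against a sample sheet
#'
#' The matrix column order is authoritative; the sheet is joined by id. An
#' error listing the symmetric difference is raised when the id sets differ.
#'
#' @param m Beta matrix.
#' @param sheet Sample sheet.
#' @return The sheet reordered to the matrix column order, invisibly.
#' @export
check_samples_match <- function(m, sheet) {
  ms <- colnames(m); ss <- sheet$sample_id
  only_m <- setdiff(ms, ss); only_s <- setdiff(ss, ms)
  if (length(only_m) || length(only_s))
    stop("sample ids differ between matrix and sheet; only in matrix: [",
         paste(only_m, collapse = ", "), "]; only in sheet: [",
         paste(only_s, collapse = ", "), "]")
  invisible(sheet[match(ms, ss), , drop = FALSE])
}

#' Read a probe manifest (probe id, chromosome) from TSV
#' @param path Path to a TSV with columns \code{probe_id}, \code{chromosome}.
#' @return A data.frame with those two columns.
#' @export
read_probe_manifest <- function(path) {
  if (!file.exists(path)) stop("probe manifest file not found: ", path)
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("probe_id", "chromosome"))
    if (!col %in% names(dat)) stop("probe manifest missing column '", col, "'")
  if (anyDuplicated(dat$probe_id))
    stop("duplicate probe_id in manifest: ",
         dat$probe_id[duplicated(dat$probe_id)][1])
  dat
}

#' Write a per-sample classification report to JSON
#'
#' @param report Data.frame with columns \code{sample_id}, \code{score},
#'   \code{band}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_classification_report <- function(report, path) {
  stopifnot(is.data.frame(report),
            all(c("sample_id", "score", "band") %in% names(report)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
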