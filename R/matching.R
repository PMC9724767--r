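#' Control-matching configuration
#'
#' @param ratio Controls per case (positive integer). Default 3, giving 24
#'   controls for an 8-case series; an explicit control list can be supplied
#'   to the pipeline instead to reproduce other counts.
#' @param require_exact_sex Require control sex to equal case sex.
#'   Default TRUE.
#' @param seed Integer seed used only to break exact age-gap ties.
#' @return A list of class \code{match_config}.
#' @export
match_config <- function(ratio = 3, require_exact_sex = TRUE, seed = 1) {
  stopifnot(ratio >= 1, ratio == as.integer(ratio),
            is.logical(require_exact_sex))
  structure(list(ratio = as.integer(ratio),
                 require_exact_sex = require_exact_sex,
                 seed = as.integer(seed)),
            class = "match_config")
}

#' Select age- and sex-matched controls for a case series
#'
#' Greedy matching without replacement: cases are visited in input order and
#' each takes the \code{ratio} sex-compatible pool samples with the smallest
#' absolute age difference. Exact ties are broken by a seeded shuffle, then
#' by sample id, so the result is reproducible and auditable via the
#' returned match table.
#'
#' @param cases Sample sheet rows for the cases.
#' @param pool Sample sheet rows for the candidate controls (disjoint from
#'   the cases).
#' @param cfg A [match_config()].
#' @return A list with \code{control_ids} (character, length
#'   \code{ratio * nrow(cases)}) and \code{match_table}, a data.frame of
#'   \code{case_id}, \code{control_id}, \code{age_gap_years}.
#' @export
select_matched_controls <- function(cases, pool, cfg = match_config()) {
  validate_sample_sheet(cases); validate_sample_sheet(pool)
  stopifnot(inherits(cfg, "match_config"))
  if (length(intersect(cases$sample_id, pool$sample_id)))
    stop("case and pool sample ids overlap")
  set.seed(cfg$seed)
  tiebreak <- stats::runif(nrow(pool))
  used <- rep(FALSE, nrow(pool))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    ok <- !used
    if (cfg$require_exact_sex) ok <- ok & pool$sex == cases$sex[i]
    if (sum(ok) < cfg$ratio)
      stop("insufficient ", if (cfg$require_exact_sex) "sex-matched " else "",
           "pool for case '", cases$sample_id[i], "': need ", cfg$ratio,
           ", have ", sum(ok))
    cand <- which(ok)
    gap <- abs(pool$age[cand] - cases$age[i])
    ord <- cand[order(gap, tiebreak[cand], pool$sample_id[cand])]
    take <- ord[seq_len(cfg$ratio)]
    used[take] <- TRUE
    rows[[i]] <- data.frame(case_id = cases$sample_id[i],
                            control_id = pool$sample_id[take],
                            age_gap_years = abs(pool$age[take] - cases$age[i]),
                            stringsAsFactors = FALSE)
  }
  match_table <- do.call(rbind, rows)
  list(control_ids = match_table$control_id, match_table = match_table)
}
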