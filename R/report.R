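# Summary reporting: percentages in the pipeline's fixed convention
# (round half-up, 2 decimals) and overlap tables against external study
# sets supplied as homology pairs.

#' Percentage, rounded half-up to two decimals
#'
#' `100 * numerator / denominator` rounded half-up to 2 decimal places (the
#' reporting convention used throughout the pipeline; note base R's
#' `round()` rounds half to even instead).
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`. Vectorized.
#' @return numeric percentage value(s) with 2 decimals.
#' @examples
#' percent(1728, 8300)  # 20.82
#' @export
percent <- function(numerator, denominator) {
  stopifnot(all(denominator > 0), all(numerator >= 0),
            all(numerator <= denominator))
  x <- 100 * numerator / denominator
  floor(x * 100 + 0.5) / 100
}

#' Format a percentage as a fixed two-decimal string
#'
#' @inheritParams percent
#' @return character, e.g. `"20.82%"`.
#' @export
percent_label <- function(numerator, denominator) {
  sprintf("%.2f%%", percent(numerator, denominator))
}

#' Assemble the run summary table
#'
#' Collects the pipeline's headline counts and derived percentages into one
#' table in reporting order.
#'
#' @param counts named list of counts; recognized names are `n_traces`,
#'   `n_orfs`, `n_urfs`, `n_forward_unique`, `n_decoy_unique`,
#'   `k_pass_decoy`, `n_forward_pass`, `n_flagged_urfs`, `n_searched_urfs`.
#'   Missing entries are skipped.
#' @return data.frame with columns `metric`, `value`, `percent_of`,
#'   `percent` (NA where no ratio applies).
#' @export
summary_table <- function(counts) {
  ratios <- list(
    n_forward_pass = "n_forward_unique",
    k_pass_decoy = "n_decoy_unique",
    n_flagged_urfs = "n_searched_urfs"
  )
  keep <- intersect(
    c("n_traces", "n_orfs", "n_urfs", "n_searched_urfs", "n_forward_unique",
      "n_decoy_unique", "k_pass_decoy", "n_forward_pass", "n_flagged_urfs"),
    names(counts))
  rows <- lapply(keep, function(m) {
    den_name <- ratios[[m]]
    has_den <- !is.null(den_name) && !is.null(counts[[den_name]])
    data.frame(
      metric = m, value = as.numeric(counts[[m]]),
      percent_of = if (has_den) den_name else NA_character_,
      percent = if (has_den) percent(counts[[m]], counts[[den_name]]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Overlap of candidate sequences with external study sets
#'
#' A candidate counts as overlapping a study set if at least one homology
#' pair links it to that set; the union row counts candidates linked to any
#' set. Homology pairs come from external alignment tools and are consumed
#' as data, not computed.
#'
#' @param candidate_ids character vector of candidate sequence ids.
#' @param homology_pairs data.frame with columns `candidate_id` and `study`.
#'   Pairs whose `candidate_id` is not in `candidate_ids` are skipped with a
#'   warning.
#' @return data.frame with one row per study plus a `"union"` row: `study`,
#'   `n_overlap`, `n_candidates`, `percent`.
#' @export
overlap_summary <- function(candidate_ids, homology_pairs) {
  stopifnot(length(candidate_ids) > 0, !anyDuplicated(candidate_ids))
  hp <- as.data.table(homology_pairs)
  if (nrow(hp) && !all(c("candidate_id", "study") %in% names(hp))) {
    stop("homology_pairs needs candidate_id and study columns")
  }
  if (nrow(hp)) {
    known <- hp$candidate_id %in% candidate_ids
    if (!all(known)) {
      warning(sum(!known), " homology pair(s) reference unknown candidates; skipped")
      hp <- hp[known]
    }
  }
  n_cand <- length(candidate_ids)
  per_study <- if (nrow(hp)) {
    hp[, .(n_overlap = length(unique(candidate_id))), by = study]
  } else {
    data.table(study = character(), n_overlap = integer())
  }
  union_n <- if (nrow(hp)) length(unique(hp$candidate_id)) else 0L
  out <- rbind(setDF(per_study),
               data.frame(study = "union", n_overlap = union_n))
  out$n_candidates <- n_cand
  out$percent <- percent(out$n_overlap, n_cand)
  out
}

#' Render the run summary as Markdown
#'
#' @param summary data.frame from [summary_table()].
#' @param overlap optional data.frame from [overlap_summary()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of Markdown lines (invisibly when written).
#' @export
render_report_md <- function(summary, overlap = NULL, path = NULL) {
  fmt_pct <- function(p) ifelse(is.na(p), "", sprintf("%.2f%%", p))
  lines <- c("# PMF pipeline summary", "",
             "| metric | value | % | of |", "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", summary$metric,
                     format(summary$value, big.mark = ",", trim = TRUE),
                     fmt_pct(summary$percent),
                     ifelse(is.na(summary$percent_of), "", summary$percent_of)))
  if (!is.null(overlap)) {
    lines <- c(lines, "", "## Overlap with external study sets", "",
               "| study | overlap | candidates | % |", "|---|---|---|---|",
               sprintf("| %s | %d | %d | %s |", overlap$study,
                       overlap$n_overlap, overlap$n_candidates,
                       fmt_pct(overlap$percent)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
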