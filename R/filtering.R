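# Decoy-calibrated score thresholding. Decoy hits are assumed false; the
# score above which a chosen fraction (the "false-negative rate") of decoy
# unique peptides remains defines the acceptance threshold for the forward
# set.

#' Select a score threshold from decoy unique-peptide scores
#'
#' Ranks the decoy unique-peptide scores and sets the threshold at the k-th
#' highest score with `k = floor(fn_rate * n)`, so that (for distinct
#' scores) exactly k decoy peptides score at or above it. "Passing" means
#' `score >= threshold`. With `k = 0` the threshold is infinite and nothing
#' passes, decoy or forward. Ties at the threshold all pass; a warning
#' reports the excess over k.
#'
#' @param decoy_scores numeric vector of decoy unique-peptide scores (after
#'   best-score collapse, see [collapse_unique_peptides()]).
#' @param fn_rate decoy false-negative rate in `[0, 1]` (default 0.05).
#' @return object of class `threshold_result`: list with `fn_rate`,
#'   `n_decoy_unique`, `k_pass_decoy` (decoy peptides actually passing,
#'   including ties), `threshold_score`.
#' @export
select_decoy_threshold <- function(decoy_scores, fn_rate = 0.05) {
  stopifnot(fn_rate >= 0, fn_rate <= 1)
  decoy_scores <- as.numeric(decoy_scores)
  if (!length(decoy_scores) || anyNA(decoy_scores)) {
    stop("decoy_scores must be non-empty and free of NA")
  }
  n <- length(decoy_scores)
  k <- floor(fn_rate * n)
  if (k == 0L) {
    threshold <- Inf  # accept nothing, decoy or forward
  } else {
    threshold <- sort(decoy_scores, decreasing = TRUE)[k]
  }
  k_pass <- sum(decoy_scores >= threshold)
  if (k_pass > k) {
    warning(sprintf(
      "ties at the threshold: %d decoy peptides pass (%d over the nominal k)",
      k_pass, k_pass - k))
  }
  structure(list(fn_rate = fn_rate, n_decoy_unique = n,
                 k_pass_decoy = k_pass, threshold_score = threshold),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result: score >= %.4g (fn_rate %.3g; %d of %d decoy peptides pass)\n",
    x$threshold_score, x$fn_rate, x$k_pass_decoy, x$n_decoy_unique))
  if (!is.null(x$n_forward_unique)) {
    cat(sprintf("  forward: %d of %d unique peptides pass (%.2f%%)\n",
                x$n_forward_pass, x$n_forward_unique,
                x$forward_pass_fraction))
  }
  invisible(x)
}

#' Apply a decoy-derived threshold to forward peptide assignments
#'
#' Retains forward unique-peptide assignments with `best_score >=` the
#' threshold and reports the pass counts and percentage. Idempotent.
#'
#' @param forward_assignments data.frame of forward peptide assignments with
#'   a `best_score` column (see [collapse_unique_peptides()]).
#' @param threshold a `threshold_result` from [select_decoy_threshold()], or
#'   a bare numeric score.
#' @return list with `passing` (the retained rows), `n_forward_unique`,
#'   `n_forward_pass`, `forward_pass_fraction` (a 2-decimal percentage, see
#'   [percent()]), and `threshold` (the completed `threshold_result` when
#'   one was supplied).
#' @export
apply_threshold <- function(forward_assignments, threshold) {
  stopifnot(is.data.frame(forward_assignments),
            "best_score" %in% names(forward_assignments))
  thr <- if (inherits(threshold, "threshold_result")) {
    threshold$threshold_score
  } else {
    as.numeric(threshold)
  }
  pass <- forward_assignments$best_score >= thr
  n <- nrow(forward_assignments)
  out <- list(passing = forward_assignments[pass, , drop = FALSE],
              n_forward_unique = n,
              n_forward_pass = sum(pass),
              forward_pass_fraction = if (n > 0) percent(sum(pass), n) else NA_real_)
  if (inherits(threshold, "threshold_result")) {
    threshold$n_forward_unique <- out$n_forward_unique
    threshold$n_forward_pass <- out$n_forward_pass
    threshold$forward_pass_fraction <- out$forward_pass_fraction
    out$threshold <- threshold
  }
  out
}

#' Flag URFs carrying at least one passing peptide
#'
#' A URF is flagged reliable iff at least one passing forward peptide maps
#' onto it (set semantics: several passing peptides flag it once).
#'
#' @param passing_assignments data.frame of passing forward assignments with
#'   columns `peptide_sequence` and `entry_ids` (`;`-joined carriers), or a
#'   two-column peptide-to-URF map (`peptide_sequence`, `urf_id`).
#' @param all_searched_urfs character vector of all searched URF ids (the
#'   denominator).
#' @return list with `reliable_urfs` (data.frame `urf_id`,
#'   `n_passing_peptides`), `n_flagged`, `n_searched`, `fraction`
#'   (2-decimal percentage).
#' @export
flag_urfs <- function(passing_assignments, all_searched_urfs) {
  stopifnot(is.data.frame(passing_assignments), length(all_searched_urfs) > 0)
  if ("entry_ids" %in% names(passing_assignments)) {
    carriers <- strsplit(passing_assignments$entry_ids, ";", fixed = TRUE)
    map <- data.table(
      peptide_sequence = rep(passing_assignments$peptide_sequence,
                             lengths(carriers)),
      urf_id = as.character(unlist(carriers, use.names = FALSE)))
  } else if ("urf_id" %in% names(passing_assignments)) {
    map <- as.data.table(passing_assignments[c("peptide_sequence", "urf_id")])
  } else {
    stop("passing_assignments needs entry_ids or urf_id")
  }
  map <- unique(map)
  unknown <- setdiff(map$urf_id, all_searched_urfs)
  if (length(unknown)) {
    stop("passing peptides map to unsearched URFs: ",
         paste(head(unknown, 3L), collapse = ", "))
  }
  flagged <- map[, .(n_passing_peptides = .N), by = urf_id]
  setorder(flagged, -n_passing_peptides, urf_id)
  list(reliable_urfs = setDF(flagged),
       n_flagged = nrow(flagged),
       n_searched = length(all_searched_urfs),
       fraction = percent(nrow(flagged), length(all_searched_urfs)))
}

#' Compositional bias of peptides in bits
#'
#' Kullback-Leibler divergence of the peptide's residue composition from the
#' uniform background over the 20-letter alphabet:
#' `sum_a f_a * log2(f_a / (1/20))`, equivalently `log2(20)` minus the
#' Shannon entropy of the composition. High values mean biased, repetitive
#' (low-complexity) sequence; the value is 0 for a peptide using all 20
#' residues equally and `log2(20) ~ 4.32` bits for a homopolymer. Peptides
#' above the threshold (default 2.5 bits) are flagged low-complexity; the
#' flag is an annotation, not an exclusion.
#'
#' @param peptide_sequence character vector of peptide sequences.
#' @param threshold low-complexity flag threshold in bits (default 2.5).
#' @return data.frame with columns `peptide_sequence`, `bias_bits`,
#'   `low_complexity` (`bias_bits > threshold`).
#' @export
composition_bias_bits <- function(peptide_sequence, threshold = 2.5) {
  if (!length(peptide_sequence)) {
    return(data.frame(peptide_sequence = character(), bias_bits = numeric(),
                      low_complexity = logical()))
  }
  peptide_sequence <- toupper(peptide_sequence)
  if (anyNA(peptide_sequence) || any(!nzchar(peptide_sequence))) {
    stop("composition_bias_bits: empty sequence")
  }
  bad <- regexpr(sprintf("[^%s]", paste(names(AA_MONO), collapse = "")),
                 peptide_sequence)
  if (any(bad > 0L)) {
    stop("composition_bias_bits: non-standard residue in peptide ",
         peptide_sequence[which(bad > 0L)[1L]])
  }
  bits <- vapply(strsplit(peptide_sequence, "", fixed = TRUE), function(ch) {
    f <- tabulate(match(ch, names(AA_MONO)), nbins = 20L) / length(ch)
    f <- f[f > 0]
    sum(f * log2(f * 20))
  }, numeric(1L))
  data.frame(peptide_sequence = peptide_sequence, bias_bits = bits,
             low_complexity = bits > threshold)
}
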