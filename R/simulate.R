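# Synthetic traces and fingerprints with known truth. Planted proteins are
# back-translated with uniform codon usage and inserted flanked by stop
# codons, so the ORF extractor recovers them exactly; fingerprints carry a
# Bernoulli-thinned subset of the planted protein's tryptic MH+ masses with
# Gaussian mass error plus uniform noise peaks.

DNA_BASES <- c("A", "C", "G", "T")

codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
}

#' Back-translate a protein with uniform codon choice
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' codons (standard genetic code), using the current RNG state.
#'
#' @param aa_sequence single amino-acid string (20-letter alphabet).
#' @return nucleotide string of length `3 * nchar(aa_sequence)`.
#' @export
back_translate <- function(aa_sequence) {
  tab <- codons_by_aa()
  res <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1L]]
  if (!all(res %in% names(tab))) {
    stop("back_translate: non-standard residue in input")
  }
  paste(vapply(tab[res], function(cc) cc[sample.int(length(cc), 1L)],
               character(1L)), collapse = "")
}

#' Random protein sequences
#'
#' Residues drawn uniformly from the 20-letter alphabet; lengths drawn
#' uniformly from `len_range`. Uses the current RNG state.
#'
#' @param n number of proteins.
#' @param len_range integer vector `c(min, max)` length range in residues.
#' @return named character vector (`protein1`, `protein2`, ...).
#' @export
random_proteins <- function(n, len_range = c(60L, 120L)) {
  if (n == 0L) return(setNames(character(0), character(0)))
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  setNames(vapply(lens, function(L) {
    paste(sample(names(AA_MONO), L, replace = TRUE), collapse = "")
  }, character(1L)), paste0("protein", seq_len(n)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate trace reads with planted protein-coding ORFs
#'
#' Generates random background nucleotides at the stated GC fraction and
#' inserts each planted protein as a back-translated CDS flanked by in-frame
#' stop codons, on a random strand at a random codon-aligned position, so
#' that six-frame ORF extraction recovers the protein sequence exactly. The
#' insertion replaces background sequence (trace lengths are unchanged).
#'
#' @param n_traces number of traces.
#' @param trace_len_mean,trace_len_sd trace length distribution (nt); drawn
#'   as `round(rnorm(...))`, floored at 30 nt and, for traces receiving a
#'   plant, at the insert length.
#' @param planted_proteins named character vector of protein sequences to
#'   plant (each in one distinct trace), or `NULL`.
#' @param gc_fraction background GC content (default 0.32, an AT-rich
#'   invertebrate genome).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `traces` (a named [Biostrings::DNAStringSet]) and
#'   `truth`: `planted_proteins` (data.frame `protein_id`, `aa_sequence`)
#'   and `placements` (data.frame `protein_id`, `trace_id`, `frame`,
#'   `nt_start`, `nt_end`, `cds` — forward-strand 0-based half-open
#'   coordinates of the coding sequence, frame sign carrying the strand).
#' @export
make_traces <- function(n_traces, trace_len_mean = 800, trace_len_sd = 80,
                        planted_proteins = NULL, gc_fraction = 0.32,
                        seed = NULL) {
  stopifnot(n_traces >= 1L, trace_len_mean > 0, trace_len_sd >= 0,
            gc_fraction > 0, gc_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  lens <- pmax(30L, as.integer(round(rnorm(n_traces, trace_len_mean,
                                           trace_len_sd))))
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  big <- paste(sample(DNA_BASES, sum(lens), replace = TRUE, prob = probs),
               collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1L, ends)
  ids <- sprintf("trace%05d", seq_len(n_traces))
  placements <- NULL
  if (!is.null(planted_proteins) && length(planted_proteins)) {
    prot <- toupper(planted_proteins)
    if (is.null(names(prot))) names(prot) <- paste0("protein", seq_along(prot))
    insert_len <- 3L * nchar(prot) + 6L
    if (max(insert_len) > max(lens)) {
      stop("planted protein too long for the trace length distribution")
    }
    eligible <- which(lens >= max(insert_len))
    if (length(eligible) < length(prot)) {
      stop("not enough traces long enough to plant all proteins")
    }
    target <- sample(eligible, length(prot))
    rows <- vector("list", length(prot))
    for (i in seq_along(prot)) {
      tr <- target[i]
      L <- lens[tr]
      m <- nchar(prot[i])
      cds <- back_translate(prot[i])
      ins <- paste0("TAA", cds, "TAA")
      minus <- runif(1) < 0.5
      if (minus) ins <- revcomp_chr(ins)
      s0 <- 3L * sample.int((L - nchar(ins)) %/% 3L + 1L, 1L) - 3L
      seqs[tr] <- paste0(substr(seqs[tr], 1L, s0), ins,
                         substr(seqs[tr], s0 + nchar(ins) + 1L, L))
      nt_start <- s0 + 3L
      nt_end <- nt_start + 3L * m
      frame <- if (minus) {
        -(((L - nt_end) %% 3L) + 1L)
      } else {
        (nt_start %% 3L) + 1L
      }
      rows[[i]] <- data.frame(
        protein_id = names(prot)[i], trace_id = ids[tr],
        frame = sprintf("%+d", frame), nt_start = nt_start, nt_end = nt_end,
        cds = if (minus) revcomp_chr(cds) else cds)
    }
    placements <- do.call(rbind, rows)
  }
  truth <- list(
    planted_proteins = if (is.null(planted_proteins)) {
      data.frame(protein_id = character(), aa_sequence = character())
    } else {
      data.frame(protein_id = names(planted_proteins) %||%
                   paste0("protein", seq_along(planted_proteins)),
                 aa_sequence = toupper(unname(planted_proteins)))
    },
    placements = placements %||% data.frame(
      protein_id = character(), trace_id = character(), frame = character(),
      nt_start = integer(), nt_end = integer(), cds = character())
  )
  dna <- Biostrings::DNAStringSet(setNames(seqs, ids))
  list(traces = dna, truth = truth)
}

#' Simulate a PMF fingerprint for a protein
#'
#' Each tryptic MH+ mass of the protein is observed independently with
#' probability `detect_prob` and perturbed by Gaussian mass error; uniform
#' noise peaks over `noise_mass_range` are added. A spot simulated from a
#' protein is guaranteed at least one true peak (detection is redrawn until
#' non-empty). With `protein = NULL` a pure-noise spot is produced.
#'
#' @param protein amino-acid sequence, or `NULL` for a pure-noise spot.
#' @param detect_prob per-peptide detection probability in (0, 1].
#' @param mass_sd_da Gaussian mass error SD in Da (>= 0).
#' @param n_noise_peaks number of uniform noise peaks.
#' @param noise_mass_range numeric `c(lo, hi)` in Da.
#' @param spot_id spot identifier.
#' @param max_missed,min_length,mods digestion settings (see [digest_db()]).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `fingerprint` (a [fingerprint()]) and `truth`
#'   (data.frame `mass`, `source` = `"true"`/`"noise"`, `peptide_sequence`).
#' @export
make_fingerprint <- function(protein, detect_prob = 0.7, mass_sd_da = 0.05,
                             n_noise_peaks = 5L,
                             noise_mass_range = c(700, 3500),
                             spot_id = "spot", max_missed = 1L,
                             min_length = 4L, mods = NULL, seed = NULL) {
  stopifnot(detect_prob > 0, detect_prob <= 1, mass_sd_da >= 0,
            n_noise_peaks >= 0L)
  if (!is.null(seed)) set.seed(seed)
  true_mass <- numeric(0)
  true_pep <- character(0)
  if (!is.null(protein)) {
    dig <- tryptic_peptides(protein, max_missed = max_missed,
                            min_length = min_length, mods = mods)
    if (!nrow(dig)) stop("protein yields no valid peptides")
    repeat {
      sel <- runif(nrow(dig)) < detect_prob
      if (any(sel)) break
    }
    true_mass <- dig$mh_mass[sel] + rnorm(sum(sel), 0, mass_sd_da)
    true_pep <- dig$sequence[sel]
  } else if (n_noise_peaks == 0L) {
    stop("a pure-noise spot needs n_noise_peaks > 0")
  }
  noise_mass <- runif(n_noise_peaks, noise_mass_range[1L], noise_mass_range[2L])
  truth <- data.frame(
    mass = c(true_mass, noise_mass),
    source = rep(c("true", "noise"), c(length(true_mass), n_noise_peaks)),
    peptide_sequence = c(true_pep, rep(NA_character_, n_noise_peaks)))
  truth <- truth[order(truth$mass), , drop = FALSE]
  rownames(truth) <- NULL
  list(fingerprint = fingerprint(spot_id, truth$mass), truth = truth)
}

#' Default benchmark configuration
#'
#' Desk-scale study conditions for the end-to-end synthetic benchmark:
#' 2,000 traces of ~800 nt, 20 planted proteins of 60-120 residues (each
#' with its own spectrum), 20 pure-noise spectra, detection probability 0.7,
#' 0.05 Da mass error, 5 noise peaks per planted spot and 15 per noise spot.
#'
#' @param ... named overrides of any default.
#' @return named list of configuration values.
#' @export
benchmark_config <- function(...) {
  cfg <- list(
    n_traces = 2000L, trace_len_mean = 800, trace_len_sd = 80,
    gc_fraction = 0.32, n_planted = 20L, protein_len_range = c(60L, 120L),
    n_noise_spectra = 20L, detect_prob = 0.7, mass_sd_da = 0.05,
    n_noise_peaks = 5L, n_noise_peaks_pure = 15L,
    noise_mass_range = c(700, 3500), min_orf_len = 50L, max_missed = 1L,
    min_pep_len = 4L, mods = NULL, tolerance = 0.2, top_n = 50L,
    fn_rate = 0.05, max_entries = 5000L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the end-to-end synthetic benchmark
#'
#' Generates traces with planted proteins and synthetic fingerprints,
#' executes the full pipeline (six-frame ORF database, URF deduplication,
#' reversed decoys, tryptic digestion, partitioned PMF search, best-score
#' peptide collapse, decoy-calibrated thresholding, reliable-URF flagging),
#' and evaluates it against the known truth: the rank of each planted
#' protein's URF for its own spectrum, and the empirical false-pass fraction
#' among forward unique peptides compared with the decoy estimate.
#'
#' @param config configuration list from [benchmark_config()].
#' @param seed integer seed driving all randomness.
#' @return object of class `pmf_benchmark`: list with `config`, `truth`,
#'   `urfs`, `threshold` (completed `threshold_result`), `assignments`,
#'   `flags`, `ranks` (data.frame per planted protein), `recovery_rate`
#'   (percent of planted proteins at rank 1), `n_false_forward`,
#'   `n_false_pass`, `empirical_false_pass_fraction`,
#'   `decoy_pass_fraction`, `fdr_binom_p` (two-sided binomial test of the
#'   false passes against the decoy pass rate), and `summary`.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 1L) {
  set.seed(seed)
  proteins <- random_proteins(config$n_planted, config$protein_len_range)
  sim <- make_traces(config$n_traces, config$trace_len_mean,
                     config$trace_len_sd, planted_proteins = proteins,
                     gc_fraction = config$gc_fraction)
  orfs <- build_orf_db(sim$traces, min_len = config$min_orf_len)
  urfs <- dedup_urfs(orfs)
  decoys <- build_decoy_db(urfs)
  fwd_parts <- split_database(urfs, config$max_entries)
  dec_parts <- split_database(decoys, config$max_entries)
  digest_part <- function(p) digest_db(p, max_missed = config$max_missed,
                                       min_length = config$min_pep_len,
                                       mods = config$mods)
  databases <- list(forward = lapply(fwd_parts, digest_part),
                    decoy = lapply(dec_parts, digest_part))

  spots <- vector("list", config$n_planted + config$n_noise_spectra)
  spot_truth <- character(length(spots))
  for (i in seq_len(config$n_planted)) {
    fp <- make_fingerprint(proteins[[i]], config$detect_prob,
                           config$mass_sd_da, config$n_noise_peaks,
                           config$noise_mass_range,
                           spot_id = sprintf("spot_%s", names(proteins)[i]),
                           max_missed = config$max_missed,
                           min_length = config$min_pep_len,
                           mods = config$mods)
    spots[[i]] <- fp
    spot_truth[i] <- names(proteins)[i]
  }
  for (j in seq_len(config$n_noise_spectra)) {
    i <- config$n_planted + j
    fp <- make_fingerprint(NULL, config$detect_prob, config$mass_sd_da,
                           config$n_noise_peaks_pure,
                           config$noise_mass_range,
                           spot_id = sprintf("spot_noise%02d", j))
    spots[[i]] <- fp
    spot_truth[i] <- "noise"
  }

  res <- search_run(lapply(spots, `[[`, "fingerprint"), databases,
                    tolerance = config$tolerance, top_n = config$top_n)
  assignments <- collapse_unique_peptides(res)
  decoy_scores <- assignments[db_label == "decoy", best_score]
  thr <- select_decoy_threshold(decoy_scores, config$fn_rate)
  fwd <- assignments[db_label == "forward"]
  app <- apply_threshold(fwd, thr)
  flags <- flag_urfs(app$passing, urfs$urf_id)

  # rank of each planted protein's URF for its own spectrum
  planted_urf <- urf_checksum(unname(proteins))
  ranks <- data.frame(protein_id = names(proteins), urf_id = planted_urf,
                      rank = rep(NA_integer_, length(proteins)))
  for (i in seq_len(config$n_planted)) {
    h <- res$hits[spot_id == sprintf("spot_%s", names(proteins)[i]) &
                    db_label == "forward"]
    setorder(h, -score, -matched, entry_id)
    r <- match(planted_urf[i], h$entry_id)
    ranks$rank[i] <- if (is.na(r)) NA_integer_ else r
  }
  recovery_rate <- if (nrow(ranks) > 0) {
    percent(sum(!is.na(ranks$rank) & ranks$rank == 1L), nrow(ranks))
  } else NA_real_

  # empirical FDR calibration: forward peptides not derivable from any
  # planted protein are false by construction
  true_peps <- unique(unlist(lapply(proteins, function(p) {
    tryptic_peptides(p, max_missed = config$max_missed,
                     min_length = config$min_pep_len,
                     mods = config$mods)$sequence
  }), use.names = FALSE))
  fwd[, is_true := peptide_sequence %in% true_peps]
  n_false <- sum(!fwd$is_true)
  n_false_pass <- sum(!fwd$is_true & fwd$best_score >= thr$threshold_score)
  decoy_frac <- thr$k_pass_decoy / thr$n_decoy_unique
  fdr_test <- if (n_false > 0) {
    binom.test(n_false_pass, n_false, p = decoy_frac)
  } else NULL

  summary <- summary_table(list(
    n_traces = config$n_traces, n_orfs = nrow(orfs), n_urfs = nrow(urfs),
    n_searched_urfs = nrow(urfs),
    n_forward_unique = app$n_forward_unique,
    n_decoy_unique = thr$n_decoy_unique,
    k_pass_decoy = thr$k_pass_decoy,
    n_forward_pass = app$n_forward_pass,
    n_flagged_urfs = flags$n_flagged))

  structure(list(
    config = config, seed = seed, truth = sim$truth,
    spot_truth = spot_truth, urfs = urfs, hits = res$hits,
    assignments = assignments, threshold = app$threshold, flags = flags,
    ranks = ranks, recovery_rate = recovery_rate,
    n_false_forward = n_false, n_false_pass = n_false_pass,
    empirical_false_pass_fraction = if (n_false > 0) n_false_pass / n_false
    else NA_real_,
    decoy_pass_fraction = decoy_frac,
    fdr_binom_p = if (!is.null(fdr_test)) fdr_test$p.value else NA_real_,
    summary = summary
  ), class = "pmf_benchmark")
}

#' @export
print.pmf_benchmark <- function(x, ...) {
  cat(sprintf("pmf_benchmark (seed %d)\n", x$seed))
  cat(sprintf("  rank-1 recovery: %.2f%% of %d planted proteins\n",
              x$recovery_rate, nrow(x$ranks)))
  cat(sprintf("  decoy threshold: %.2f (%d of %d decoy peptides pass)\n",
              x$threshold$threshold_score, x$threshold$k_pass_decoy,
              x$threshold$n_decoy_unique))
  cat(sprintf(
    "  empirical false-pass: %d of %d (%.3f) vs decoy estimate %.3f (p = %.3g)\n",
    x$n_false_pass, x$n_false_forward,
    x$empirical_false_pass_fraction, x$decoy_pass_fraction, x$fdr_binom_p))
  invisible(x)
}
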