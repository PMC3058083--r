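# In-silico tryptic digestion. Trypsin cleaves C-terminal to K or R except
# when the next residue is P (Keil rule); peptides with up to `max_missed`
# internal missed cleavage sites are emitted.

# Fragment boundaries for one protein: seqs/starts(0-based)/missed vectors.
tryptic_fragments <- function(protein, max_missed) {
  nres <- nchar(protein)
  sites <- gregexpr("[KR](?!P)", protein, perl = TRUE)[[1L]]
  sites <- if (sites[1L] == -1L) integer(0) else as.integer(sites)
  sites <- sites[sites < nres]  # the C-terminus is not a cleavage site
  starts <- c(1L, sites + 1L)
  ends <- c(sites, nres)
  k <- length(starts)
  out_seq <- vector("list", max_missed + 1L)
  out_start <- vector("list", max_missed + 1L)
  out_missed <- vector("list", max_missed + 1L)
  for (m in 0:min(max_missed, k - 1L)) {
    s <- starts[seq_len(k - m)]
    e <- ends[seq_len(k - m) + m]
    out_seq[[m + 1L]] <- substring(protein, s, e)
    out_start[[m + 1L]] <- s - 1L
    out_missed[[m + 1L]] <- rep.int(m, k - m)
  }
  list(sequence = unlist(out_seq, use.names = FALSE),
       start = unlist(out_start, use.names = FALSE),
       missed = unlist(out_missed, use.names = FALSE))
}

#' Tryptic peptides of one protein
#'
#' Digests a protein with trypsin under the Keil rule and emits every peptide
#' with 0 to `max_missed` internal missed cleavage sites. Peptides containing
#' `X` (unresolved ambiguity residues) are dropped; the number dropped is
#' recorded in the `n_dropped_x` attribute of the result.
#'
#' @param protein amino-acid sequence (single string).
#' @param max_missed maximum number of missed cleavages (default 1).
#' @param min_length minimum peptide length in residues (default 1; database
#'   searches use 4 by default, see [digest_db()]).
#' @param parent_id identifier recorded in the output.
#' @param mods,monoisotopic passed to [peptide_mass()].
#' @return data.frame with columns `parent_id`, `start` (0-based offset in
#'   the parent), `sequence`, `missed`, `mh_mass`.
#' @examples
#' tryptic_peptides("AAKRCC", max_missed = 0)$sequence  # AAK, R, CC
#' @export
tryptic_peptides <- function(protein, max_missed = 1L, min_length = 1L,
                             parent_id = "protein", mods = NULL,
                             monoisotopic = TRUE) {
  stopifnot(length(protein) == 1L, max_missed >= 0L)
  protein <- toupper(protein)
  fr <- tryptic_fragments(protein, max_missed)
  has_x <- grepl("X", fr$sequence, fixed = TRUE)
  keep <- !has_x & nchar(fr$sequence) >= min_length
  out <- data.frame(parent_id = parent_id,
                    start = fr$start[keep],
                    sequence = fr$sequence[keep],
                    missed = fr$missed[keep])
  out$mh_mass <- if (nrow(out)) {
    peptide_mass(out$sequence, mods = mods, monoisotopic = monoisotopic)
  } else numeric(0)
  attr(out, "n_dropped_x") <- sum(has_x)
  out
}

#' Digest a protein database
#'
#' Applies [tryptic_peptides()] to every entry of a database and returns one
#' peptide table sorted by mass, ready for fingerprint matching. Peptides
#' shorter than `min_length` residues are excluded (mass collisions within
#' tolerance dominate below ~4 residues), as are peptides containing `X`.
#'
#' @param db a `urf_db`, a decoy data.frame, or any data.frame with an id
#'   column (`urf_id`, `decoy_id` or `parent_id`) and `aa_sequence`.
#' @param max_missed maximum missed cleavages (default 1).
#' @param min_length minimum peptide length (default 4).
#' @param mods,monoisotopic passed to [peptide_mass()].
#' @return data.table with columns `parent_id`, `start`, `sequence`,
#'   `missed`, `mh_mass`, keyed/sorted by `mh_mass`. The number of
#'   X-containing peptides dropped is in `attr(, "n_dropped_x")`.
#' @export
digest_db <- function(db, max_missed = 1L, min_length = 4L, mods = NULL,
                      monoisotopic = TRUE) {
  id_col <- intersect(c("urf_id", "decoy_id", "parent_id"), names(db))[1L]
  if (is.na(id_col)) stop("db needs an id column (urf_id/decoy_id/parent_id)")
  ids <- db[[id_col]]
  seqs <- toupper(db$aa_sequence)
  frags <- lapply(seqs, tryptic_fragments, max_missed = max_missed)
  lens <- vapply(frags, function(f) length(f$sequence), integer(1L))
  dt <- data.table(
    parent_id = rep(ids, lens),
    start = unlist(lapply(frags, `[[`, "start"), use.names = FALSE),
    sequence = unlist(lapply(frags, `[[`, "sequence"), use.names = FALSE),
    missed = unlist(lapply(frags, `[[`, "missed"), use.names = FALSE)
  )
  has_x <- grepl("X", dt$sequence, fixed = TRUE)
  n_dropped_x <- sum(has_x)
  dt <- dt[!has_x & nchar(sequence) >= min_length]
  uniq <- unique(dt$sequence)
  dt[, mh_mass := peptide_mass(uniq, mods, monoisotopic)[match(sequence, uniq)]]
  setorder(dt, mh_mass)
  setattr(dt, "n_dropped_x", n_dropped_x)
  dt[]
}
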