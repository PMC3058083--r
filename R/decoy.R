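# Reversed-sequence decoy databases. Reversal preserves length and residue
# composition (hence total mass) but displaces the tryptic cleavage pattern,
# so decoy hits calibrate the score distribution of false matches.

DECOY_PREFIX <- "DECOY_"

#' Reverse protein sequences
#'
#' Character-wise reversal; reversing twice is the identity and the residue
#' multiset is conserved.
#'
#' @param seq character vector of non-empty amino-acid sequences.
#' @return character vector of reversed sequences.
#' @examples
#' reverse_protein("MKRP")  # "PRKM"
#' @export
reverse_protein <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (anyNA(seq) || any(!nzchar(seq))) stop("reverse_protein: empty sequence")
  as.character(Biostrings::reverse(Biostrings::AAStringSet(seq)))
}

#' Build a reversed-sequence decoy database
#'
#' Produces one decoy entry per forward URF, in the same order, with id
#' `DECOY_<urf_id>`. The prefix is applied to the forward checksum (it is not
#' part of any digest computation), so the forward/decoy pairing is always
#' recoverable by stripping it.
#'
#' @param forward a `urf_db` or data.frame with columns `urf_id`,
#'   `aa_sequence`.
#' @return data.frame with columns `decoy_id`, `aa_sequence`, `source_id`.
#' @export
build_decoy_db <- function(forward) {
  stopifnot(is.data.frame(forward),
            all(c("urf_id", "aa_sequence") %in% names(forward)))
  if (anyDuplicated(forward$urf_id)) stop("forward ids must be unique")
  if (nrow(forward) == 0L) {
    return(data.frame(decoy_id = character(), aa_sequence = character(),
                      source_id = character()))
  }
  data.frame(
    decoy_id = paste0(DECOY_PREFIX, forward$urf_id),
    aa_sequence = reverse_protein(forward$aa_sequence),
    source_id = forward$urf_id
  )
}

#' Write a decoy database to protein FASTA
#'
#' @param decoys data.frame from [build_decoy_db()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_decoy_fasta <- function(decoys, path) {
  writeLines(paste0(">", decoys$decoy_id, "\n", decoys$aa_sequence), path)
  invisible(path)
}
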