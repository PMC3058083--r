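# Six-frame translation of genome trace reads, ORF extraction, and
# deduplication into checksum-keyed URFs (unique reading frames).

FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")
IUPAC_DNA_RE <- "[^ACGTRYSWKMBDHVN]"

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (!is.character(x)) stop("expected a character vector or DNAStringSet of traces")
  x <- toupper(x)
  bad <- regexpr(IUPAC_DNA_RE, x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "unrecognized nucleotide '%s' at position %d of trace %s",
      substr(x[i], bad[i], bad[i]), bad[i],
      if (is.null(names(x))) as.character(i) else names(x)[i]
    ))
  }
  if (is.null(names(x))) names(x) <- paste0("trace", seq_along(x))
  Biostrings::DNAStringSet(x)
}

translate_frame <- function(dna, offset) {
  len <- Biostrings::width(dna)
  w <- pmax(0L, (len - offset) %/% 3L) * 3L
  sub <- Biostrings::subseq(dna, start = pmin(offset + 1L, len + 1L), width = w)
  # no.init.codon: frame translations have no privileged start position, so
  # alternative initiators (TTG/CTG) must not become M
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}

#' Translate traces in all six reading frames
#'
#' Translates each nucleotide sequence in frames +1/+2/+3 (forward strand at
#' offsets 0/1/2) and -1/-2/-3 (reverse complement at offsets 0/1/2) under the
#' standard genetic code. Stops appear as `*`; trailing partial codons are
#' dropped; codons with ambiguity codes that do not resolve to a unique amino
#' acid translate to `X`.
#'
#' @param x character vector (IUPAC nucleotide codes, case-insensitive) or a
#'   [Biostrings::DNAStringSet] of traces.
#' @return character matrix with one row per trace and columns
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' six_frame_translate("ATGAAATAG")[, "+1"]  # "MK*"
#' @export
six_frame_translate <- function(x) {
  dna <- as_dna_set(x)
  rc <- Biostrings::reverseComplement(dna)
  out <- matrix("", nrow = length(dna), ncol = 6L,
                dimnames = list(names(dna), FRAME_LABELS))
  for (o in 0:2) {
    out[, o + 1L] <- translate_frame(dna, o)
    out[, o + 4L] <- translate_frame(rc, o)
  }
  out
}

# ORFs from one frame translation: maximal stop-free runs of length >= min_len.
# Returns aa-coordinate runs (1-based start/end in the translation).
frame_runs <- function(aa, min_len) {
  hit <- gregexpr("[^*]+", aa)[[1L]]
  if (hit[1L] == -1L) return(NULL)
  len <- attr(hit, "match.length")
  keep <- len >= min_len
  if (!any(keep)) return(NULL)
  list(start = as.integer(hit[keep]), len = len[keep])
}

#' Extract ORFs from six-frame translations
#'
#' An ORF is a maximal stop-free run in one frame translation (stop-to-stop,
#' including runs touching the trace ends; no start-codon requirement). `X`
#' residues do not break an ORF. Nucleotide coordinates are reported 0-based
#' half-open on the forward strand of the trace for both strands, with the
#' frame sign carrying the strand.
#'
#' @param frames named character vector of the six frame translations of one
#'   trace, as one row of [six_frame_translate()] output.
#' @param min_len minimum ORF length in amino acids (inclusive; default 50).
#' @param trace_id identifier recorded in the output.
#' @param trace_len trace length in nucleotides (required to place reverse
#'   strand ORFs on forward-strand coordinates).
#' @return data.frame with columns `trace_id`, `frame`, `nt_start`, `nt_end`,
#'   `aa_sequence`.
#' @seealso [build_orf_db()] for the vectorized whole-run version.
#' @export
extract_orfs <- function(frames, min_len = 50L, trace_id = "trace",
                         trace_len = NULL) {
  stopifnot(min_len >= 1L)
  if (is.matrix(frames)) {
    stopifnot(nrow(frames) == 1L)
    frames <- frames[1L, ]
  }
  if (!all(FRAME_LABELS %in% names(frames))) {
    stop("frames must be named with the six frame labels +1..+3, -1..-3")
  }
  if (is.null(trace_len)) {
    stop("trace_len is required to compute forward-strand coordinates")
  }
  out <- vector("list", 6L)
  for (f in seq_along(FRAME_LABELS)) {
    lab <- FRAME_LABELS[f]
    runs <- frame_runs(frames[[lab]], min_len)
    if (is.null(runs)) next
    o <- abs(as.integer(lab)) - 1L
    s <- runs$start; e <- runs$start + runs$len - 1L
    if (f <= 3L) {
      nt_start <- o + 3L * (s - 1L); nt_end <- o + 3L * e
    } else {
      nt_start <- trace_len - o - 3L * e; nt_end <- trace_len - o - 3L * (s - 1L)
    }
    out[[f]] <- data.frame(
      trace_id = trace_id, frame = lab, nt_start = nt_start, nt_end = nt_end,
      aa_sequence = substring(frames[[lab]], s, e)
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(trace_id = character(), frame = character(),
                      nt_start = integer(), nt_end = integer(),
                      aa_sequence = character())
  }
  rownames(out) <- NULL
  out
}

#' Build the ORF set of a whole trace run
#'
#' Translates every trace in six frames and extracts all ORFs of at least
#' `min_len` amino acids (see [extract_orfs()] for the ORF definition and
#' coordinate convention).
#'
#' @param traces character vector or [Biostrings::DNAStringSet] of traces,
#'   named by trace id.
#' @param min_len minimum ORF length in amino acids (default 50).
#' @return data.frame of ORFs (`trace_id`, `frame`, `nt_start`, `nt_end`,
#'   `aa_sequence`).
#' @export
build_orf_db <- function(traces, min_len = 50L) {
  stopifnot(min_len >= 1L)
  dna <- as_dna_set(traces)
  if (anyDuplicated(names(dna))) stop("trace ids must be unique")
  frames <- six_frame_translate(dna)
  lens <- Biostrings::width(dna)
  parts <- vector("list", 6L)
  for (f in seq_len(6L)) {
    lab <- FRAME_LABELS[f]
    o <- abs(as.integer(lab)) - 1L
    hits <- gregexpr("[^*]+", frames[, f])
    per <- lapply(seq_along(hits), function(i) {
      h <- hits[[i]]
      if (h[1L] == -1L) return(NULL)
      len <- attr(h, "match.length")
      keep <- len >= min_len
      if (!any(keep)) return(NULL)
      s <- as.integer(h[keep]); e <- s + len[keep] - 1L
      if (f <= 3L) {
        nt_start <- o + 3L * (s - 1L); nt_end <- o + 3L * e
      } else {
        nt_start <- lens[i] - o - 3L * e; nt_end <- lens[i] - o - 3L * (s - 1L)
      }
      data.table(trace_id = names(dna)[i], frame = lab,
                 nt_start = nt_start, nt_end = nt_end,
                 aa_sequence = substring(frames[i, f], s, e))
    })
    parts[[f]] <- rbindlist(per)
  }
  orfs <- rbindlist(parts)
  if (!nrow(orfs)) {
    return(data.frame(trace_id = character(), frame = character(),
                      nt_start = integer(), nt_end = integer(),
                      aa_sequence = character()))
  }
  setorder(orfs, trace_id, frame, nt_start)
  setDF(orfs)
  orfs
}

#' Deduplicate ORFs into URFs
#'
#' Collapses ORFs with identical amino-acid sequences into URFs (unique
#' reading frames). Each URF is keyed by the lowercase hex MD5 checksum of its
#' uppercase amino-acid sequence, and carries the provenance of every ORF that
#' contributed it. A checksum collision between unequal sequences aborts with
#' the offending provenances (none has ever been observed for MD5 on distinct
#' short protein strings, but the check is cheap).
#'
#' @param orfs data.frame of ORFs as produced by [build_orf_db()] or
#'   [extract_orfs()].
#' @return a `urf_db`: data.frame with columns `urf_id`, `aa_sequence` (first
#'   occurrence order), with the provenance table in `attr(, "provenance")`
#'   and run metadata (digest algorithm, counts) in `attr(, "metadata")`.
#' @export
dedup_urfs <- function(orfs) {
  stopifnot(is.data.frame(orfs), "aa_sequence" %in% names(orfs))
  seqs <- toupper(orfs$aa_sequence)
  ids <- urf_checksum(seqs)
  # collision audit: one distinct sequence per digest bucket
  first <- !duplicated(ids)
  canon <- setNames(seqs[first], ids[first])
  clash <- seqs != canon[ids]
  if (any(clash)) {
    i <- which(clash)[1L]
    j <- which(ids == ids[i] & first)[1L]
    stop(sprintf(
      "checksum collision for digest %s between %s|%s|%d and %s|%s|%d",
      ids[i], orfs$trace_id[i], orfs$frame[i], orfs$nt_start[i],
      orfs$trace_id[j], orfs$frame[j], orfs$nt_start[j]
    ))
  }
  urfs <- data.frame(urf_id = ids[first], aa_sequence = seqs[first])
  prov_cols <- intersect(c("trace_id", "frame", "nt_start", "nt_end"), names(orfs))
  prov <- cbind(data.frame(urf_id = ids), orfs[prov_cols])
  rownames(prov) <- NULL
  structure(urfs,
            provenance = prov,
            metadata = list(digest_algorithm = "md5",
                            n_orfs = nrow(orfs), n_urfs = nrow(urfs)),
            class = c("urf_db", "data.frame"))
}

#' URF checksum identifiers
#'
#' Lowercase hex MD5 digest of the uppercase amino-acid string; the identity
#' of a URF is a deterministic function of its sequence alone.
#'
#' @param aa_sequence character vector of protein sequences.
#' @return character vector of 32-character hex digests.
#' @export
urf_checksum <- function(aa_sequence) {
  if (!length(aa_sequence)) return(character(0))
  as.character(openssl::md5(toupper(aa_sequence)))
}

#' @export
print.urf_db <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat(sprintf("urf_db: %d URFs from %d ORFs (digest: %s)\n",
              nrow(x), meta$n_orfs %||% NA_integer_, meta$digest_algorithm))
  print(head(as.data.frame(x), 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a database into ordered partitions
#'
#' Splits a database into consecutive partitions of at most `max_entries`
#' entries each, preserving input order, so that search engines with an entry
#' limit can process each partition separately and results can be merged
#' losslessly afterwards.
#'
#' @param x data.frame of database entries (e.g. a `urf_db`).
#' @param max_entries maximum entries per partition (>= 1).
#' @return list of data.frames whose row-wise concatenation equals `x`.
#' @export
split_database <- function(x, max_entries) {
  stopifnot(is.data.frame(x), max_entries >= 1L)
  n <- nrow(x)
  if (n == 0L) return(list(x))
  grp <- (seq_len(n) - 1L) %/% as.integer(max_entries)
  lapply(split(seq_len(n), grp), function(i) {
    part <- x[i, , drop = FALSE]
    rownames(part) <- NULL
    part
  })
}

#' Write URFs to a protein FASTA
#'
#' Headers carry the checksum id followed by space-separated provenance
#' tokens `trace|frame|start|end`.
#'
#' @param urfs a `urf_db` from [dedup_urfs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_urf_fasta <- function(urfs, path) {
  prov <- attr(urfs, "provenance")
  tokens <- character(nrow(urfs))
  if (!is.null(prov) && nrow(prov)) {
    tok <- sprintf("%s|%s|%d|%d", prov$trace_id, prov$frame,
                   prov$nt_start, prov$nt_end)
    by_id <- split(tok, factor(prov$urf_id, levels = urfs$urf_id))
    tokens <- vapply(by_id, paste, character(1L), collapse = " ")
  }
  header <- trimws(paste(urfs$urf_id, tokens))
  writeLines(paste0(">", header, "\n", urfs$aa_sequence), path)
  invisible(path)
}

#' Read a URF protein FASTA written by [write_urf_fasta()]
#'
#' @param path FASTA file path.
#' @return a `urf_db` with provenance reconstructed from the header tokens.
#' @export
read_urf_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  header <- names(aa)
  fields <- strsplit(header, " ", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  prov <- rbindlist(lapply(seq_along(fields), function(i) {
    tok <- fields[[i]][-1L]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) return(NULL)
    p <- tstrsplit(tok, "|", fixed = TRUE)
    data.table(urf_id = ids[i], trace_id = p[[1L]], frame = p[[2L]],
               nt_start = as.integer(p[[3L]]), nt_end = as.integer(p[[4L]]))
  }))
  setDF(prov)
  structure(data.frame(urf_id = ids, aa_sequence = as.character(aa)),
            provenance = prov,
            metadata = list(digest_algorithm = "md5", n_urfs = length(ids)),
            class = c("urf_db", "data.frame"))
}

#' Read trace reads from a (multi-)FASTA file
#'
#' @param path FASTA file of nucleotide traces.
#' @return [Biostrings::DNAStringSet] named by trace id (first header token).
#' @export
read_traces <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(names(dna))) stop("duplicate trace ids in ", path)
  dna
}
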