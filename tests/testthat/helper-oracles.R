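# Independent oracles used by the tests: deliberately simple, position-by-
# position implementations that share no code with the package internals.

# Manual codon translation with IUPAC expansion: a fuzzy codon translating
# to a unique symbol gets that symbol, otherwise X.
IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(codon, "")[[1L]]
  combos <- expand.grid(IUPAC_EXPAND[[chars[1L]]], IUPAC_EXPAND[[chars[2L]]],
                        IUPAC_EXPAND[[chars[3L]]], stringsAsFactors = FALSE)
  aas <- unique(gc[paste0(combos[[1L]], combos[[2L]], combos[[3L]])])
  if (length(aas) == 1L) aas else "X"
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1L]]]), collapse = "")
}

oracle_translate <- function(seq, offset) {
  n_codons <- (nchar(seq) - offset) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  paste(vapply(substring(seq, starts, starts + 2L), oracle_translate_codon,
               character(1L)), collapse = "")
}

# Brute-force ORF enumeration: scan every frame of both strands position by
# position, accumulating stop-free runs.
oracle_orfs <- function(seq, min_len) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- oracle_revcomp(seq)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (o in 0:2) {
      aa <- oracle_translate(s, o)
      if (!nchar(aa)) next
      chars <- strsplit(aa, "")[[1L]]
      run_start <- NA_integer_
      for (j in seq_len(length(chars) + 1L)) {
        in_seq <- j <= length(chars) && chars[j] != "*"
        if (in_seq && is.na(run_start)) run_start <- j
        if (!in_seq && !is.na(run_start)) {
          run_len <- j - run_start
          if (run_len >= min_len) {
            s_aa <- run_start; e_aa <- j - 1L
            if (strand == 1L) {
              nt_start <- o + 3L * (s_aa - 1L); nt_end <- o + 3L * e_aa
            } else {
              nt_start <- L - o - 3L * e_aa; nt_end <- L - o - 3L * (s_aa - 1L)
            }
            out[[length(out) + 1L]] <- data.frame(
              frame = sprintf("%+d", strand * (o + 1L)),
              nt_start = nt_start, nt_end = nt_end,
              aa_sequence = paste(chars[s_aa:e_aa], collapse = ""))
          }
          run_start <- NA_integer_
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = character(), nt_start = integer(),
                      nt_end = integer(), aa_sequence = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$frame, res$nt_start), , drop = FALSE]
}

# Exhaustive upper-tail binomial sum P(X >= k), X ~ Binomial(n, p)
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0L) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1L)))
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}
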