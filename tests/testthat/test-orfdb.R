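test_that("six-frame translation handles the worked codon examples", {
  f <- six_frame_translate("ATGAAATAG")
  expect_equal(f[, "+1"], "MK*", ignore_attr = TRUE)
  expect_equal(six_frame_translate("CTATTTCAT")[, "-1"], "MK*",
               ignore_attr = TRUE)
  # empty input: six empty strings
  expect_equal(unname(six_frame_translate("")[1L, ]), rep("", 6L))
  # lower case accepted; unknown symbol rejected with position
  expect_equal(six_frame_translate("atgaaatag")[, "+1"], "MK*",
               ignore_attr = TRUE)
  expect_error(six_frame_translate("ATGAUA"), "position 5")
})

test_that("ambiguity codes translate to X unless uniquely resolvable", {
  f <- six_frame_translate("GCNATGNNN")[, "+1"]
  expect_equal(unname(f), "AMX")  # GCN -> Ala uniquely, NNN -> X
  # X does not terminate an ORF
  orfs <- extract_orfs(six_frame_translate(strrep("GCNNNNGCA", 20L))[1L, ],
                       min_len = 10L, trace_len = 180L)
  expect_equal(nrow(orfs[orfs$frame == "+1", ]), 1L)
})

test_that("six frames jointly cover every codon of both strands once", {
  set.seed(101)
  for (L in c(29L, 300L, 1001L)) {
    tr <- random_dna(L)
    f <- six_frame_translate(tr)[1L, ]
    per_strand <- sum((L - 0:2) %/% 3L)
    expect_equal(sum(nchar(f)), 2L * per_strand)
  }
})

test_that("boundary at the minimum ORF length is inclusive", {
  # one 49-residue and one 50-residue stop-free run in frame +1
  aa49 <- random_aa(49L); aa50 <- random_aa(50L)
  frames <- setNames(rep("", 6L), c("+1", "+2", "+3", "-1", "-2", "-3"))
  frames["+1"] <- paste0(aa49, "*", aa50)
  orfs <- extract_orfs(frames, min_len = 50L, trace_len = 300L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_sequence, aa50)
  # frame of all stops yields nothing
  frames["+1"] <- strrep("*", 60L)
  expect_equal(nrow(extract_orfs(frames, min_len = 1L, trace_len = 180L)), 0L)
})

test_that("ORF extraction matches the brute-force frame scanner", {
  set.seed(202)
  for (rep in 1:100) {
    L <- 1000L
    tr <- random_dna(L, gc = runif(1, 0.3, 0.6))
    min_len <- sample(c(10L, 25L, 50L), 1L)
    got <- build_orf_db(setNames(tr, "t1"), min_len = min_len)
    want <- oracle_orfs(tr, min_len)
    got <- got[order(got$frame, got$nt_start),
               c("frame", "nt_start", "nt_end", "aa_sequence")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("ORF nucleotide coordinates point back at the coding substring", {
  set.seed(303)
  tr <- random_dna(2000L)
  orfs <- build_orf_db(setNames(tr, "t1"), min_len = 20L)
  expect_true(all(orfs$nt_end - orfs$nt_start == 3L * nchar(orfs$aa_sequence)))
  expect_true(all(orfs$nt_start >= 0L & orfs$nt_end <= 2000L))
  for (i in seq_len(nrow(orfs))) {
    cds <- substr(tr, orfs$nt_start[i] + 1L, orfs$nt_end[i])
    if (startsWith(orfs$frame[i], "-")) cds <- oracle_revcomp(cds)
    expect_equal(unname(six_frame_translate(cds)[, "+1"]),
                 orfs$aa_sequence[i])
  }
})

test_that("URF deduplication collapses identical sequences with provenance", {
  seq60 <- random_aa(60L)
  orfs <- data.frame(
    trace_id = c("t1", "t2", "t3"), frame = c("+1", "-2", "+3"),
    nt_start = c(0L, 30L, 2L), nt_end = c(180L, 210L, 182L),
    aa_sequence = c(seq60, seq60, random_aa(60L)))
  urfs <- dedup_urfs(orfs)
  expect_equal(nrow(urfs), 2L)
  prov <- attr(urfs, "provenance")
  expect_equal(sum(prov$urf_id == urfs$urf_id[1L]), 2L)
  # identity over n distinct sequences
  distinct <- data.frame(trace_id = "t", frame = "+1", nt_start = 0L,
                         nt_end = 30L,
                         aa_sequence = vapply(1:25, function(i) random_aa(10L),
                                              character(1L)))
  expect_equal(nrow(dedup_urfs(distinct)), 25L)
  # checksum is a deterministic function of the sequence alone
  expect_identical(urf_checksum(seq60), urf_checksum(tolower(seq60)))
  expect_match(urfs$urf_id[1L], "^[0-9a-f]{32}$")
})

test_that("dedup never adds sequence", {
  set.seed(404)
  traces <- setNames(vapply(1:30, function(i) random_dna(600L), character(1L)),
                     paste0("t", 1:30))
  orfs <- build_orf_db(traces, min_len = 20L)
  urfs <- dedup_urfs(orfs)
  expect_lte(sum(nchar(urfs$aa_sequence)), sum(nchar(orfs$aa_sequence)))
})

test_that("URF FASTA round trip preserves ids, sequences and provenance", {
  set.seed(505)
  traces <- setNames(vapply(1:20, function(i) random_dna(800L), character(1L)),
                     paste0("t", 1:20))
  urfs <- dedup_urfs(build_orf_db(traces, min_len = 30L))
  path <- withr::local_tempfile(fileext = ".fa")
  write_urf_fasta(urfs, path)
  back <- read_urf_fasta(path)
  expect_identical(back$urf_id, urfs$urf_id)
  expect_identical(back$aa_sequence, urfs$aa_sequence)
  p1 <- attr(urfs, "provenance"); p2 <- attr(back, "provenance")
  expect_equal(p2[order(p2$urf_id, p2$trace_id, p2$nt_start), ],
               p1[order(p1$urf_id, p1$trace_id, p1$nt_start), ],
               ignore_attr = TRUE)
  # and the ids still match the sequences
  expect_identical(back$urf_id, urf_checksum(back$aa_sequence))
})

test_that("database splitting preserves order and respects the entry cap", {
  urfs <- data.frame(urf_id = sprintf("u%02d", 1:10),
                     aa_sequence = vapply(1:10, function(i) random_aa(12L),
                                          character(1L)))
  expect_length(split_database(urfs, 24L), 1L)
  parts <- split_database(urfs, 4L)
  expect_equal(vapply(parts, nrow, integer(1L)), c(4L, 4L, 2L),
               ignore_attr = TRUE)
  expect_equal(do.call(rbind, parts)$urf_id, urfs$urf_id)
})
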