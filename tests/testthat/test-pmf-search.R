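make_digest <- function(masses, parent = "p1") {
  data.table::data.table(parent_id = parent, start = seq_along(masses) - 1L,
                         sequence = vapply(seq_along(masses),
                                           function(i) random_aa(6L),
                                           character(1L)),
                         missed = 0L, mh_mass = sort(masses))
}

test_that("peak matching is within-tolerance, one-to-one and deterministic", {
  expect_equal(nrow(match_peaks(numeric(0),
                                make_digest(c(800, 900)))), 0L)
  set.seed(31)
  theo <- make_digest(sort(runif(5, 800, 2000)))
  m <- match_peaks(theo$mh_mass, theo, tolerance = 0.2)
  expect_equal(nrow(m), 5L)
  expect_equal(m$error, rep(0, 5L))
  # a peak 0.5 Da away from the nearest theoretical mass stays unmatched
  expect_equal(nrow(match_peaks(1000.5, make_digest(1000), tolerance = 0.2)),
               0L)
  # one-to-one: two peaks near one peptide use it once, best error first
  m2 <- match_peaks(c(1000.01, 1000.05), make_digest(1000), tolerance = 0.2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$peak_mass, 1000.01)
})

test_that("greedy matching never reuses a peak or a peptide", {
  set.seed(32)
  for (i in 1:25) {
    theo <- make_digest(sort(runif(30, 700, 1500)))
    peaks <- runif(15, 700, 1500)
    m <- match_peaks(peaks, theo, tolerance = 5)
    expect_false(anyDuplicated(m$peak_idx) > 0L)
    expect_false(anyDuplicated(m$pep_idx) > 0L)
    expect_true(all(abs(m$error) <= 5))
  }
})

test_that("binomial score matches the exhaustive summation oracle", {
  # no matches carry no evidence
  z <- score_hit(0L, 10L, 0.01)
  expect_equal(z$p_value, 1)
  expect_equal(z$score, 0)
  got <- score_hit(3L, 10L, 0.01)
  expect_equal(got$p_value, oracle_binom_tail(3L, 10L, 0.01),
               tolerance = 1e-12)
  for (n in c(5L, 17L, 30L)) {
    for (p in c(0.003, 0.05, 0.4)) {
      for (k in unique(c(0L, 1L, n %/% 2L, n))) {
        got <- score_hit(k, n, p)
        expect_equal(got$p_value, oracle_binom_tail(k, n, p),
                     tolerance = 1e-10)
        expect_equal(got$score, -10 * log10(got$p_value))
      }
    }
  }
  # tail monotonicity in k
  s <- score_hit(0:10, 10L, 0.05)$score
  expect_true(all(diff(s) > 0))
  # impossible null model is clamped with a warning
  expect_warning(z1 <- score_hit(4L, 10L, 1.2), "match probability")
  expect_equal(z1$score, 0)
})

test_that("a planted protein ranks first against a random background", {
  set.seed(33)
  source_prot <- random_aa(60L)
  bg <- data.frame(urf_id = sprintf("bg%03d", 1:500),
                   aa_sequence = vapply(1:500,
                                        function(i) random_aa(sample(50:90, 1L)),
                                        character(1L)))
  db <- rbind(bg, data.frame(urf_id = "source",
                             aa_sequence = source_prot))
  dig_true <- tryptic_peptides(source_prot, max_missed = 1L, min_length = 4L)
  peaks <- c(sample(dig_true$mh_mass, min(12L, nrow(dig_true))) +
               rnorm(min(12L, nrow(dig_true)), 0, 0.05),
             runif(5, 700, 3500))
  res <- search_spot(fingerprint("s1", peaks), list(forward = db),
                     tolerance = 0.2, top_n = 50L)
  expect_equal(res$hits$entry_id[1L], "source")
  expect_true(all(res$hits$score >= 0))
  expect_equal(res$hits$score, -10 * log10(res$hits$p_value))
  expect_true(all(res$hits$matched <= res$hits$n_peaks))
})

test_that("searching partitions and merging equals searching the whole db", {
  set.seed(34)
  db <- data.frame(urf_id = sprintf("u%03d", 1:60),
                   aa_sequence = vapply(1:60,
                                        function(i) random_aa(sample(50:80, 1L)),
                                        character(1L)))
  peaks <- c(head(tryptic_peptides(db$aa_sequence[7L], 1L, 4L)$mh_mass, 8L),
             runif(6, 700, 3000))
  fp <- fingerprint("s1", peaks)
  whole <- search_spot(fp, list(forward = db), top_n = 60L)
  parts <- split_database(db, 17L)
  merged <- search_spot(fp, list(forward = parts), top_n = 60L)
  expect_equal(merged$hits, whole$hits)
  expect_equal(merged$peptide_matches, whole$peptide_matches)
})

test_that("a single-entry database is rank one; empty databases warn", {
  db <- data.frame(urf_id = "only", aa_sequence = random_aa(60L))
  fp <- fingerprint("s", c(900, 1200))
  res <- search_spot(fp, list(forward = db))
  expect_equal(res$hits$entry_id, "only")
  expect_warning(
    empty <- search_spot(fp, list(forward = data.frame(
      parent_id = character(), start = integer(), sequence = character(),
      missed = integer(), mh_mass = numeric()))),
    "empty database")
  expect_equal(nrow(empty$hits), 0L)
})

test_that("forward and decoy labels run through one code path symmetrically", {
  set.seed(35)
  db <- data.frame(urf_id = sprintf("u%d", 1:50),
                   aa_sequence = vapply(1:50, function(i) random_aa(70L),
                                        character(1L)))
  fp <- fingerprint("s", runif(12, 700, 3000))
  # same sequences presented under both labels give identical scores
  res <- search_spot(fp, list(forward = db,
                              decoy = data.frame(urf_id = db$urf_id,
                                                 aa_sequence = db$aa_sequence)))
  fwd <- res$hits[res$hits$db_label == "forward", ]
  dec <- res$hits[res$hits$db_label == "decoy", ]
  expect_equal(fwd$score, dec$score)
  expect_equal(fwd$entry_id, dec$entry_id)
})

test_that("unique-peptide collapse keeps the best score and all carriers", {
  pm <- data.frame(
    spot_id = c("s1", "s1", "s2", "s1"),
    db_label = c("forward", "forward", "forward", "decoy"),
    entry_id = c("u1", "u2", "u1", "d1"),
    peptide_sequence = c("AAK", "AAK", "CCR", "AAK"),
    score = c(40, 55, 30, 12))
  out <- collapse_unique_peptides(pm)
  fwd_aak <- out[out$peptide_sequence == "AAK" & out$db_label == "forward", ]
  expect_equal(fwd_aak$best_score, 55)
  expect_equal(fwd_aak$n_entries, 2L)
  expect_equal(fwd_aak$entry_ids, "u1;u2")
  # one record per distinct (peptide, label)
  expect_equal(nrow(out), 3L)
  expect_equal(out[out$db_label == "decoy", ]$best_score, 12)
})

test_that("MGF and two-column peak lists round-trip through the parsers", {
  fps <- list(fingerprint("spotA", c(1200.5, 800.25, 2100.125)),
              fingerprint("spotB", c(950.5, 1500.75)))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(fps, path)
  back <- read_mgf(path)
  expect_equal(vapply(back, `[[`, character(1L), "spot_id"),
               c("spotA", "spotB"))
  expect_equal(back[[1L]]$peaks, sort(c(1200.5, 800.25, 2100.125)))
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# spot peaks", "800.25\t100", "1200.5\t55"), txt)
  fp <- read_peaklist(txt, spot_id = "s9")
  expect_equal(fp$peaks, c(800.25, 1200.5))
})
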