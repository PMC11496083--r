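## reference_builder: rules, flank chains, the containment guarantee

write_rules <- function(lines) {
  p <- tempfile(fileext = ".rules")
  writeLines(lines, p)
  p
}

test_that("rules files parse into validated feature and follows sets", {
  m <- manual_model(rep(200L, 8))
  r <- parse_rules(write_rules(c(
    "# toy rules",
    "feature RA exon E4",
    "feature RO junction E3 E7",
    "follows E3: E4, E5, E6, E7",
    "follows E4: E5")), m)
  expect_s3_class(r, "build_rules")
  expect_equal(nrow(r$features), 2L)
  expect_equal(r$follows$E3, c("E4", "E5", "E6", "E7"))
  expect_error(parse_rules(write_rules(c(
    "feature RA exon E4", "follows E5: E4")), m), "transcript order")
  expect_error(parse_rules(write_rules("feature RA exon E99"), m),
               "unknown exon")
  expect_error(parse_rules(write_rules("feature RO junction E7 E3"), m),
               "junction")
  expect_error(parse_rules(write_rules("# only comments"), m),
               "no features")
})

test_that("flank length is read length minus the guaranteed overlap", {
  expect_equal(compute_flank_length(98, 1), 97L)
  expect_equal(compute_flank_length(91, 5), 86L)
  expect_error(compute_flank_length(8, 5), "2\\*min_overlap")
})

test_that("flank chains extend until the flank length is reached", {
  ## all exons 200 bp: one exon alone already exceeds a 97 bp flank
  m <- manual_model(rep(200L, 8), seed = 5)
  r <- parse_rules(write_rules(c(
    "feature RA exon E4",
    "follows E4: E5, E7",
    "follows E5: E7")), m)
  ch <- enumerate_flank_chains(r, m, "E4", "downstream", 97)
  expect_setequal(vapply(ch$chains, paste, "", collapse = "-"),
                  c("E5", "E7"))
  expect_true(all(nchar(ch$flanks) == 97))

  ## short E5 (40 bp) forces the chain to continue into E7
  m2 <- manual_model(c(200L, 200L, 200L, 200L, 40L, 200L, 200L, 200L),
                     seed = 6)
  r2 <- parse_rules(write_rules(c(
    "feature RA exon E4",
    "follows E4: E5, E7",
    "follows E5: E7")), m2)
  ch2 <- enumerate_flank_chains(r2, m2, "E4", "downstream", 97)
  expect_setequal(vapply(ch2$chains, paste, "", collapse = "-"),
                  c("E5-E7", "E7"))

  ## 3' terminal anchor: single empty chain, flank shorter than requested
  ch3 <- enumerate_flank_chains(r, m, "E8", "downstream", 97)
  expect_length(ch3$chains, 1L)
  expect_identical(ch3$chains[[1]], character(0))
  expect_identical(ch3$flanks, "")
})

test_that("upstream chains are reported 5'->3' and truncate to the last bases", {
  m <- manual_model(c(200L, 30L, 40L, 200L, 200L, 200L, 200L), seed = 7)
  r <- parse_rules(write_rules(c(
    "feature RA exon E4",
    "follows E1: E2", "follows E2: E3", "follows E3: E4")), m)
  ch <- enumerate_flank_chains(r, m, "E4", "upstream", 97)
  ## E3 (40) + E2 (30) < 97, so the chain climbs into E1
  expect_identical(ch$chains[[1]], c("E1", "E2", "E3"))
  full <- paste(cd45iso:::exon_seq(m, c("E1", "E2", "E3")), collapse = "")
  expect_equal(ch$flanks[1], substr(full, nchar(full) - 96, nchar(full)))
})

test_that("reference construction arithmetic matches the flank layout", {
  lens <- cd45iso:::exon_lengths(toy9$model)
  tx <- toy_ref98$transcripts
  ro <- tx[tx$feature == "RO", ]
  expect_equal(nrow(ro), 1L) # both junction exons exceed the flank length
  expect_equal(nchar(ro$sequence), 194L)
  expect_equal(c(ro$fs, ro$fe), c(97L, 97L))
  ra <- tx[tx$feature == "RA", ]
  expect_equal(nrow(ra), 3L) # one upstream chain x three skip patterns
  expect_true(all(nchar(ra$sequence) == 97L + lens[["E4"]] + 97L))
  expect_true(all(ra$fs == 97L & ra$fe == 97L + lens[["E4"]]))
  rb <- tx[tx$feature == "RB", ]
  expect_equal(nrow(rb), 4L) # {E3,E4} upstream x {E6,E7} downstream
})

test_that("every fully contained window overlaps its feature (guarantee)", {
  set.seed(11)
  for (rep in 1:8) {
    n_ex <- sample(7:12, 1)
    m <- make_toy_model(n_exons = n_ex,
                        exon_len_range = c(60L, 250L),
                        intron_len_range = c(50L, 300L),
                        seed = 1000 + rep)$model
    k <- sample(1:10, 1)
    R <- sample(max(50, 2 * k):150, 1)
    rs <- build_reference(m, default_ptprc_rules(m), R, k)
    expect_equal(window_scan_violations(rs), 0L)
  }
})

test_that("written references are byte-identical across reruns", {
  f1 <- tempfile(); t1 <- tempfile()
  f2 <- tempfile(); t2 <- tempfile()
  write_reference(toy_ref98, f1, t1)
  write_reference(toy_ref98, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  ## FASTA record count == transcript count; t2g rows match
  expect_equal(sum(startsWith(readLines(f1), ">")),
               nrow(toy_ref98$transcripts))
  expect_equal(length(readLines(t1)), nrow(toy_ref98$transcripts))
})

test_that("default CD45 rules need at least seven exons", {
  m33 <- make_toy_model(n_exons = 33, seed = 33)$model
  r <- default_ptprc_rules(m33)
  expect_equal(r$features$name, c("RA", "RB", "RC", "RO"))
  m6 <- manual_model(rep(100L, 6))
  expect_error(default_ptprc_rules(m6), "model too short")
  rs <- build_reference(m33, r, 98, 1)
  expect_equal(window_scan_violations(rs), 0L)
})

test_that("exhaustive windows over rule-consistent transcripts classify correctly", {
  ## slide every read-length window over every isoform transcript and
  ## check the k-mer call against transcript-space geometry
  idx <- toy_index_k21
  rules <- toy_rules
  for (lab in c("RABC", "RAC", "RB", "RO")) {
    lay <- cd45iso:::isoform_layout(toy9$model, lab, rules)
    tx <- isoform_sequence(toy9$model, lab)
    starts <- seq(1L, nchar(tx) - 98L + 1L, by = 13L)
    seqs <- substring(tx, starts, starts + 97L)
    got <- classify_reads(seqs, idx, min_kmer_frac = 1)
    want <- lapply(starts, function(s)
      cd45iso:::read_truth_features(lay, s, 98L, 21L))
    expect_identical(got, want, label = paste("isoform", lab))
  }
})
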