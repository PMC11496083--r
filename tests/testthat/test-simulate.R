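## synthetic_fixtures: toy models, isoform transcripts, spliced reads

test_that("toy models are deterministic, in range, and non-overlapping", {
  a <- make_toy_model(n_exons = 9, seed = 5)
  b <- make_toy_model(n_exons = 9, seed = 5)
  expect_identical(a$model$exons, b$model$exons)
  expect_identical(as.character(a$genome), as.character(b$genome))
  lens <- a$model$exons$end - a$model$exons$start + 1
  expect_true(all(lens >= 120 & lens <= 200))
  ## different seed, different genome
  expect_false(identical(as.character(a$genome),
                         as.character(make_toy_model(seed = 6)$genome)))
  expect_error(make_toy_model(n_exons = 5), "at least 7")
  expect_error(make_toy_model(exon_len_range = c(50, 10)), "ranges")
})

test_that("isoform transcripts contain exactly the labelled exons", {
  m <- toy9$model
  lens <- cd45iso:::exon_lengths(m)
  ## RO: exon 3 abuts exon 7
  ro <- isoform_sequence(m, "RO")
  e3 <- m$exons$sequence[3]; e7 <- m$exons$sequence[7]
  j <- sum(lens[1:3])
  expect_equal(substr(ro, j - 19, j + 20),
               paste0(substr(e3, nchar(e3) - 19, nchar(e3)),
                      substr(e7, 1, 20)))
  expect_equal(nchar(ro), sum(lens[c(1:3, 7:9)]))
  ## RABC: everything
  expect_equal(nchar(isoform_sequence(m, "RABC")), sum(lens))
  ## single alternative exons
  expect_equal(nchar(isoform_sequence(m, "RB")),
               sum(lens[c(1:3, 5, 7:9)]))
  expect_error(isoform_sequence(m, "RQ"), "invalid isoform")
})

test_that("simulated reads carry valid spliced CIGARs and exact gaps", {
  sim <- simulate_reads(toy9$model, random_profiles(10, seed = 17),
                        read_len = 98, seed = 17, reads_per_molecule = 3)
  ## query-consuming ops add up to the read length, for every read
  widths <- GenomicAlignments::cigarWidthAlongQuerySpace(sim$reads$cigar)
  expect_true(all(widths == 98L))
  ## reference span stays inside the toy genome
  glen <- nchar(as.character(toy9$genome[[1]]))
  ends <- sim$reads$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(sim$reads$cigar) - 1L
  expect_true(all(sim$reads$pos >= 1 & ends <= glen))
  ## an RO junction read shows one N gap of exactly the E3-E7 intron
  ex <- toy9$model$exons
  intron <- ex$start[7] - ex$end[3] - 1L
  ro_j <- sim$reads$isoform == "RO" & grepl("N", sim$reads$cigar) &
    sim$reads$features == "RO"
  expect_gt(sum(ro_j), 0)
  expect_true(all(grepl(sprintf("^[0-9]+M%dN[0-9]+M$", intron),
                        sim$reads$cigar[ro_j])))
  ## the read sequence equals the genome lifted through the CIGAR
  g <- as.character(toy9$genome[[1]])
  i <- which(ro_j)[1]
  parts <- regmatches(sim$reads$cigar[i],
                      regexec("^([0-9]+)M[0-9]+N([0-9]+)M$",
                              sim$reads$cigar[i]))[[1]]
  m1 <- as.integer(parts[2]); m2 <- as.integer(parts[3])
  expect_equal(sim$reads$seq[i],
               paste0(substr(g, sim$reads$pos[i],
                             sim$reads$pos[i] + m1 - 1L),
                      substr(g, ex$start[7], ex$start[7] + m2 - 1L)))
})

test_that("simulation is reproducible and respects transcript bounds", {
  pr <- random_profiles(4, seed = 23)
  s1 <- simulate_reads(toy9$model, pr, seed = 23)
  s2 <- simulate_reads(toy9$model, pr, seed = 23)
  expect_identical(s1$sam, s2$sam)
  expect_error(simulate_reads(toy9$model, pr, read_len = 10000),
               "exceeds transcript length")
})

test_that("per-read truth sets are subsets of the molecule's feature set", {
  sim <- simulate_reads(toy9$model, random_profiles(8, seed = 29),
                        read_len = 98, seed = 29, reads_per_molecule = 4,
                        min_feature_overlap = 21)
  key <- paste(sim$reads$barcode, sim$reads$umi)
  mol_key <- paste(sim$truth$molecules$barcode, sim$truth$molecules$umi)
  split_feats <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                    function(v) v[nzchar(v)])
  read_f <- split_feats(sim$reads$features)
  mol_f <- split_feats(sim$truth$molecules$features)[match(key, mol_key)]
  expect_true(all(mapply(function(r, m) all(r %in% m), read_f, mol_f)))
  ## and the union over a molecule's reads equals its recorded set
  uni <- lapply(split(read_f, key), function(l) sort(unique(unlist(l))))
  for (mk in mol_key)
    expect_identical(uni[[mk]],
                     sort(unlist(split_feats(
                       sim$truth$molecules$features[mol_key == mk]))))
  ## the genomic oracle agrees with the recorded per-read truth
  g <- classify_reads_genomic(sim$reads, toy9$model, toy_rules, k = 21)
  expect_identical(g, lapply(read_f, function(x) sort(x)))
})

test_that("expected counts follow union-then-split over molecules", {
  pr <- list(CELL1 = c(RABC = 2, RO = 1))
  sim <- simulate_reads(toy9$model, pr, seed = 3,
                        informative_only = TRUE, min_feature_overlap = 21)
  ec <- sim$truth$expected_counts
  expect_equal(dim(ec), c(4L, 1L))
  expect_equal(sum(ec), 3) # three molecules, unit weight each
  expect_equal(as.numeric(ec["RO", ]), 1)
})
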