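## quantifier: k-mer classification, genomic oracle, counting

## tiny hand-made reference set wrapper
mini_refset <- function(seqs, features, read_len = 98L, min_overlap = 1L) {
  structure(list(
    transcripts = data.frame(
      ref_id = paste0("r", seq_along(seqs)), feature = features,
      up_chain = ".", down_chain = ".", sequence = seqs,
      fs = 0L, fe = nchar(seqs), stringsAsFactors = FALSE),
    feature_names = unique(features),
    read_len = read_len, min_overlap = min_overlap,
    flank_len = read_len - min_overlap), class = "reference_set")
}

test_that("the k-mer index covers every reference k-mer position", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 194, replace = TRUE),
             collapse = "")
  idx <- build_index(mini_refset(s, "RA"), k = 31)
  positions <- sum(lengths(as.list(idx$env)))
  expect_equal(positions, 194 - 31 + 1) # L - k + 1
  ## a k-mer shared by two references maps to both
  idx2 <- build_index(mini_refset(c(s, substr(s, 50, 120)),
                                  c("RA", "RB")), k = 31)
  shared <- cd45iso:::seq_kmers(substr(s, 50, 120), 31)[1]
  expect_setequal(get(shared, idx2$env), c(1L, 2L))
  expect_error(build_index(mini_refset("ACGTACGTACGT", "RA"), k = 21),
               "shortest")
  expect_error(build_index(mini_refset(s, "RA"), k = 5), ">= 11")
})

test_that("k-mer classification hits features, both strands, or nothing", {
  tx <- toy_ref_k21$transcripts
  ra_seq <- tx$sequence[tx$feature == "RA"][1]
  inside <- substr(ra_seq, tx$fs[tx$feature == "RA"][1] + 1,
                   tx$fs[tx$feature == "RA"][1] + 98)
  expect_equal(classify_read(inside, toy_index_k21, 1), "RA")
  ## antisense read: best-strand matching recovers the same feature
  expect_equal(classify_read(cd45iso:::revcomp(inside), toy_index_k21, 1),
               "RA")
  ## a read spanning the E4-E5 junction supports both RA and RB
  rab <- isoform_sequence(toy9$model, "RAB")
  lay <- cd45iso:::isoform_layout(toy9$model, "RAB", toy_rules)
  e4_end <- lay$ce[match("E4", lay$exons$exon_id)]
  spanning <- substr(rab, e4_end - 48, e4_end + 49)
  expect_equal(classify_read(spanning, toy_index_k21, 1), c("RA", "RB"))
  ## random sequence stays unassigned
  set.seed(4)
  noise <- paste(sample(c("A", "C", "G", "T"), 98, replace = TRUE),
                 collapse = "")
  expect_length(classify_read(noise, toy_index_k21, 1), 0L)
})

test_that("the genomic oracle reads CIGAR geometry", {
  ex <- toy9$model$exons
  e4 <- ex[ex$exon_id == "E4", ]
  e3 <- ex[ex$exon_id == "E3", ]
  e7 <- ex[ex$exon_id == "E7", ]
  ## fully exonic read inside exon 4
  r1 <- rec_df("a", pos = e4$start, cigar = "98M", seq = strrep("A", 98))
  expect_equal(classify_reads_genomic(r1, toy9$model, toy_rules, k = 1)[[1]],
               "RA")
  ## spliced read bridging exon 3 end to exon 7 start
  gap <- e7$start - e3$end - 1L
  r2 <- rec_df("b", pos = e3$end - 48L,
               cigar = sprintf("49M%dN49M", gap), seq = strrep("A", 98))
  expect_equal(classify_reads_genomic(r2, toy9$model, toy_rules, k = 1)[[1]],
               "RO")
  expect_equal(classify_reads_genomic(r2, toy9$model, toy_rules, k = 49)[[1]],
               "RO")
  ## k-1 overlap stays below the reporting threshold
  k <- 5L
  r3 <- rec_df("c", pos = e4$start - 94L, cigar = "98M",
               seq = strrep("A", 98)) # overlaps exon 4 by 4 bases
  expect_length(classify_reads_genomic(r3, toy9$model, toy_rules,
                                       k = k)[[1]], 0L)
  ## a gap not matching the intron exactly is not a junction call
  r4 <- rec_df("d", pos = e3$end - 48L,
               cigar = sprintf("49M%dN49M", gap - 2L), seq = strrep("A", 98))
  expect_length(classify_reads_genomic(r4, toy9$model, toy_rules,
                                       k = 1)[[1]], 0L)
  expect_error(classify_reads_genomic(rec_df("e", pos = -1L), toy9$model,
                                      toy_rules), "unmapped")
})

asg <- function(qname, barcode, umi, features) {
  out <- data.frame(qname = qname, barcode = barcode, umi = umi,
                    features = features, stringsAsFactors = FALSE)
  attr(out, "feature_names") <- c("RA", "RB", "RC", "RO")
  out
}

test_that("UMI groups contribute unit weight split across their features", {
  ## three reads of one molecule: one UMI count, not three
  m <- quantify(asg(c("r1", "r2", "r3"), "C1", "U1",
                    c("RA", "RA", "RA")), whitelist = c("C1", "C2"))
  expect_equal(as.numeric(m["RA", ]), c(1, 0))
  ## a two-feature molecule splits 0.5/0.5
  m2 <- quantify(asg("r1", "C1", "U1", "RA;RB"), whitelist = "C1")
  expect_equal(as.numeric(m2[, "C1"]), c(0.5, 0.5, 0, 0))
  ## distinct UMIs count separately
  m3 <- quantify(asg(c("r1", "r2"), "C1", c("U1", "U2"),
                     c("RA", "RO")), whitelist = "C1")
  expect_equal(as.numeric(m3[, "C1"]), c(1, 0, 0, 1))
  ## union-then-split: reads of one molecule disagreeing -> union set
  m4 <- quantify(asg(c("r1", "r2"), "C1", "U1", c("RA", "RO")),
                 whitelist = "C1")
  expect_equal(as.numeric(m4[, "C1"]), c(0.5, 0, 0, 0.5))
  ## unassigned reads contribute nothing; whitelisted cell stays as column
  m5 <- quantify(asg("r1", "C1", "U1", ""), whitelist = "C1")
  expect_equal(sum(m5), 0)
  expect_equal(dim(m5), c(4L, 1L))
  expect_error(quantify(asg("r", "C", "U", "RA"), whitelist = character(0)),
               "empty whitelist")
})

test_that("weight is conserved: matrix total equals assigned UMI groups", {
  set.seed(77)
  n <- 400
  feats <- replicate(n, paste(sample(c("RA", "RB", "RC", "RO"),
                                     sample(0:3, 1)), collapse = ";"))
  a <- asg(sprintf("r%03d", 1:n),
           sample(paste0("C", 1:12), n, replace = TRUE),
           sample(paste0("U", 1:25), n, replace = TRUE),
           feats)
  m <- quantify(a)
  key <- paste(a$barcode, a$umi)
  n_groups <- length(unique(key[nzchar(a$features)]))
  expect_equal(sum(m), n_groups)
  ## forced-cells keeps the top-N columns by weight
  mf <- quantify(a, forced_cells = 5)
  expect_equal(ncol(mf), 5L)
  tot <- Matrix::colSums(m)
  expect_setequal(colnames(mf),
                  names(sort(tot, decreasing = TRUE))[1:5])
})

test_that("count matrices add over the barcode union", {
  a <- quantify(asg("r1", "C1", "U1", "RA"), whitelist = c("C1", "C2"))
  b <- quantify(asg(c("r2", "r3"), c("C2", "C3"), c("U1", "U2"),
                    c("RA", "RB")), whitelist = c("C2", "C3"))
  m <- merge_counts(a, b)
  expect_equal(colnames(m), c("C1", "C2", "C3"))
  expect_equal(as.numeric(m["RA", ]), c(1, 1, 0))
  expect_equal(as.numeric(m["RB", ]), c(0, 0, 1))
  ## identity: adding an all-zero matrix changes nothing
  z <- quantify(asg("r", "C1", "U1", ""), whitelist = c("C1", "C2"))
  expect_equal(as.matrix(merge_counts(a, z)), as.matrix(a))
  ## commutative and associative
  expect_equal(as.matrix(merge_counts(a, b)), as.matrix(merge_counts(b, a)))
  c3 <- quantify(asg("r4", "C1", "U9", "RO"), whitelist = "C1")
  expect_equal(as.matrix(merge_counts(merge_counts(a, b), c3)),
               as.matrix(merge_counts(a, merge_counts(b, c3))))
  expect_error(merge_counts(a, a[1:2, , drop = FALSE]), "feature sets")
})

test_that("log normalization is per cell with zero-total cells at zero", {
  m <- Matrix::Matrix(c(10, 90, 0, 0), 2, 2, sparse = TRUE,
                      dimnames = list(c("RA", "RO"), c("C1", "C2")))
  ln <- log_normalize(m, scale = 1e4)
  expect_equal(ln["RA", "C1"], log2(1 + 1e4 * 10 / 100)) # log2(1001)
  expect_equal(ln["RA", "C1"], 9.967226, tolerance = 1e-6)
  expect_equal(as.numeric(ln[, "C2"]), c(0, 0))
  ## single feature carrying the whole cell: log2(1 + scale)
  m2 <- Matrix::Matrix(5, 1, 1, dimnames = list("RA", "C1"))
  expect_equal(log_normalize(m2, 1e4)[1, 1], log2(1 + 1e4))
})
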