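## Shared fixtures, built once per test run.

toy9 <- make_toy_model(seed = 101)
toy_rules <- default_ptprc_rules(toy9$model)
toy_ref98 <- build_reference(toy9$model, toy_rules, read_len = 98,
                             min_overlap = 1)
## validation reference: guaranteed overlap = one full k-mer, so k-mer
## containment and genomic overlap are exactly equivalent on clean reads
toy_ref_k21 <- build_reference(toy9$model, toy_rules, read_len = 98,
                               min_overlap = 21)
toy_index_k21 <- build_index(toy_ref_k21, 21)

## a gene model with chosen exon lengths on a random + strand genome
manual_model <- function(exon_lens, intron_len = 150L, seed = 1L,
                         gene_id = "g", chrom = "chrM") {
  set.seed(seed)
  n <- length(exon_lens)
  starts <- 101L + cumsum(c(0L, exon_lens[-n] + intron_len))
  ends <- starts + exon_lens - 1L
  genome_seq <- paste(sample(c("A", "C", "G", "T"), ends[n] + 100L,
                             replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
  m <- cd45iso:::new_gene_model(
    gene_id, chrom, "+",
    data.frame(exon_id = paste0("E", seq_len(n)), start = starts, end = ends))
  attach_sequences(m, genome)
}

## number of fully-contained read windows violating the feature-overlap
## guarantee, by exhaustive window enumeration (independent of the k-mer
## classifier)
window_scan_violations <- function(refset) {
  tx <- refset$transcripts
  R <- refset$read_len
  k <- refset$min_overlap
  total <- 0L
  for (i in seq_len(nrow(tx))) {
    L <- nchar(tx$sequence[i])
    if (L < R) next
    s <- 0:(L - R) # 0-based window starts, windows [s, s+R)
    ok <- if (tx$fs[i] == tx$fe[i]) {
      (tx$fs[i] - s >= k) & (s + R - tx$fs[i] >= k)
    } else {
      (pmin(s + R, tx$fe[i]) - pmax(s, tx$fs[i])) >= k
    }
    total <- total + sum(!ok)
  }
  total
}

## random cell profiles for simulation
random_profiles <- function(n_cells, umi_range = 1:3, n_iso = 4L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bcs <- unique(apply(matrix(sample(c("A", "C", "G", "T"), n_cells * 16L,
                                    replace = TRUE), n_cells), 1,
                      paste, collapse = ""))
  while (length(bcs) < n_cells)
    bcs <- unique(c(bcs, paste(sample(c("A", "C", "G", "T"), 16L,
                                      replace = TRUE), collapse = "")))
  stats::setNames(lapply(seq_len(n_cells), function(i) {
    labs <- sample(cd45iso:::valid_isoform_labels(), n_iso)
    stats::setNames(sample(umi_range, n_iso, replace = TRUE), labs)
  }), bcs)
}

## minimal records data.frame builder for unit tests
rec_df <- function(qname, barcode = "B1", umi = "U1", seq = "ACGT",
                   chrom = "chrT", pos = 1L, cigar = "4M", mapq = 255L,
                   flag = 0L, nh = NA_integer_) {
  df <- data.frame(qname = qname, barcode = barcode, umi = umi, seq = seq,
                   chrom = chrom, pos = pos, cigar = cigar, mapq = mapq,
                   flag = flag, nh = nh, stringsAsFactors = FALSE)
  df$len <- nchar(df$seq)
  df
}
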