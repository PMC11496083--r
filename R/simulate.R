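#' Synthetic multi-exon gene and spliced-read simulation
#'
#' A self-contained generator for everything the pipeline consumes: a toy
#' plus-strand gene with alternatively spliced exons 4-6 embedded in a
#' random genome, rule-consistent isoform transcripts (RABC ... RO), and
#' barcoded, UMI-tagged spliced reads emitted as SAM text with exact
#' N-gapped CIGARs plus a ground-truth table. Reads are sampled from the
#' spliced transcript and lifted back to genomic coordinates, mirroring
#' cDNA sequencing, so junction reads are consistent by construction.
#'
#' @name synthetic_fixtures
NULL

## run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a toy gene model embedded in a random genome
#'
#' Exons of random length are placed on the plus strand of a single random
#' chromosome, separated by random introns, with padding on both sides.
#' Deterministic for a given seed.
#'
#' @param n_exons number of exons (>= 7 so the default CD45-style rules
#'   apply; default 9).
#' @param exon_len_range integer range of exon lengths (default 120-200,
#'   comfortably above typical read lengths' k-mer size).
#' @param intron_len_range integer range of intron lengths (default
#'   80-300).
#' @param seed RNG seed.
#' @param gene_id,chrom identifiers used in the model, GTF and SAM.
#' @return list with `model` (a `gene_model` with sequences) and `genome`
#'   (a [Biostrings::DNAStringSet] with one chromosome).
#' @export
make_toy_model <- function(n_exons = 9L, exon_len_range = c(120L, 200L),
                           intron_len_range = c(80L, 300L), seed = 1L,
                           gene_id = "toygene", chrom = "chrT") {
  if (n_exons < 7L) stop("need at least 7 exons")
  if (exon_len_range[1] > exon_len_range[2] || exon_len_range[1] < 1L ||
      intron_len_range[1] > intron_len_range[2] || intron_len_range[1] < 1L)
    stop("invalid length ranges")
  with_seed(seed, {
    elens <- sample(exon_len_range[1]:exon_len_range[2], n_exons,
                    replace = TRUE)
    ilens <- sample(intron_len_range[1]:intron_len_range[2], n_exons - 1L,
                    replace = TRUE)
    pad <- 100L
    starts <- pad + 1L + cumsum(c(0L, elens[-n_exons] + ilens))
    ends <- starts + elens - 1L
    glen <- ends[n_exons] + pad
    genome_seq <- rand_dna(glen)
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
    model <- new_gene_model(
      gene_id, chrom, "+",
      data.frame(exon_id = paste0("E", seq_len(n_exons)),
                 start = starts, end = ends))
    model <- attach_sequences(model, genome)
    list(model = model, genome = genome)
  })
}

valid_isoform_labels <- function()
  c("RABC", "RAB", "RAC", "RBC", "RA", "RB", "RC", "RO")

## exon row indices (transcript order) included in an isoform
exons_for_label <- function(label, n_exons) {
  if (!label %in% valid_isoform_labels())
    stop("invalid isoform label: ", label)
  alt <- if (label == "RO") integer(0) else
    c(4L, 5L, 6L)[c(grepl("A", label), grepl("B", label), grepl("C", label))]
  sort(c(1:3, alt, 7:n_exons))
}

#' Spliced transcript sequence of a named isoform
#'
#' Constitutive exons (all but 4-6) plus the label's alternative exons, in
#' transcript order. `"RO"` skips exons 4-6 entirely, so exon 3 is directly
#' followed by exon 7.
#'
#' @param model a `gene_model` with sequences (>= 7 exons).
#' @param label one of `RABC, RAB, RAC, RBC, RA, RB, RC, RO`.
#' @return transcript sequence (character scalar).
#' @export
isoform_sequence <- function(model, label) {
  idx <- exons_for_label(label, nrow(model$exons))
  paste(model$exons$sequence[idx], collapse = "")
}

## transcript geometry of one isoform: per included exon, transcript-space
## interval [cs, ce] and genomic interval [gs, ge]; plus feature intervals
isoform_layout <- function(model, label, rules) {
  idx <- exons_for_label(label, nrow(model$exons))
  ex <- model$exons[idx, , drop = FALSE]
  lens <- ex$end - ex$start + 1L
  ce <- cumsum(lens); cs <- ce - lens + 1L
  feats <- rules$features
  fint <- list() # per feature: c(type, lo, hi) in transcript coords
  for (j in seq_len(nrow(feats))) {
    if (feats$kind[j] == "exon") {
      at <- match(feats$left[j], ex$exon_id)
      if (!is.na(at))
        fint[[feats$name[j]]] <- list(kind = "exon", lo = cs[at], hi = ce[at])
    } else {
      il <- match(feats$left[j], ex$exon_id)
      ir <- match(feats$right[j], ex$exon_id)
      if (!is.na(il) && !is.na(ir) && ir == il + 1L)
        fint[[feats$name[j]]] <- list(kind = "junction", p = ce[il])
    }
  }
  list(exons = ex, cs = cs, ce = ce, len = sum(lens), features = fint)
}

## truth feature set of a read [s, s+R-1] in transcript space
read_truth_features <- function(layout, s, R, k) {
  e <- s + R - 1L
  out <- character(0)
  for (nm in names(layout$features)) {
    f <- layout$features[[nm]]
    hit <- if (f$kind == "exon")
      (min(e, f$hi) - max(s, f$lo) + 1L) >= k
    else (f$p - s + 1L) >= k && (e - f$p) >= k
    if (hit) out <- c(out, nm)
  }
  sort(out)
}

## genomic POS and CIGAR of a transcript-space read [s, s+R-1]
project_read <- function(layout, s, R) {
  e <- s + R - 1L
  touched <- which(layout$ce >= s & layout$cs <= e)
  qlens <- pmin(e, layout$ce[touched]) - pmax(s, layout$cs[touched]) + 1L
  gstarts <- layout$exons$start[touched] +
    (pmax(s, layout$cs[touched]) - layout$cs[touched])
  gends <- gstarts + qlens - 1L
  cig <- paste0(qlens[1], "M")
  if (length(touched) > 1L)
    for (i in 2:length(touched))
      cig <- paste0(cig, gstarts[i] - gends[i - 1L] - 1L, "N",
                    qlens[i], "M")
  list(pos = gstarts[1], cigar = cig)
}

rand_tag <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate barcoded, UMI-tagged spliced reads with ground truth
#'
#' For every molecule (a `(cell, isoform, UMI)` triple) one or more reads
#' are drawn from uniform positions on the spliced transcript and projected
#' to genomic coordinates with exact N-gap CIGARs. Substitution errors are
#' applied at `error_rate`. With `informative_only = TRUE` start positions
#' are restricted to reads that overlap at least one feature of the
#' molecule's isoform by `min_feature_overlap` bases (junctions: that many
#' aligned bases on each side), which makes every molecule recoverable and
#' is the mode used for truth-recovery testing.
#'
#' @param model a plus-strand `gene_model` with sequences.
#' @param cell_profiles named list: barcode -> named integer vector of
#'   molecules per isoform label, e.g.
#'   `list(AAAC... = c(RABC = 5, RO = 3))`.
#' @param read_len read length (default 98, a typical 5' R2 length).
#' @param error_rate per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @param reads_per_molecule reads sequenced per molecule (default 1).
#' @param informative_only restrict read starts to feature-informative
#'   positions (default FALSE).
#' @param min_feature_overlap overlap threshold defining "informative" and
#'   used for the per-read truth feature sets (default 1; keep equal to the
#'   `min_overlap` the reference is built with when comparing pipeline
#'   output against the truth).
#' @param rules `build_rules` used for the truth annotation (default
#'   [default_ptprc_rules()] on the model).
#' @param umi_len UMI length (default 12, 10x v2+ shape; barcodes are taken
#'   verbatim from `names(cell_profiles)`).
#' @return list with
#'   `sam` (character vector: header + one line per read, CB/UB tagged),
#'   `reads` (per-read data.frame incl. truth `features`),
#'   `truth` (list: `molecules` data.frame and `expected_counts`, the
#'   features x barcodes matrix of UMI counts after union-then-split).
#' @export
simulate_reads <- function(model, cell_profiles, read_len = 98L,
                           error_rate = 0, seed = 1L,
                           reads_per_molecule = 1L,
                           informative_only = FALSE,
                           min_feature_overlap = 1L,
                           rules = NULL, umi_len = 12L) {
  stopifnot(inherits(model, "gene_model"))
  if (model$strand != "+")
    stop("the simulator emits plus-strand models only")
  if (is.null(rules)) rules <- default_ptprc_rules(model)
  labels <- unique(unlist(lapply(cell_profiles, names)))
  layouts <- lapply(stats::setNames(labels, labels),
                    function(l) isoform_layout(model, l, rules))
  txseqs <- lapply(stats::setNames(labels, labels),
                   function(l) isoform_sequence(model, l))
  short <- labels[vapply(layouts, function(x) x$len, 0) < read_len]
  if (length(short))
    stop("read_len exceeds transcript length for: ",
         paste(short, collapse = ", "))
  ## precompute admissible start positions per label
  starts_for <- lapply(stats::setNames(labels, labels), function(l) {
    lay <- layouts[[l]]
    s <- seq_len(lay$len - read_len + 1L)
    if (!informative_only) return(s)
    ok <- vapply(s, function(si)
      length(read_truth_features(lay, si, read_len,
                                 min_feature_overlap)) > 0L, logical(1))
    if (!any(ok)) stop("no informative positions for isoform ", l)
    s[ok]
  })
  glen <- model$locus_end + 100L
  with_seed(seed, {
    reads <- list(); mols <- list()
    rid <- 0L
    for (bc in names(cell_profiles)) {
      prof <- cell_profiles[[bc]]
      n_mol <- sum(prof)
      umis <- character(0)
      while (length(unique(umis)) < n_mol) # collisions are ~impossible, but be safe
        umis <- unique(c(umis, rand_tag(n_mol - length(unique(umis)), umi_len)))
      ui <- 0L
      for (lab in names(prof)) {
        lay <- layouts[[lab]]; tx <- txseqs[[lab]]
        for (mi in seq_len(prof[[lab]])) {
          ui <- ui + 1L
          umi <- umis[ui]
          mol_feats <- character(0)
          for (ri in seq_len(reads_per_molecule)) {
            rid <- rid + 1L
            s <- sample(starts_for[[lab]], 1L)
            sq <- substr(tx, s, s + read_len - 1L)
            if (error_rate > 0) {
              hit <- which(stats::runif(read_len) < error_rate)
              if (length(hit)) {
                ch <- strsplit(sq, "")[[1]]
                ch[hit] <- vapply(ch[hit], function(b)
                  sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
                sq <- paste(ch, collapse = "")
              }
            }
            pr <- project_read(lay, s, read_len)
            fts <- read_truth_features(lay, s, read_len, min_feature_overlap)
            mol_feats <- union(mol_feats, fts)
            reads[[rid]] <- data.frame(
              qname = sprintf("r%07d", rid), barcode = bc, umi = umi,
              isoform = lab, tstart = s, pos = pr$pos, cigar = pr$cigar,
              seq = sq, features = paste(sort(fts), collapse = ";"),
              stringsAsFactors = FALSE)
          }
          mols[[length(mols) + 1L]] <- data.frame(
            barcode = bc, umi = umi, isoform = lab,
            features = paste(sort(mol_feats), collapse = ";"),
            n_reads = reads_per_molecule, stringsAsFactors = FALSE)
        }
      }
    }
    reads <- do.call(rbind, reads)
    mols <- do.call(rbind, mols)
    feature_names <- rules$features$name
    barcodes <- names(cell_profiles)
    expected <- matrix(0, length(feature_names), length(barcodes),
                       dimnames = list(feature_names, barcodes))
    has <- nzchar(mols$features)
    for (i in which(has)) {
      fs <- strsplit(mols$features[i], ";", fixed = TRUE)[[1]]
      expected[fs, mols$barcode[i]] <-
        expected[fs, mols$barcode[i]] + 1 / length(fs)
    }
    sam <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, glen),
      sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s",
              reads$qname, model$chrom, reads$pos, reads$cigar, reads$seq,
              strrep("F", read_len), reads$barcode, reads$umi))
    list(sam = sam, reads = reads,
         truth = list(molecules = mols, expected_counts = expected))
  })
}

#' Write simulated SAM lines to a file
#'
#' @param sam character vector of SAM lines (header included).
#' @param path output path; use a `.sam` suffix so downstream readers
#'   convert it automatically.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  writeLines(sam, path)
  invisible(path)
}
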