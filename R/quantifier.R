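#' Read classification and per-cell counting
#'
#' Two independent classifiers are provided. The production route indexes
#' the discriminating reference by k-mers and assigns a read to every
#' reference in which at least `min_kmer_frac` of its k-mers occur (best of
#' the two strands), collapsing reference hits to the feature level. The
#' oracle route ignores the reference entirely and decides from the read's
#' genomic alignment geometry (CIGAR aligned blocks and N gaps) whether it
#' overlaps a feature exon by at least `k` bases or straddles a feature
#' junction with `k` aligned bases on each side. On error-free reads from
#' rule-consistent transcripts the two routes agree exactly when the k-mer
#' threshold is 1 (full containment).
#'
#' @name quantifier
NULL

## ---- k-mer index ----------------------------------------------------------

seq_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1L), k:L)
}

#' Build a k-mer index over a reference set
#'
#' @param refset a `reference_set` from [build_reference()].
#' @param k k-mer size (default 21; must be at least 11 and no longer than
#'   the shortest reference sequence).
#' @return a `feature_index` holding the k-mer -> reference map, the
#'   per-reference feature labels and the reference set itself.
#' @export
build_index <- function(refset, k = 21L) {
  stopifnot(inherits(refset, "reference_set"))
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  if (k > min(nchar(refset$transcripts$sequence)))
    stop("k exceeds the shortest reference sequence")
  tx <- refset$transcripts
  km <- lapply(tx$sequence, seq_kmers, k = k)
  pairs_ref <- rep.int(seq_len(nrow(tx)), lengths(km))
  env <- list2env(lapply(split(pairs_ref, unlist(km)), unique),
                  hash = TRUE, size = length(unlist(km)))
  structure(list(k = k, env = env,
                 ref_ids = tx$ref_id,
                 ref_feature = tx$feature,
                 feature_names = refset$feature_names,
                 refset = refset),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("feature_index: k=%d, %d references, %d features, %d k-mers\n",
              x$k, length(x$ref_ids), length(x$feature_names),
              length(ls(x$env))))
  invisible(x)
}

## per-reference fraction of the read's k-mers found in that reference
kmer_fractions <- function(s, index) {
  km <- seq_kmers(s, index$k)
  if (!length(km)) return(numeric(length(index$ref_ids)))
  hits <- unlist(mget(km, envir = index$env, ifnotfound = list(NULL)))
  if (is.null(hits)) return(numeric(length(index$ref_ids)))
  tabulate(hits, nbins = length(index$ref_ids)) / length(km)
}

#' Classify a read against the k-mer index
#'
#' For each reference the fraction of the read's k-mers present in that
#' reference is computed on both strands; references reaching
#' `min_kmer_frac` on their better strand are hits, which are collapsed to
#' feature labels (hits on several references of the same feature count
#' once).
#'
#' @param sequence read sequence (character scalar).
#' @param index a `feature_index`.
#' @param min_kmer_frac hit threshold on the k-mer fraction (default 0.7;
#'   use 1 for exact containment semantics on error-free data).
#' @return character vector of feature names (empty if unassigned).
#' @export
classify_read <- function(sequence, index, min_kmer_frac = 0.7) {
  classify_reads(sequence, index, min_kmer_frac)[[1]]
}

#' Classify many reads at once
#'
#' Vectorized version of [classify_read()].
#'
#' @param sequences character vector of read sequences.
#' @inheritParams classify_read
#' @return list of feature-name character vectors, one per read.
#' @export
classify_reads <- function(sequences, index, min_kmer_frac = 0.7) {
  stopifnot(inherits(index, "feature_index"))
  if (!length(sequences)) return(list())
  rc <- revcomp(sequences)
  feats <- factor(index$ref_feature, levels = index$feature_names)
  lapply(seq_along(sequences), function(i) {
    fr <- pmax(kmer_fractions(sequences[i], index),
               kmer_fractions(rc[i], index))
    hit <- fr >= min_kmer_frac
    if (!any(hit)) character(0)
    else as.character(sort(unique(feats[hit])))
  })
}

## ---- genomic oracle -------------------------------------------------------

#' Classify reads from genomic alignment geometry (oracle)
#'
#' Independent of the reference set: aligned blocks (`M`/`=`/`X` runs) and
#' `N` gaps are computed in genomic coordinates from the CIGAR. A feature
#' exon is reported when the aligned blocks overlap it by at least `k`
#' bases in total; a junction feature is reported when an `N` gap joins a
#' block ending at the left exon's 3' genomic boundary to a block starting
#' at the right exon's 5' boundary, with at least `k` aligned bases on each
#' side of the gap.
#'
#' @param records records data.frame (mapped reads with valid CIGARs).
#' @param model the `gene_model` (coordinates only; sequences not needed).
#' @param rules the `build_rules` declaring the features.
#' @param k minimum overlap in bases (use the reference set's
#'   `min_overlap` to match the containment guarantee).
#' @return list of feature-name character vectors, one per record.
#' @export
classify_reads_genomic <- function(records, model, rules, k = 1L) {
  stopifnot(inherits(model, "gene_model"), inherits(rules, "build_rules"))
  n <- nrow(records)
  if (!n) return(list())
  if (any(is.na(records$cigar)) || any(records$pos < 1L))
    stop("unmapped record passed to the genomic classifier")
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    records$cigar, pos = records$pos, ops = c("M", "=", "X"))
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    records$cigar, pos = records$pos, ops = "N")
  bs_l <- as.list(BiocGenerics::start(blocks))
  be_l <- as.list(BiocGenerics::end(blocks))
  gs_l <- as.list(BiocGenerics::start(gaps))
  ge_l <- as.list(BiocGenerics::end(gaps))
  ## hoist feature geometry out of the per-read loop
  ex <- model$exons
  fts <- rules$features
  plus <- model$strand == "+"
  is_exon <- fts$kind == "exon"
  e_start <- ex$start[match(fts$left, ex$exon_id)]
  e_end <- ex$end[match(fts$left, ex$exon_id)]
  L_start <- e_start; L_end <- e_end
  R_start <- ex$start[match(fts$right, ex$exon_id)]
  R_end <- ex$end[match(fts$right, ex$exon_id)]
  ## splice gap the junction read must bridge exactly
  gap_s <- if (plus) L_end + 1L else R_end + 1L
  gap_e <- if (plus) R_start - 1L else L_start - 1L
  lapply(seq_len(n), function(i) {
    bs <- bs_l[[i]]; be <- be_l[[i]]
    gs <- gs_l[[i]]; ge <- ge_l[[i]]
    out <- character(0)
    for (j in seq_len(nrow(fts))) {
      hit <- if (is_exon[j]) {
        sum(pmax(0L, pmin(be, e_end[j]) - pmax(bs, e_start[j]) + 1L)) >= k
      } else {
        any(gs == gap_s[j] & ge == gap_e[j]) &&
          any(be == gap_s[j] - 1L & be - bs + 1L >= k) &&
          any(bs == gap_e[j] + 1L & be - bs + 1L >= k)
      }
      if (hit) out <- c(out, fts$name[j])
    }
    out
  })
}

#' Assign reads to features
#'
#' Runs the k-mer classifier over a records data.frame and returns one
#' assignment row per read, keeping barcode and UMI for downstream
#' counting. The declared feature universe travels along as an attribute.
#'
#' @param records records data.frame from [extract_locus_reads()].
#' @param index a `feature_index`.
#' @param min_kmer_frac see [classify_read()].
#' @return data.frame `qname`, `barcode`, `umi`, `features`
#'   (`;`-joined, `""` when unassigned), with attribute `feature_names`.
#' @export
assign_reads <- function(records, index, min_kmer_frac = 0.7) {
  fl <- classify_reads(records$seq, index, min_kmer_frac)
  out <- data.frame(qname = records$qname,
                    barcode = records$barcode,
                    umi = records$umi,
                    features = vapply(fl, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  attr(out, "feature_names") <- index$feature_names
  out
}

## ---- counting -------------------------------------------------------------

#' Aggregate read assignments into a per-cell count matrix
#'
#' Reads are grouped by `(barcode, umi)`; a group's feature set is the
#' union of its reads' feature sets; each group with a non-empty set
#' contributes total weight 1, split equally over its features (1/|F|
#' each). Groups with empty sets contribute nothing.
#'
#' Column modes: with `whitelist`, columns are exactly the whitelisted
#' barcodes (all-zero columns included); with `forced_cells = N`, columns
#' are the top-N barcodes by total assigned weight (ties broken
#' alphabetically, columns sorted alphabetically); with neither, all
#' barcodes observed with any assigned weight, sorted.
#'
#' @param assignments data.frame from [assign_reads()] (or of the same
#'   shape).
#' @param whitelist optional character vector of barcodes.
#' @param forced_cells optional integer, number of cells to keep.
#' @return a [Matrix::sparseMatrix] (features x barcodes, dgCMatrix) of
#'   possibly fractional counts.
#' @export
quantify <- function(assignments, whitelist = NULL, forced_cells = NULL) {
  if (!is.null(whitelist) && !is.null(forced_cells))
    stop("use either whitelist or forced_cells, not both")
  if (!is.null(whitelist) && !length(whitelist))
    stop("empty whitelist")
  features <- attr(assignments, "feature_names") %||%
    sort(unique(unlist(strsplit(assignments$features[
      nzchar(assignments$features)], ";", fixed = TRUE))))
  a <- assignments[nzchar(assignments$features), , drop = FALSE]
  if (nrow(a)) {
    key <- paste(a$barcode, a$umi, sep = "\r")
    fl <- strsplit(a$features, ";", fixed = TRUE)
    ## one row per (molecule, feature), deduplicated across the reads of a
    ## molecule before weights are computed
    pf <- unique(data.frame(key = rep.int(key, lengths(fl)),
                            barcode = rep.int(a$barcode, lengths(fl)),
                            feature = unlist(fl),
                            stringsAsFactors = FALSE))
    nf <- table(pf$key)
    pf$w <- 1 / as.numeric(nf[pf$key])
    agg <- stats::aggregate(w ~ feature + barcode, data = pf, FUN = sum)
  } else {
    agg <- data.frame(feature = character(0), barcode = character(0),
                      w = numeric(0))
  }
  if (!is.null(whitelist)) {
    barcodes <- unique(whitelist)
    agg <- agg[agg$barcode %in% barcodes, , drop = FALSE]
  } else if (!is.null(forced_cells)) {
    tot <- tapply(agg$w, agg$barcode, sum)
    keep <- names(tot)[order(-tot, names(tot))]
    barcodes <- sort(utils::head(keep, forced_cells))
    agg <- agg[agg$barcode %in% barcodes, , drop = FALSE]
  } else {
    barcodes <- sort(unique(agg$barcode))
  }
  Matrix::sparseMatrix(
    i = match(agg$feature, features),
    j = match(agg$barcode, barcodes),
    x = agg$w,
    dims = c(length(features), length(barcodes)),
    dimnames = list(features, barcodes))
}

#' Add two count matrices feature-wise over the union of barcodes
#'
#' @param a,b sparse count matrices with identical feature sets (row
#'   names); `b`'s rows are reordered to `a`'s if needed.
#' @return element-wise sum over the union of barcodes (sorted).
#' @export
merge_counts <- function(a, b) {
  if (!setequal(rownames(a), rownames(b)))
    stop("feature sets differ")
  b <- b[rownames(a), , drop = FALSE]
  barcodes <- sort(union(colnames(a), colnames(b)))
  pad <- function(m) {
    out <- Matrix::Matrix(0, nrow(m), length(barcodes), sparse = TRUE,
                          dimnames = list(rownames(m), barcodes))
    if (ncol(m)) out[, colnames(m)] <- m
    out
  }
  methods::as(pad(a) + pad(b), "CsparseMatrix")
}

#' Per-cell log2 normalization
#'
#' `log2(1 + scale * c / T)` where `T` is the cell's total count within the
#' matrix; all-zero cells map to zero.
#'
#' @param m count matrix (features x cells).
#' @param scale library-size scale factor (default 1e4).
#' @return a dense base matrix of normalized values.
#' @export
log_normalize <- function(m, scale = 1e4) {
  d <- as.matrix(m)
  tot <- colSums(d)
  tot[tot == 0] <- Inf # zero-total cells stay all-zero
  log2(1 + scale * sweep(d, 2, tot, "/"))
}
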