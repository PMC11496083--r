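#' Read extraction from barcoded alignments
#'
#' Readers around [Rsamtools] that pull primary, mapped, barcoded and
#' UMI-tagged records overlapping the target locus out of a Cell Ranger
#' style BAM (or SAM, converted on the fly), keeping the 10x tag
#' conventions: corrected `CB`/`UB` preferred, raw `CR`/`UR` as fallback.
#' Positions are reported 1-based (leftmost aligned base), the samtools
#' convention.
#'
#' @name bam_reads
NULL

## Accept .sam or .bam; return path to a sorted, indexed BAM.
prepare_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    sorted <- Rsamtools::sortBam(path, tempfile())
    Rsamtools::indexBam(sorted)
    path <- sorted
  }
  path
}

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

is_primary_mapped <- function(flag) {
  bitwAnd(flag, FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY) == 0L
}

#' Extract barcoded reads overlapping a locus
#'
#' Returns every primary, mapped record whose aligned span intersects the
#' region. Records lacking both `CB` and `CR`, or both `UB` and `UR`, are
#' dropped (their count is reported in the `"dropped_untagged"` attribute);
#' secondary and supplementary alignments are dropped; with a whitelist,
#' records whose barcode is not listed are dropped.
#'
#' @param bam_path path to a BAM (indexed, or sortable) or SAM file.
#' @param region 1-based inclusive region string `"chrom:start-end"`, e.g.
#'   from [locus_region()].
#' @param whitelist optional character vector of cell barcodes to keep.
#' @return a data.frame with one row per retained record: `qname`,
#'   `barcode`, `umi`, `seq`, `chrom`, `pos` (1-based leftmost), `cigar`,
#'   `mapq`, `flag`, `nh` (NA when the tag is absent), `len`.
#' @export
extract_locus_reads <- function(bam_path, region, whitelist = NULL) {
  rg <- parse_region(region)
  bam <- prepare_bam(bam_path)
  which <- GenomicRanges::GRanges(rg$chrom,
                                  IRanges::IRanges(rg$start, rg$end))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("CB", "CR", "UB", "UR", "NH"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  tag <- function(t) {
    v <- res$tag[[t]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  df <- data.frame(
    qname = res$qname,
    barcode = ifelse(is.na(tag("CB")), tag("CR"), tag("CB")),
    umi = ifelse(is.na(tag("UB")), tag("UR"), tag("UB")),
    seq = as.character(res$seq),
    chrom = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    mapq = res$mapq,
    flag = res$flag,
    nh = if (is.null(res$tag$NH)) rep(NA_integer_, n) else as.integer(res$tag$NH),
    stringsAsFactors = FALSE)
  df <- df[is_primary_mapped(df$flag), , drop = FALSE]
  untagged <- is.na(df$barcode) | is.na(df$umi) |
    !nzchar(df$barcode) | !nzchar(df$umi)
  dropped <- sum(untagged)
  df <- df[!untagged, , drop = FALSE]
  if (!is.null(whitelist))
    df <- df[df$barcode %in% whitelist, , drop = FALSE]
  df$len <- nchar(df$seq)
  rownames(df) <- NULL
  attr(df, "dropped_untagged") <- dropped
  df
}

#' Infer the cDNA read length from extracted records
#'
#' Modal sequence length; ties broken towards the larger length.
#'
#' @param records a records data.frame from [extract_locus_reads()], or a
#'   numeric vector of lengths.
#' @return the inferred read length.
#' @export
infer_read_length <- function(records) {
  lens <- if (is.data.frame(records)) records$len else records
  if (!length(lens)) stop("cannot infer read length from zero records")
  tab <- table(lens)
  cand <- as.integer(names(tab)[tab == max(tab)])
  max(cand)
}

#' Partition records by read length
#'
#' Exact partition into a short group (`len <= threshold`) and a long group
#' (`len > threshold`), mirroring a samtools `length(seq)<=threshold` /
#' `length(seq)>threshold` filter pair.
#'
#' @param records records data.frame.
#' @param threshold length cutoff in bases (default 100).
#' @return list with elements `short` and `long`.
#' @export
split_by_length <- function(records, threshold = 100L) {
  short <- records$len <= threshold
  list(short = records[short, , drop = FALSE],
       long = records[!short, , drop = FALSE])
}

#' Deterministic qname-level subsampling
#'
#' Each distinct read name is retained independently with probability
#' `fraction`, decided by a hash of `(seed, qname)`, so all records of a
#' qname share fate and, for a fixed seed, the subset at a smaller fraction
#' is nested inside the subset at a larger one.
#'
#' @param records records data.frame.
#' @param fraction retention probability in `[0, 1]`.
#' @param seed integer subsampling seed (default 42).
#' @return the subsampled records data.frame.
#' @export
subsample_reads <- function(records, fraction, seed = 42L) {
  if (fraction < 0 || fraction > 1) stop("fraction out of range [0,1]")
  if (fraction == 1) return(records)
  if (fraction == 0 || nrow(records) == 0L)
    return(records[integer(0), , drop = FALSE])
  qn <- unique(records$qname)
  keep_qn <- qn[qname_hash(qn, seed) < fraction]
  records[records$qname %in% keep_qn, , drop = FALSE]
}

#' Mean uniquely mapped reads per cell
#'
#' The depth covariate of the saturation analysis: the number of primary,
#' mapped, non-supplementary records mapping to the genome exactly once
#' (`NH == 1`; when no record carries `NH`, `mapq == 255` is used as the
#' unique-mapper criterion) whose barcode is on the whitelist, divided by
#' the number of whitelisted cells. Cells without any read still count in
#' the denominator.
#'
#' @param x a records data.frame, or a BAM/SAM path (the whole file is then
#'   scanned, not just one locus).
#' @param whitelist character vector of cell barcodes (non-empty).
#' @return average reads per cell (numeric scalar).
#' @export
reads_per_cell <- function(x, whitelist) {
  if (!length(whitelist)) stop("empty whitelist")
  whitelist <- unique(whitelist)
  if (is.character(x) && length(x) == 1L) {
    bam <- prepare_bam(x)
    param <- Rsamtools::ScanBamParam(what = c("flag", "mapq"),
                                     tag = c("CB", "CR", "NH"))
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    n <- length(res$flag)
    cb <- res$tag$CB; cr <- res$tag$CR
    if (is.null(cb)) cb <- rep(NA_character_, n)
    if (is.null(cr)) cr <- rep(NA_character_, n)
    x <- data.frame(flag = res$flag, mapq = res$mapq,
                    barcode = ifelse(is.na(cb), cr, cb),
                    nh = if (is.null(res$tag$NH)) rep(NA_integer_, n)
                         else as.integer(res$tag$NH),
                    stringsAsFactors = FALSE)
  }
  ok <- is_primary_mapped(x$flag)
  unique_map <- if (all(is.na(x$nh))) x$mapq == 255L else
    !is.na(x$nh) & x$nh == 1L
  num <- sum(ok & unique_map & !is.na(x$barcode) &
               x$barcode %in% whitelist)
  num / length(whitelist)
}

#' Export extracted reads as FASTQ
#'
#' The read id line carries the barcode and UMI
#' (`@qname CB:<barcode> UB:<umi>`), emulating a bamtofastq step. Qualities
#' are not tracked by the extractor, so a constant high quality is written.
#'
#' @param records records data.frame.
#' @param path output FASTQ path (plain text).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records)) {
    quals <- vapply(records$len, function(l) strrep("F", l), character(1))
    writeLines(as.vector(rbind(
      sprintf("@%s CB:%s UB:%s", records$qname, records$barcode, records$umi),
      records$seq, "+", quals)), con)
  }
  invisible(path)
}
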