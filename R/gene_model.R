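#' Gene models: ordered, sequence-attached exon lists
#'
#' A gene model is the union exon set of one locus, ordered 5'->3' in
#' transcript orientation, optionally carrying exon sequences (already
#' reverse-complemented for minus-strand genes so they read 5'->3' in the
#' transcript). All genomic coordinates are 1-based inclusive, the GTF and
#' samtools convention used throughout the package.
#'
#' @name gene_model
NULL

new_gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.data.frame(exons),
            all(c("exon_id", "start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) stop("no exons")
  if (any(exons$start > exons$end)) stop("exon with start > end")
  ## non-overlap check on genomic coordinates
  o <- order(exons$start)
  if (nrow(exons) > 1L &&
      any(exons$start[o][-1L] <= exons$end[o][-nrow(exons)]))
    stop("overlapping exons in gene model")
  ## transcript orientation: + strand ascending, - strand descending starts
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  if (is.null(exons$sequence)) exons$sequence <- NA_character_
  structure(list(
    gene_id     = gene_id,
    chrom       = chrom,
    strand      = strand,
    exons       = exons,
    locus_start = min(exons$start),
    locus_end   = max(exons$end)
  ), class = "gene_model")
}

#' Parse the union exon model of one gene from a GTF file
#'
#' Exon features of `gene_id` are collected across all its transcripts,
#' deduplicated by exact genomic `(start, end)`, and ordered 5'->3' in
#' transcript orientation (ascending genomic start on `+`, descending on
#' `-`). Exons are labelled `E1..En` in that order; overlapping-but-unequal
#' exon variants are kept as separate entries.
#'
#' @param gtf_path path to a GTF file (Ensembl-style attributes; gzip
#'   allowed).
#' @param gene_id gene identifier to extract (matched against the
#'   `gene_id` attribute).
#' @return a `gene_model` object without sequences; attach them with
#'   [attach_sequences()].
#' @examples
#' toy <- make_toy_model(n_exons = 8, seed = 1)
#' gtf <- tempfile(fileext = ".gtf")
#' write_gene_gtf(toy$model, gtf)
#' m <- parse_gtf_exons(gtf, "toygene")
#' m$exons$exon_id
#' @export
parse_gtf_exons <- function(gtf_path, gene_id) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF has no gene_id attribute")
  gr <- gr[!is.na(gr$gene_id) & gr$gene_id == gene_id]
  if (length(gr) == 0L) stop("gene not found: ", gene_id)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) stop("no exons for gene: ", gene_id)
  strands <- unique(as.character(BiocGenerics::strand(gr)))
  if (length(strands) != 1L || !strands %in% c("+", "-"))
    stop("inconsistent strand for gene: ", gene_id)
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(chroms) != 1L) stop("gene spans multiple chromosomes")
  df <- unique(data.frame(start = BiocGenerics::start(gr),
                          end   = BiocGenerics::end(gr)))
  ord <- if (strands == "+") order(df$start) else order(-df$start)
  df <- df[ord, , drop = FALSE]
  df$exon_id <- paste0("E", seq_len(nrow(df)))
  new_gene_model(gene_id, chroms, strands,
                 df[, c("exon_id", "start", "end")])
}

#' Attach genomic sequences to a gene model
#'
#' Extracts each exon's sequence from the genome; minus-strand exons are
#' reverse-complemented so every stored sequence reads 5'->3' in transcript
#' orientation.
#'
#' @param model a `gene_model`.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return the model with `exons$sequence` filled in.
#' @export
attach_sequences <- function(model, genome) {
  stopifnot(inherits(model, "gene_model"))
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome)) # FASTA ids up to first whitespace
  names(genome) <- nm
  if (!model$chrom %in% nm)
    stop("chromosome not in genome: ", model$chrom)
  chr <- genome[[model$chrom]]
  if (model$locus_end > length(chr) || model$locus_start < 1L)
    stop("exon span outside chromosome bounds")
  seqs <- as.character(Biostrings::DNAStringSet(
    chr, start = model$exons$start, end = model$exons$end))
  if (model$strand == "-") seqs <- revcomp(seqs)
  model$exons$sequence <- toupper(seqs)
  model
}

#' Locus region string for read extraction
#'
#' @param model a `gene_model`.
#' @param pad bases of padding added on both sides; the start clamps at 1.
#' @return a 1-based inclusive region string `"chrom:start-end"` suitable
#'   for [extract_locus_reads()].
#' @export
locus_region <- function(model, pad = 0) {
  stopifnot(inherits(model, "gene_model"), pad >= 0)
  if (nrow(model$exons) == 0L) stop("empty gene model")
  sprintf("%s:%d-%d", model$chrom,
          max(1L, model$locus_start - as.integer(pad)),
          model$locus_end + as.integer(pad))
}

#' Write a gene model back to GTF
#'
#' Emits one transcript carrying the union exon set, with Ensembl-style
#' `gene_id`/`transcript_id`/`exon_id` attributes. Mainly used to create toy
#' annotation files and for round-trip testing.
#'
#' @param model a `gene_model`.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  lines <- sprintf(
    '%s\tcd45iso\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_id "%s";',
    model$chrom, ex$start, ex$end, model$strand,
    model$gene_id, paste0(model$gene_id, ".t1"), ex$exon_id)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s strand) %s:%d-%d, %d exons\n",
              x$gene_id, x$strand, x$chrom, x$locus_start, x$locus_end,
              nrow(x$exons)))
  has_seq <- !all(is.na(x$exons$sequence))
  cat(if (has_seq) "  sequences attached\n" else "  no sequences attached\n")
  invisible(x)
}

## exon lengths in transcript order (helper used by the reference builder)
exon_lengths <- function(model) {
  stats::setNames(model$exons$end - model$exons$start + 1L,
                  model$exons$exon_id)
}

## exon sequence lookup, errors on missing sequences
exon_seq <- function(model, ids) {
  s <- model$exons$sequence[match(ids, model$exons$exon_id)]
  if (anyNA(s)) stop("gene model has no sequences; call attach_sequences()")
  s
}
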