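#' 10x-compatible MatrixMarket persistence
#'
#' Count matrices are stored in the Cell Ranger v3 directory layout:
#' `matrix.mtx`, `features.tsv` (feature id, feature name, literal
#' `"Gene Expression"`), `barcodes.tsv`, each optionally gzipped. MTX
#' indices are 1-based, values real (weights may be fractional), triplets
#' ordered column-major, so reruns produce byte-identical files.
#'
#' @name matrix_io
NULL

#' Write a count matrix as a 10x-style MTX bundle
#'
#' @param m sparse count matrix (features x barcodes) with dimnames.
#' @param out_dir output directory, created if needed.
#' @param gzip write `*.gz` files (default TRUE, the Cell Ranger v3
#'   convention); plain text is convenient for tests and inspection.
#' @return invisibly, the paths of the three files written.
#' @export
write_mtx <- function(m, out_dir, gzip = TRUE) {
  if (is.null(rownames(m)) || (ncol(m) > 0L && is.null(colnames(m))))
    stop("matrix must carry feature and barcode names")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  open_out <- function(name) {
    p <- file.path(out_dir, paste0(name, ext))
    list(path = p, con = if (gzip) gzfile(p, "wb") else file(p, "w"))
  }
  t <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  ord <- order(t@j, t@i) # column-major
  mtx <- open_out("matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "%",
               sprintf("%d %d %d", nrow(m), ncol(m), length(t@x)),
               sprintf("%d %d %.12g",
                       t@i[ord] + 1L, t@j[ord] + 1L, t@x[ord])),
             mtx$con)
  close(mtx$con)
  ft <- open_out("features.tsv")
  writeLines(sprintf("%s\t%s\tGene Expression", rownames(m), rownames(m)),
             ft$con)
  close(ft$con)
  bc <- open_out("barcodes.tsv")
  writeLines(colnames(m) %||% character(0), bc$con)
  close(bc$con)
  invisible(list(matrix = mtx$path, features = ft$path, barcodes = bc$path))
}

find_bundle_file <- function(dir, name) {
  for (p in file.path(dir, c(paste0(name, ".gz"), name)))
    if (file.exists(p)) return(p)
  stop("missing file in matrix bundle: ", name)
}

#' Read a 10x-style MTX bundle
#'
#' Exact inverse of [write_mtx()] (within float formatting); both gzipped
#' and plain bundles are accepted.
#'
#' @param dir bundle directory.
#' @return a dgCMatrix with feature row names and barcode column names.
#' @export
read_mtx <- function(dir) {
  mtx_path <- find_bundle_file(dir, "matrix.mtx")
  ft_path <- find_bundle_file(dir, "features.tsv")
  bc_path <- find_bundle_file(dir, "barcodes.tsv")
  read_with <- function(p, fun) {
    con <- if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
    on.exit(close(con))
    fun(con)
  }
  m <- tryCatch(read_with(mtx_path, Matrix::readMM), error = function(e)
    stop("malformed matrix.mtx: ", conditionMessage(e)))
  ft_lines <- read_with(ft_path, function(con) readLines(con, warn = FALSE))
  feats <- vapply(strsplit(ft_lines, "\t", fixed = TRUE), `[`, "", 1L)
  bcs <- read_with(bc_path, function(con) readLines(con, warn = FALSE))
  bcs <- bcs[nzchar(bcs)]
  if (nrow(m) != length(feats) || ncol(m) != length(bcs))
    stop("dimension mismatch between matrix and features/barcodes")
  if (anyDuplicated(bcs)) stop("duplicate barcode in bundle")
  dimnames(m) <- list(feats, bcs)
  methods::as(m, "CsparseMatrix")
}

#' Flat wide CSV export of a count matrix
#'
#' One row per feature, one column per barcode; intended for quick
#' inspection, not as an interchange format.
#'
#' @param m count matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(m, path) {
  d <- as.data.frame(as.matrix(m))
  d <- cbind(feature = rownames(m), d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
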