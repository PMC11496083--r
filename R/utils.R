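## small internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

## reverse complement for plain character vectors (ACGTN alphabet)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Deterministic per-name subsampling hash
#'
#' 32-bit FNV-1a over `paste(seed, name)` mapped to `[0, 1)`. Used to decide,
#' independently per read name, whether a read survives subsampling, so that
#' all records sharing a qname share their fate and subsets are nested across
#' fractions at a fixed seed (the contract of samtools-style `--subsample`).
#'
#' @param names character vector of read names.
#' @param seed integer subsampling seed.
#' @return numeric vector in `[0, 1)`, one value per name.
#' @keywords internal
#' @noRd
qname_hash <- function(names, seed) {
  prime <- 16777619
  vapply(paste0(seed, ":", names), function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- bitwXor32(h, b)
      h <- mul32(h, prime)
    }
    ## murmur3-style finalizer: FNV alone leaves neighbouring inputs with
    ## neighbouring hashes, which would correlate subsampling decisions of
    ## consecutively named reads
    h <- xor32(h, h %/% 65536)
    h <- mul32(h, 2246822507)
    h <- xor32(h, h %/% 8192)
    h <- mul32(h, 3266489909)
    h <- xor32(h, h %/% 65536)
    h / 4294967296
  }, numeric(1), USE.NAMES = FALSE)
}

## 32-bit modular multiply on doubles, split so intermediates stay exact
mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

## full 32-bit xor on doubles via 16-bit halves
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

## xor of a 32-bit value (stored in a double) with one byte: only the low
## 8 bits are touched, so the xor can run in integer space
bitwXor32 <- function(h, b) {
  lo8 <- h %% 256
  (h - lo8) + bitwXor(as.integer(lo8), as.integer(b))
}

## parse "chrom:start-end" (1-based inclusive)
parse_region <- function(region) {
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region string: ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

## read a one-barcode-per-line whitelist file
#' Read a cell-barcode whitelist
#'
#' One barcode per line; blank lines and `#` comments are ignored.
#'
#' @param path path to a text file.
#' @return character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) x <- unique(x)
  x
}
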