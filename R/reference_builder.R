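#' Discriminating reference construction
#'
#' The core of the method: for every feature of interest (an alternative
#' exon, or an exon-exon junction), build reference sequences consisting of
#' the feature plus flanking sequence on either side, where each flank is
#' assembled from exon chains allowed by the transcript-building rules and
#' truncated to `read_len - min_overlap` bases. Because every flank is
#' shorter than a read, any read fully contained in such a sequence must
#' overlap the feature by at least `min_overlap` bases -- so a reference hit
#' is evidence for the feature itself, never for flank sequence alone.
#'
#' @name reference_builder
NULL

## ---- transcript-building rules -------------------------------------------

new_build_rules <- function(features, follows, model) {
  idx <- function(id) match(id, model$exons$exon_id)
  ids <- model$exons$exon_id
  bad <- setdiff(c(features$left, features$right[!is.na(features$right)],
                   names(follows), unlist(follows)), ids)
  if (length(bad))
    stop("unknown exon id in rules: ", paste(bad, collapse = ", "))
  if (anyDuplicated(features$name)) stop("duplicate feature name")
  jx <- features$kind == "junction"
  if (any(jx & (idx(features$left) >= idx(features$right))[jx]))
    stop("junction exons not in transcript order")
  for (from in names(follows))
    if (any(idx(follows[[from]]) <= idx(from)))
      stop("follows edge violates transcript order at ", from)
  structure(list(features = features, follows = follows),
            class = "build_rules")
}

#' Parse a transcript-building-rules file
#'
#' Line-oriented grammar (`#` starts a comment):
#' \preformatted{
#' feature <NAME> exon <EXON_ID>
#' feature <NAME> junction <LEFT_ID> <RIGHT_ID>
#' follows <EXON_ID>: <ID>[,<ID>...]
#' }
#' `follows` lists the exons that may immediately follow an exon in a
#' transcript; every edge must point strictly downstream in transcript
#' order, which also guarantees acyclicity.
#'
#' @param path path to the rules file.
#' @param model the `gene_model` whose exon ids the rules refer to.
#' @return a validated `build_rules` object.
#' @export
parse_rules <- function(path, model) {
  stopifnot(inherits(model, "gene_model"))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  feats <- list()
  follows <- list()
  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (toks[1] == "feature") {
      if (length(toks) == 4L && toks[3] == "exon") {
        feats[[length(feats) + 1L]] <-
          data.frame(name = toks[2], kind = "exon",
                     left = toks[4], right = NA_character_)
      } else if (length(toks) == 5L && toks[3] == "junction") {
        feats[[length(feats) + 1L]] <-
          data.frame(name = toks[2], kind = "junction",
                     left = toks[4], right = toks[5])
      } else stop("malformed feature line: ", ln)
    } else if (toks[1] == "follows") {
      m <- regmatches(ln, regexec(
        "^follows[[:space:]]+([^:[:space:]]+)[[:space:]]*:[[:space:]]*(.+)$", ln))[[1]]
      if (length(m) != 3L) stop("malformed follows line: ", ln)
      succ <- trimws(strsplit(m[3], ",")[[1]])
      follows[[m[2]]] <- unique(c(follows[[m[2]]], succ))
    } else stop("unrecognized rules line: ", ln)
  }
  if (!length(feats)) stop("rules file declares no features")
  new_build_rules(do.call(rbind, feats), follows, model)
}

#' Default CD45/PTPRC rules
#'
#' Features RA/RB/RC = alternative exons 4/5/6, RO = the exon 3 - exon 7
#' junction; alternative exons may be skipped in any combination
#' (`E3 -> {E4,E5,E6,E7}`, `E4 -> {E5,E6,E7}`, `E5 -> {E6,E7}`,
#' `E6 -> {E7}`) and the constitutive backbone is chained
#' `E1 -> E2 -> E3` and `E7 -> E8 -> ...`. The same topology applies to the
#' human and the mouse gene.
#'
#' @param model a `gene_model` with at least 7 exons labelled in transcript
#'   order.
#' @return a `build_rules` object with features RA, RB, RC, RO.
#' @export
default_ptprc_rules <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  n <- nrow(model$exons)
  if (n < 7L) stop("model too short: need >= 7 exons, have ", n)
  E <- model$exons$exon_id
  features <- data.frame(
    name = c("RA", "RB", "RC", "RO"),
    kind = c("exon", "exon", "exon", "junction"),
    left = c(E[4], E[5], E[6], E[3]),
    right = c(NA, NA, NA, E[7]))
  follows <- list()
  follows[[E[3]]] <- E[4:7]
  follows[[E[4]]] <- E[5:7]
  follows[[E[5]]] <- E[6:7]
  follows[[E[6]]] <- E[7]
  follows[[E[1]]] <- E[2]
  follows[[E[2]]] <- E[3]
  if (n > 7L)
    for (i in 7:(n - 1L)) follows[[E[i]]] <- E[i + 1L]
  new_build_rules(features, follows, model)
}

#' Flank length for a read length and minimum feature overlap
#'
#' Flanks of `read_len - min_overlap` bases guarantee that a read of
#' `read_len` bases fully contained in a flanked reference overlaps the
#' feature by at least `min_overlap` bases. A junction feature needs the
#' overlap on both sides, hence the precondition `read_len >= 2*min_overlap`.
#'
#' @param read_len cDNA (R2) read length in bases.
#' @param min_overlap required feature overlap `k` in bases (default 1, the
#'   weakest guarantee: a fully mapped read touches the feature at all).
#' @return the flank length `read_len - min_overlap`.
#' @export
compute_flank_length <- function(read_len, min_overlap = 1L) {
  read_len <- as.integer(read_len); min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (read_len < 2L * min_overlap)
    stop("read_len must be >= 2*min_overlap (", read_len, " < ",
         2L * min_overlap, ")")
  read_len - min_overlap
}

#' Enumerate flank chains for an anchor exon
#'
#' Walks the `follows` edges (or their reverse, for the upstream side)
#' starting at `anchor_exon`, extending each chain until the accumulated
#' exon sequence length reaches `flank_len` or the gene end is hit. Chains
#' are deduplicated by the flank sequence they produce after truncation
#' (distinct chains whose truncated flanks are identical are
#' indistinguishable to any aligner).
#'
#' @param rules a `build_rules` object.
#' @param model a `gene_model` with sequences.
#' @param anchor_exon exon id the flank attaches to.
#' @param side `"upstream"` or `"downstream"` of the anchor.
#' @param flank_len target flank length in bases.
#' @param include_anchor if `TRUE` the anchor itself starts the chain and
#'   counts towards the length (used for junction features, whose flanks
#'   contain the junction's own exons).
#' @return a list with components `chains` (list of exon-id vectors, each
#'   ordered 5'->3') and `flanks` (the corresponding truncated flank
#'   sequences; for the upstream side the LAST `flank_len` bases of the
#'   concatenated chain, for the downstream side the FIRST `flank_len`).
#' @export
enumerate_flank_chains <- function(rules, model, anchor_exon,
                                   side = c("downstream", "upstream"),
                                   flank_len, include_anchor = FALSE) {
  side <- match.arg(side)
  stopifnot(inherits(rules, "build_rules"), inherits(model, "gene_model"))
  if (!anchor_exon %in% model$exons$exon_id)
    stop("unknown anchor exon: ", anchor_exon)
  lens <- exon_lengths(model)
  adj <- if (side == "downstream") rules$follows else {
    rev_map <- list()
    for (from in names(rules$follows))
      for (to in rules$follows[[from]])
        rev_map[[to]] <- c(rev_map[[to]], from)
    rev_map
  }
  chains <- list()
  walk <- function(chain, len) {
    tip <- if (length(chain)) chain[length(chain)] else anchor_exon
    succ <- adj[[tip]]
    if (len >= flank_len || is.null(succ) || !length(succ)) {
      chains[[length(chains) + 1L]] <<- chain
      return(invisible())
    }
    for (nxt in succ) walk(c(chain, nxt), len + lens[[nxt]])
  }
  if (include_anchor) walk(anchor_exon, lens[[anchor_exon]])
  else walk(character(0), 0L)
  ## chains were built walking away from the anchor; upstream chains must be
  ## reported 5'->3'
  if (side == "upstream") chains <- lapply(chains, rev)
  flanks <- vapply(chains, function(ch) {
    s <- paste(exon_seq(model, ch), collapse = "")
    if (side == "upstream") substr(s, max(1L, nchar(s) - flank_len + 1L), nchar(s))
    else substr(s, 1L, min(nchar(s), flank_len))
  }, character(1))
  keep <- !duplicated(flanks)
  list(chains = chains[keep], flanks = flanks[keep])
}

## ---- reference assembly ---------------------------------------------------

chain_id <- function(ch) if (length(ch)) paste(ch, collapse = "-") else "."

#' Build the discriminating reference set
#'
#' For each feature, every (upstream chain x downstream chain) combination
#' yields one reference sequence: upstream flank (last `flank_len` bases of
#' the concatenated upstream chain), then -- for exon features -- the full
#' feature exon, then the downstream flank (first `flank_len` bases of the
#' concatenated downstream chain). Junction flanks include the junction's
#' own exons and abut directly, leaving a zero-width feature interval at the
#' splice point. Duplicate sequences are removed.
#'
#' @param model a `gene_model` with sequences.
#' @param rules a `build_rules` object.
#' @param read_len cDNA read length (bases).
#' @param min_overlap minimum guaranteed feature overlap `k` (bases).
#' @return a `reference_set`: a list with `transcripts` (data.frame with
#'   `ref_id`, `feature`, `up_chain`, `down_chain`, `sequence`, and the
#'   half-open, 0-based feature interval `fs`/`fe` within the sequence),
#'   plus `read_len`, `min_overlap` and `flank_len`.
#' @examples
#' toy <- make_toy_model(seed = 1)
#' rs <- build_reference(toy$model, default_ptprc_rules(toy$model),
#'                       read_len = 98, min_overlap = 1)
#' rs
#' @export
build_reference <- function(model, rules, read_len, min_overlap = 1L) {
  stopifnot(inherits(model, "gene_model"), inherits(rules, "build_rules"))
  flank_len <- compute_flank_length(read_len, min_overlap)
  rows <- list()
  for (i in seq_len(nrow(rules$features))) {
    ft <- rules$features[i, ]
    if (ft$kind == "exon") {
      ups <- enumerate_flank_chains(rules, model, ft$left, "upstream", flank_len)
      dns <- enumerate_flank_chains(rules, model, ft$left, "downstream", flank_len)
      mid <- exon_seq(model, ft$left)
      for (u in seq_along(ups$chains)) for (d in seq_along(dns$chains)) {
        up <- ups$flanks[u]; dn <- dns$flanks[d]
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = sprintf("%s__%s__%s", ft$name,
                           chain_id(ups$chains[[u]]), chain_id(dns$chains[[d]])),
          feature = ft$name,
          up_chain = chain_id(ups$chains[[u]]),
          down_chain = chain_id(dns$chains[[d]]),
          sequence = paste0(up, mid, dn),
          fs = nchar(up), fe = nchar(up) + nchar(mid))
      }
    } else { # junction: flanks contain the junction's own exons and abut
      ups <- enumerate_flank_chains(rules, model, ft$left, "upstream",
                                    flank_len, include_anchor = TRUE)
      dns <- enumerate_flank_chains(rules, model, ft$right, "downstream",
                                    flank_len, include_anchor = TRUE)
      for (u in seq_along(ups$chains)) for (d in seq_along(dns$chains)) {
        up <- ups$flanks[u]; dn <- dns$flanks[d]
        rows[[length(rows) + 1L]] <- data.frame(
          ref_id = sprintf("%s__%s__%s", ft$name,
                           chain_id(ups$chains[[u]]), chain_id(dns$chains[[d]])),
          feature = ft$name,
          up_chain = chain_id(ups$chains[[u]]),
          down_chain = chain_id(dns$chains[[d]]),
          sequence = paste0(up, dn),
          fs = nchar(up), fe = nchar(up))
      }
    }
  }
  tx <- do.call(rbind, rows)
  ## dedup by full sequence; identical sequences across distinct features
  ## would make the reference uninterpretable
  dup <- duplicated(tx$sequence)
  if (any(dup)) {
    first_feat <- tx$feature[match(tx$sequence, tx$sequence)]
    if (any(first_feat[dup] != tx$feature[dup]))
      stop("identical reference sequence shared by two features")
    tx <- tx[!dup, , drop = FALSE]
  }
  missing <- setdiff(rules$features$name, tx$feature)
  if (length(missing))
    stop("feature with no valid chains: ", paste(missing, collapse = ", "))
  if (any(grepl("[[:space:]]", tx$ref_id))) stop("whitespace in ref_id")
  if (anyDuplicated(tx$ref_id))
    tx$ref_id <- make.unique(tx$ref_id, sep = "_")
  rownames(tx) <- NULL
  structure(list(transcripts = tx,
                 feature_names = rules$features$name,
                 read_len = as.integer(read_len),
                 min_overlap = as.integer(min_overlap),
                 flank_len = flank_len),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d sequences, %d features (R=%d, k=%d, flank=%d)\n",
              nrow(x$transcripts), length(x$feature_names),
              x$read_len, x$min_overlap, x$flank_len))
  print(table(factor(x$transcripts$feature, levels = x$feature_names)))
  invisible(x)
}

#' Write a reference set to FASTA plus a transcript-to-feature map
#'
#' @param refset a `reference_set`.
#' @param fasta_path output FASTA of all reference sequences.
#' @param t2g_path output two-column tab-separated `ref_id -> feature` map.
#' @return invisibly, a list with the two paths.
#' @export
write_reference <- function(refset, fasta_path, t2g_path) {
  stopifnot(inherits(refset, "reference_set"))
  tx <- refset$transcripts
  if (nrow(tx) == 0L) stop("empty reference set")
  seqs <- Biostrings::DNAStringSet(stats::setNames(tx$sequence, tx$ref_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(tx[, c("ref_id", "feature")], t2g_path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, t2g = t2g_path))
}
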