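#' End-to-end pipeline entry points
#'
#' The `cmd_*` functions wire the modules into the complete workflow
#' (reference construction, read extraction, classification, counting,
#' MTX export, saturation analysis, fixture simulation) and are what the
#' command-line front-end in `inst/scripts/cd45iso.R` calls. Each takes a
#' plain named list of options so a config can be assembled from flags or
#' from a key-value file.
#'
#' @name cli
NULL

pipe_log <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

## shared plumbing: model + rules from config
load_model_rules <- function(config) {
  model <- parse_gtf_exons(config$gtf, config$gene_id)
  model <- attach_sequences(model, config$genome)
  rules <- if (is.null(config$rules)) default_ptprc_rules(model)
           else if (inherits(config$rules, "build_rules")) config$rules
           else parse_rules(config$rules, model)
  list(model = model, rules = rules)
}

#' Build and write the discriminating reference
#'
#' @param config named list with `gtf`, `genome`, `gene_id`, optional
#'   `rules` (path or `build_rules`), `read_len` (omit to infer from `bam`),
#'   `bam` (needed only for read-length inference), `min_overlap`
#'   (default 1), `pad` (locus padding, default 0), `out_dir`, `verbose`.
#' @return the `reference_set`, invisibly; writes `reference.fa` and
#'   `t2g.tsv` into `out_dir` when given.
#' @export
cmd_build_ref <- function(config) {
  mr <- load_model_rules(config)
  read_len <- config$read_len
  if (is.null(read_len)) {
    if (is.null(config$bam))
      stop("read_len not given and no bam to infer it from")
    recs <- extract_locus_reads(config$bam,
                                locus_region(mr$model, config$pad %||% 0))
    read_len <- infer_read_length(recs)
    pipe_log(config$verbose %||% TRUE,
             "inferred read length %d from %d reads", read_len, nrow(recs))
  }
  refset <- build_reference(mr$model, mr$rules, read_len,
                            config$min_overlap %||% 1L)
  tab <- table(refset$transcripts$feature)
  pipe_log(config$verbose %||% TRUE, "reference: %s",
           paste(names(tab), tab, sep = "=", collapse = ", "))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(refset,
                    file.path(config$out_dir, "reference.fa"),
                    file.path(config$out_dir, "t2g.tsv"))
  }
  invisible(refset)
}

#' Run the full quantification
#'
#' Extract locus reads, split them at the length threshold, quantify each
#' group against a reference built for that group's read length, add the
#' two groups' matrices, and (optionally) write a 10x-style MTX bundle.
#' Exactly one of whitelist / forced-cells modes is active: `whitelist`
#' fixes the columns, otherwise `forced_cells` (default 3000) keeps the
#' top-N barcodes by assigned weight.
#'
#' @param config named list; in addition to the [cmd_build_ref()] fields:
#'   `bam` (required), `whitelist` (path or character vector),
#'   `forced_cells` (default 3000 when no whitelist), `kmer` (default 21),
#'   `min_kmer_frac` (default 0.7), `split_threshold` (default 100),
#'   `out_dir`, `gzip` (default TRUE).
#' @return list with `counts` (sparse matrix), `stats` (per-stage read
#'   counts) and, when `out_dir` is set, the bundle paths.
#' @export
cmd_run <- function(config) {
  mr <- load_model_rules(config)
  verbose <- config$verbose %||% TRUE
  whitelist <- config$whitelist
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist))
    whitelist <- read_whitelist(whitelist)
  forced <- if (is.null(whitelist)) config$forced_cells %||% 3000L else NULL
  region <- locus_region(mr$model, config$pad %||% 0)
  recs <- extract_locus_reads(config$bam, region, whitelist)
  pipe_log(verbose, "extracted %d reads from %s (%d untagged dropped)",
           nrow(recs), region, attr(recs, "dropped_untagged"))
  groups <- split_by_length(recs, config$split_threshold %||% 100L)
  groups <- Filter(nrow, groups)
  feature_names <- mr$rules$features$name
  mats <- list()
  assigned <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    R <- config$read_len %||% infer_read_length(g)
    refset <- build_reference(mr$model, mr$rules, R,
                              config$min_overlap %||% 1L)
    index <- build_index(refset, config$kmer %||% 21L)
    asg <- assign_reads(g, index, config$min_kmer_frac %||% 0.7)
    assigned <- assigned + sum(nzchar(asg$features))
    ## quantify over observed barcodes; cell selection happens after merging
    mats[[gname]] <- quantify(asg)
    pipe_log(verbose, "group '%s': %d reads (R=%d), %d assigned",
             gname, nrow(g), R, sum(nzchar(asg$features)))
  }
  counts <- if (!length(mats)) {
    cols <- if (!is.null(whitelist)) unique(whitelist) else character(0)
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(feature_names), length(cols)),
                         dimnames = list(feature_names, cols))
  } else Reduce(merge_counts, mats)
  if (!length(mats))
    warning("no reads in locus; returning an all-zero matrix")
  ## final column selection
  if (!is.null(whitelist)) {
    cols <- unique(whitelist)
    full <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nrow(counts), length(cols)),
      dimnames = list(rownames(counts), cols))
    shared <- intersect(colnames(counts), cols)
    full[, shared] <- counts[, shared, drop = FALSE]
    counts <- methods::as(full, "CsparseMatrix")
  } else if (ncol(counts) > forced) {
    tot <- Matrix::colSums(counts)
    keep <- colnames(counts)[order(-tot, colnames(counts))][seq_len(forced)]
    counts <- counts[, sort(keep), drop = FALSE]
  }
  stats <- list(reads_seen = nrow(recs), reads_assigned = assigned,
                cells = ncol(counts),
                cells_with_signal = sum(Matrix::colSums(counts) > 0))
  pipe_log(verbose, "%d/%d reads assigned; %d/%d cells with any isoform",
           stats$reads_assigned, stats$reads_seen,
           stats$cells_with_signal, stats$cells)
  out <- list(counts = counts, stats = stats)
  if (!is.null(config$out_dir))
    out$bundle <- write_mtx(counts, config$out_dir,
                            gzip = config$gzip %||% TRUE)
  out
}

#' Saturation analysis over a subsampling grid
#'
#' Runs [saturation_curve()] for each requested feature on the extracted
#' locus reads and fits the rational model, writing a CSV of points and a
#' CSV of fits when `out_dir` is set.
#'
#' @param config as for [cmd_run()]; a whitelist is required (the cell set
#'   must be fixed for depth to be comparable across fractions). Extra
#'   fields: `features` (default all declared), `estimator`, `seed`
#'   (default 42), `scale`.
#' @param fractions subsampling grid (default [default_fraction_grid()]).
#' @return list per feature: `points` data.frame and `fit`
#'   (a `rational_fit`).
#' @export
cmd_saturation <- function(config, fractions = default_fraction_grid()) {
  mr <- load_model_rules(config)
  whitelist <- config$whitelist
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist))
    whitelist <- read_whitelist(whitelist)
  if (is.null(whitelist)) stop("saturation analysis requires a whitelist")
  recs <- extract_locus_reads(config$bam,
                              locus_region(mr$model, config$pad %||% 0),
                              whitelist)
  R <- config$read_len %||% infer_read_length(recs)
  refset <- build_reference(mr$model, mr$rules, R, config$min_overlap %||% 1L)
  index <- build_index(refset, config$kmer %||% 21L)
  features <- config$features %||% mr$rules$features$name
  estimator <- config$estimator %||% "fraction_positive"
  out <- lapply(stats::setNames(features, features), function(ft) {
    pts <- saturation_curve(recs, index, whitelist, ft,
                            fractions = fractions,
                            seed = config$seed %||% 42L,
                            estimator = estimator,
                            min_kmer_frac = config$min_kmer_frac %||% 0.7,
                            scale = config$scale %||% 1e4)
    fit <- tryCatch(fit_rational(pts), error = function(e) NULL)
    list(points = pts, fit = fit)
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pts <- do.call(rbind, lapply(names(out), function(ft)
      cbind(feature = ft, out[[ft]]$points)))
    utils::write.csv(pts, file.path(config$out_dir, "saturation_points.csv"),
                     row.names = FALSE)
    fits <- do.call(rbind, lapply(names(out), function(ft) {
      f <- out[[ft]]$fit
      data.frame(feature = ft,
                 a = f$a %||% NA, b = f$b %||% NA,
                 rss = f$rss %||% NA,
                 converged = f$converged %||% FALSE)
    }))
    utils::write.csv(fits, file.path(config$out_dir, "saturation_fit.csv"),
                     row.names = FALSE)
  }
  out
}

#' Generate fixture files (toy genome, GTF, SAM, truth)
#'
#' @param config named list: `out_dir` (required), `seed` (default 1),
#'   `n_cells` (default 20), `n_exons`, `read_len`, `error_rate`,
#'   `reads_per_molecule`, `informative_only`, `min_feature_overlap`,
#'   `umis_per_isoform` (default 1-6 molecules drawn per isoform and cell).
#' @return list with the generated paths and the simulation object.
#' @export
cmd_simulate <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  toy <- make_toy_model(n_exons = config$n_exons %||% 9L, seed = seed)
  profiles <- with_seed(seed + 1L, {
    n_cells <- config$n_cells %||% 20L
    bcs <- rand_tag(n_cells, 16L)
    while (anyDuplicated(bcs)) bcs <- unique(c(bcs, rand_tag(1L, 16L)))
    stats::setNames(lapply(seq_len(n_cells), function(i) {
      labs <- sample(valid_isoform_labels(),
                     sample(2:4, 1L))
      stats::setNames(sample(config$umis_per_isoform %||% 1:6,
                             length(labs), replace = TRUE), labs)
    }), bcs)
  })
  sim <- simulate_reads(toy$model, profiles,
                        read_len = config$read_len %||% 98L,
                        error_rate = config$error_rate %||% 0,
                        seed = seed,
                        reads_per_molecule = config$reads_per_molecule %||% 1L,
                        informative_only = config$informative_only %||% FALSE,
                        min_feature_overlap = config$min_feature_overlap %||% 1L)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    sam = file.path(out_dir, "reads.sam"),
    truth = file.path(out_dir, "truth.json"),
    whitelist = file.path(out_dir, "whitelist.txt"))
  Biostrings::writeXStringSet(toy$genome, paths$genome)
  write_gene_gtf(toy$model, paths$gtf)
  write_sam(sim$sam, paths$sam)
  writeLines(names(profiles), paths$whitelist)
  jsonlite::write_json(
    list(molecules = sim$truth$molecules,
         expected_counts = as.data.frame(sim$truth$expected_counts)),
    paths$truth, digits = NA)
  c(paths, list(model = toy$model, sim = sim))
}
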