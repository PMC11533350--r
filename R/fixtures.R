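## Seeded synthetic fixtures: bins, assembly, quality table, annotation
## files and a ground-truth manifest, in exactly the formats the readers
## consume. Sequence content is random A/C/G/T — fixtures exercise the
## formats and the classification rules, not biology. Completeness and
## contamination are injected via the quality table (the tool's scope
## starts downstream of the marker-gene estimator).

#' Specify a synthetic fixture
#'
#' One row per bin: the target quality category plus the
#' completeness/contamination, tRNA amino-acid coverage and rRNA flags that
#' should produce it, and the contig layout. The spec is validated at
#' construction: the requested scores and census must classify to the
#' target category under default thresholds.
#'
#' @param bins data frame with columns `bin_id`, `target_category`,
#'   `completeness`, `contamination`, `trna_aa_count` (0-20), `rrna_5s`,
#'   `rrna_16s`, `rrna_23s` (logical), `n_contigs`, `min_contig_bp`,
#'   `max_contig_bp`. Missing layout columns default to 3 contigs of
#'   500-2000 bp.
#' @param seed integer seed; all fixture randomness derives from it.
#' @param unbinned_fraction fraction of extra assembly contigs not assigned
#'   to any bin, relative to the binned contig count; default 0.25.
#' @param annotation_format `"tsv"`, `"gff3"` or `"both"`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(bins, seed, unbinned_fraction = 0.25,
                         annotation_format = c("tsv", "gff3", "both")) {
  annotation_format <- match.arg(annotation_format)
  stopifnot(is.data.frame(bins), nrow(bins) >= 1L)
  defaults <- list(n_contigs = 3L, min_contig_bp = 500L, max_contig_bp = 2000L)
  for (nm in names(defaults))
    if (is.null(bins[[nm]])) bins[[nm]] <- defaults[[nm]]
  needed <- c("bin_id", "target_category", "completeness", "contamination",
              "trna_aa_count", "rrna_5s", "rrna_16s", "rrna_23s")
  missing <- setdiff(needed, names(bins))
  if (length(missing))
    magqc_stop("fixture_spec: bins is missing column(s) ",
               paste(missing, collapse = ", "))
  if (anyDuplicated(bins$bin_id))
    magqc_stop("fixture_spec: duplicate bin ids")
  for (i in seq_len(nrow(bins))) {
    b <- bins[i, ]
    if (!b$target_category %in% MAGQC_CATEGORIES)
      magqc_stop("bin '", b$bin_id, "': unknown category '",
                 b$target_category, "'")
    if (b$trna_aa_count < 0 || b$trna_aa_count > 20)
      magqc_stop("bin '", b$bin_id, "': trna_aa_count must be in [0, 20]")
    got <- classify_bin(
      quality_estimate(b$bin_id, b$completeness, b$contamination),
      census_from_counts(b$trna_aa_count, b$rrna_5s, b$rrna_16s, b$rrna_23s))
    if (got$category != b$target_category)
      magqc_stop("bin '", b$bin_id, "': requested scores classify as '",
                 got$category, "', not the target '", b$target_category, "'")
  }
  structure(list(bins = bins, seed = as.integer(seed),
                 unbinned_fraction = unbinned_fraction,
                 annotation_format = annotation_format),
            class = "fixture_spec")
}

## Build an rna_census directly from requested counts/flags (first k amino
## acids); used to validate fixture specs against the classifier.
census_from_counts <- function(trna_aa_count, rrna_5s, rrna_16s, rrna_23s) {
  structure(list(trna_amino_acids = MAGQC_AMINO_ACIDS[seq_len(trna_aa_count)],
                 trna_count = as.integer(trna_aa_count),
                 rrna_5s = isTRUE(rrna_5s), rrna_16s = isTRUE(rrna_16s),
                 rrna_23s = isTRUE(rrna_23s)),
            class = "rna_census")
}

#' Draw a random fixture spec targeting given categories
#'
#' Samples completeness, contamination and RNA census values uniformly
#' within each target category's region of score space, so end-to-end
#' round trips can be fuzzed.
#'
#' @param categories character vector of target categories, one bin each.
#' @param seed integer seed.
#' @param ... passed to [fixture_spec()].
#' @return a [fixture_spec()].
#' @export
random_fixture_spec <- function(categories, seed, ...) {
  stopifnot(all(categories %in% MAGQC_CATEGORIES))
  set.seed(seed)
  draw <- function(i, cat_) {
    trna <- 0L; r5 <- FALSE; r16 <- FALSE; r23 <- FALSE
    if (cat_ == "high_quality") {
      comp <- stats::runif(1, 90.5, 100); cont <- stats::runif(1, 0, 5)
      trna <- sample(18:20, 1); r5 <- r16 <- r23 <- TRUE
    } else if (cat_ == "near_complete") {
      comp <- stats::runif(1, 90.5, 100); cont <- stats::runif(1, 0, 5)
      ## must miss the high-quality census: short tRNA set or a missing rRNA
      if (stats::runif(1) < 0.5) {
        trna <- sample(0:17, 1); r5 <- r16 <- r23 <- TRUE
      } else {
        trna <- sample(0:20, 1)
        flags <- sample(c(TRUE, TRUE, FALSE))  # drop one rRNA
        r5 <- flags[1]; r16 <- flags[2]; r23 <- flags[3]
        if (trna >= 18) r16 <- FALSE
      }
    } else if (cat_ == "medium_quality") {
      comp <- stats::runif(1, 50, 90); cont <- stats::runif(1, 0, 10)
      trna <- sample(0:20, 1)
    } else if (cat_ == "low_quality") {
      comp <- stats::runif(1, 0, 49.9); cont <- stats::runif(1, 0, 10)
      trna <- sample(0:10, 1)
    } else {  # failed
      comp <- stats::runif(1, 0, 100); cont <- stats::runif(1, 10.5, 40)
      trna <- sample(0:20, 1)
    }
    data.frame(bin_id = sprintf("bin%02d_%s", i, cat_),
               target_category = cat_,
               completeness = round(comp, 2), contamination = round(cont, 2),
               trna_aa_count = trna, rrna_5s = r5, rrna_16s = r16,
               rrna_23s = r23, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, Map(draw, seq_along(categories), categories))
  fixture_spec(bins, seed = seed, ...)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_bakta_tsv <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#Annotated with a Bakta-style feature table",
               paste("#Sequence Id", "Type", "Start", "Stop", "Strand",
                     "Locus Tag", "Gene", "Product", sep = "\t")), con)
  if (nrow(features))
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                       features$contig_id, features$feature_type,
                       features$start, features$stop, features$strand,
                       paste0("LOC_", seq_len(nrow(features))),
                       ifelse(is.na(features$gene), "", features$gene),
                       features$product), con)
  invisible(path)
}

write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features))
    writeLines(sprintf("%s\tmagqc\t%s\t%d\t%d\t.\t%s\t.\tID=f%d;product=%s",
                       features$contig_id, features$feature_type,
                       features$start, features$stop, features$strand,
                       seq_len(nrow(features)), features$product), con)
  invisible(path)
}

## Fabricate the annotation feature table for one fixture bin: the requested
## number of distinct tRNA amino acids (sampled without replacement) and the
## requested rRNA genes, laid head-to-tail along the first contig
## (coordinates need only be valid, not biological).
fixture_features <- function(contig_id, trna_aa_count, rrna_5s, rrna_16s,
                             rrna_23s) {
  aas <- if (trna_aa_count > 0)
    sort(sample(MAGQC_AMINO_ACIDS, trna_aa_count)) else character()
  rows <- list()
  pos <- 1L
  for (aa in aas) {
    rows[[length(rows) + 1L]] <- list(type = "tRNA", len = 75L,
                                      product = paste0("tRNA-", aa))
    }
  if (rrna_5s) rows[[length(rows) + 1L]] <-
    list(type = "rRNA", len = 115L, product = "5S ribosomal RNA")
  if (rrna_16s) rows[[length(rows) + 1L]] <-
    list(type = "rRNA", len = 1500L, product = "16S ribosomal RNA")
  if (rrna_23s) rows[[length(rows) + 1L]] <-
    list(type = "rRNA", len = 2900L, product = "23S ribosomal RNA")
  if (!length(rows)) return(annotation_features())
  starts <- integer(length(rows)); stops <- integer(length(rows))
  for (i in seq_along(rows)) {
    starts[[i]] <- pos
    stops[[i]] <- pos + rows[[i]]$len - 1L
    pos <- stops[[i]] + 10L
  }
  annotation_features(
    contig_id = contig_id,
    feature_type = vapply(rows, `[[`, "", "type"),
    start = starts, stop = stops,
    strand = rep(c("+", "-"), length.out = length(rows)),
    product = vapply(rows, `[[`, "", "product"))
}

#' Generate a synthetic fixture on disk
#'
#' Writes, under `out_dir`: `bins/<id>.fa` (random A/C/G/T contigs),
#' `assembly.fa` (the union of all bin contigs plus unbinned extras),
#' `quality.tsv` (CheckM-dialect, with the requested scores), per-bin
#' annotation files under `annotations/`, and `manifest.json` recording the
#' ground-truth categories. Identical specs and seeds produce byte-identical
#' files.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly: paths plus a `truth` map of bin id to
#'   target category.
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(file.path(out_dir, "bins"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)

  all_seqs <- character(); all_ids <- character()
  quality_rows <- character()
  truth <- list()
  for (i in seq_len(nrow(spec$bins))) {
    b <- spec$bins[i, ]
    n <- max(1L, as.integer(b$n_contigs))
    lens <- as.integer(round(stats::runif(n, b$min_contig_bp,
                                          b$max_contig_bp)))
    ids <- sprintf("%s_c%02d", b$bin_id, seq_len(n))
    seqs <- vapply(lens, random_dna, "")
    fa <- file.path(out_dir, "bins", paste0(b$bin_id, ".fa"))
    writeLines(paste0(">", ids, "\n", seqs), fa)
    all_seqs <- c(all_seqs, seqs); all_ids <- c(all_ids, ids)

    feats <- fixture_features(ids[[1L]], b$trna_aa_count, b$rrna_5s,
                              b$rrna_16s, b$rrna_23s)
    if (spec$annotation_format %in% c("tsv", "both"))
      write_bakta_tsv(feats, file.path(out_dir, "annotations",
                                       paste0(b$bin_id, ".tsv")))
    if (spec$annotation_format %in% c("gff3", "both"))
      write_gff3(feats, file.path(out_dir, "annotations",
                                  paste0(b$bin_id, ".gff3")))
    quality_rows <- c(quality_rows,
                      sprintf("%s\tk__Bacteria (UID1)\t%s\t%s", b$bin_id,
                              format(b$completeness, nsmall = 2),
                              format(b$contamination, nsmall = 2)))
    truth[[b$bin_id]] <- b$target_category
  }

  n_unbinned <- ceiling(spec$unbinned_fraction * length(all_ids))
  if (n_unbinned > 0) {
    lens <- as.integer(round(stats::runif(n_unbinned, 500, 2000)))
    ids <- sprintf("unbinned_c%02d", seq_len(n_unbinned))
    all_ids <- c(all_ids, ids)
    all_seqs <- c(all_seqs, vapply(lens, random_dna, ""))
  }
  writeLines(paste0(">", all_ids, "\n", all_seqs),
             file.path(out_dir, "assembly.fa"))
  writeLines(c("Bin Id\tMarker lineage\tCompleteness\tContamination",
               quality_rows), file.path(out_dir, "quality.tsv"))

  manifest <- list(
    seed = spec$seed,
    bins_dir = file.path(out_dir, "bins"),
    assembly = file.path(out_dir, "assembly.fa"),
    quality_table = file.path(out_dir, "quality.tsv"),
    annotations_dir = file.path(out_dir, "annotations"),
    truth = truth)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
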