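## The full pipeline: scan bins, join the quality table, census the
## annotation, classify, compute assembly statistics, write the metadata
## CSV, sort bins by quality, and render the report.

## Gather per-bin censuses from an annotation directory (per-bin files,
## stem = bin id) or a single concatenated file (features assigned to bins
## by contig-id membership).
collect_censuses <- function(annotations, bins, min_len_fraction = 0) {
  if (is.null(annotations)) return(list())
  censuses <- list()
  if (dir.exists(annotations)) {
    files <- list.files(annotations, pattern = "\\.(tsv|gff3?)$",
                        full.names = TRUE, ignore.case = TRUE)
    for (f in files) {
      id <- tools::file_path_sans_ext(basename(f))
      if (!id %in% names(bins)) next
      feats <- parse_annotation_file(f)
      if (id %in% names(censuses)) {
        ## same bin annotated in both dialects: merge feature tables
        feats <- rbind(censuses[[paste0(".features.", id)]], feats)
      }
      censuses[[paste0(".features.", id)]] <- feats
      censuses[[id]] <- rna_census(feats, min_len_fraction)
    }
    censuses <- censuses[!grepl("^\\.features\\.", names(censuses))]
  } else if (file.exists(annotations)) {
    feats <- parse_annotation_file(annotations)
    for (id in names(bins)) {
      keep <- feats$contig_id %in% names(bins[[id]]$contig_lengths)
      censuses[[id]] <- rna_census(feats[keep, , drop = FALSE],
                                   min_len_fraction)
    }
  } else {
    magqc_stop("annotations path '", annotations, "' does not exist")
  }
  censuses
}

#' Run the MAG quality pipeline
#'
#' End-to-end quality assignment for one binning run: reads the bin FASTA
#' directory, the source assembly, the CheckM-dialect quality table and the
#' Bakta-style annotation files; classifies every bin into
#' high-quality / near-complete / medium-quality / low-quality / failed;
#' and writes the metadata CSV, the per-quality bin directories, the run's
#' JSON sidecar and a static HTML report under `outdir`.
#'
#' @param bins_dir directory of bin FASTA files (`.fasta`/`.fna`/`.fa`).
#' @param assembly the source metagenome assembly FASTA, or `NULL` to skip
#'   the bases/contigs-binned summary.
#' @param quality_table CheckM-dialect completeness/contamination table.
#' @param annotations directory of per-bin annotation files (TSV/GFF3,
#'   file stem = bin id), a single concatenated annotation file, or `NULL`
#'   (every bin then gets an empty census and high-quality is unreachable).
#' @param outdir output directory; default `"<prefix>_output"`.
#' @param prefix run identifier; default `"magqc_YYYYMMDD"` (today).
#' @param thresholds a [classification_thresholds()] object.
#' @param min_rrna_len_fraction optional partial-rRNA filter passed to
#'   [rna_census()]; default 0 (presence only).
#' @param provenance software provenance strings for the metadata CSV; a
#'   list with `completeness_software` and `annotation_software`.
#' @param sort_mode `"copy"` or `"link"` for the per-quality directories.
#' @param write_outputs set `FALSE` to classify only (nothing written).
#' @return an object of class `magqc_run`: the run report, classifications,
#'   censuses, statistics and output paths.
#' @export
#' @examples
#' \donttest{
#' fx_dir <- tempfile("fixture")
#' spec <- random_fixture_spec(c("high_quality", "medium_quality", "failed"),
#'                             seed = 1)
#' make_fixture(spec, fx_dir)
#' res <- magqc_run(bins_dir = file.path(fx_dir, "bins"),
#'                  assembly = file.path(fx_dir, "assembly.fa"),
#'                  quality_table = file.path(fx_dir, "quality.tsv"),
#'                  annotations = file.path(fx_dir, "annotations"),
#'                  outdir = tempfile("out"))
#' summary(res)
#' }
magqc_run <- function(bins_dir, assembly = NULL, quality_table,
                      annotations = NULL, outdir = NULL,
                      prefix = default_run_prefix(),
                      thresholds = classification_thresholds(),
                      min_rrna_len_fraction = 0,
                      provenance = list(completeness_software = "CheckM",
                                        annotation_software = "Bakta"),
                      sort_mode = c("copy", "link"),
                      write_outputs = TRUE) {
  sort_mode <- match.arg(sort_mode)
  bins <- scan_bin_directory(bins_dir)
  qualities <- parse_quality_table(quality_table,
                                   software = provenance$completeness_software)
  censuses <- collect_censuses(annotations, bins, min_rrna_len_fraction)
  classifications <- classify_all(qualities, censuses,
                                  thresholds = thresholds,
                                  bin_ids = names(bins))
  stats <- lapply(bins, function(b) contig_stats(b$contig_lengths))
  binned <- NULL
  if (!is.null(assembly)) {
    asm <- read_bin_fasta(assembly, bin_id = "assembly")
    binned <- binned_summary(asm, bins)
  }
  rows <- build_metadata_rows(bins, qualities, censuses, classifications,
                              stats = stats, provenance = provenance)
  report <- summarize_run(classifications, binned, prefix = prefix,
                          rows = rows)

  paths <- list()
  if (write_outputs) {
    if (is.null(outdir)) outdir <- paste0(prefix, "_output")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths$metadata_csv <- file.path(outdir, paste0(prefix, "_metadata.csv"))
    write_metadata_csv(rows, paths$metadata_csv)
    bin_paths <- vapply(bins, `[[`, "", "source_path")
    paths$quality_dirs <- file.path(outdir, MAGQC_CATEGORIES)
    sort_bins_by_quality(classifications, bin_paths,
                         file.path(outdir, "bins_by_quality"),
                         mode = sort_mode)
    paths$quality_dirs <- file.path(outdir, "bins_by_quality",
                                    MAGQC_CATEGORIES)
    paths$sidecar <- file.path(outdir, paste0(prefix, ".magqc.json"))
    write_run_sidecar(report, paths$sidecar)
    all_runs <- discover_runs(outdir)
    rpt <- render_report(all_runs, file.path(outdir, "report.html"))
    paths$report_html <- rpt$html
    paths$report_json <- rpt$json
  }

  structure(list(prefix = prefix, report = report,
                 classifications = classifications, censuses = censuses,
                 qualities = qualities, stats = stats,
                 binned_summary = binned, rows = rows,
                 thresholds = thresholds, paths = paths),
            class = "magqc_run")
}

#' @export
print.magqc_run <- function(x, ...) {
  cat(sprintf("magqc run '%s': %d MAG(s) classified\n", x$prefix,
              nrow(x$rows)))
  print(x$report)
  if (!is.null(x$binned_summary)) print(x$binned_summary)
  if (length(x$paths))
    cat("outputs under:", dirname(x$paths$metadata_csv), "\n")
  invisible(x)
}

#' Summarise a quality run
#'
#' @param object a `magqc_run` object.
#' @param ... ignored.
#' @return `object`, invisibly.
#' @method summary magqc_run
#' @export
summary.magqc_run <- function(object, ...) {
  cat(sprintf("magqc run '%s'\n\n", object$prefix))
  counts <- object$report$counts
  df <- data.frame(quality = unname(MAGQC_CATEGORY_LABELS),
                   n = unname(counts[MAGQC_CATEGORIES]))
  print(df, row.names = FALSE)
  cat(sprintf("\n%d MAG(s); median completeness %.1f%%, median contamination %.1f%%, median N50 %s bp\n",
              nrow(object$rows), stats::median(object$rows$completeness),
              stats::median(object$rows$contamination),
              format(stats::median(object$rows$n50_bp), big.mark = ",")))
  invisible(object)
}

#' Plot a quality-run overview
#'
#' Two base-graphics panels: completeness against contamination, coloured
#' by assigned quality category, and the per-category MAG counts.
#'
#' @param x a `magqc_run` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @method plot magqc_run
#' @export
plot.magqc_run <- function(x, ...) {
  cols <- c(high_quality = "#1b7837", near_complete = "#7fbf7b",
            medium_quality = "#fdb863", low_quality = "#b2abd2",
            failed = "#d7191c")
  cats <- vapply(x$classifications[x$rows$bin_id], `[[`, "", "category")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$rows$completeness, x$rows$contamination,
                 col = cols[cats], pch = 19,
                 xlab = "Completeness (%)", ylab = "Contamination (%)",
                 main = x$prefix, xlim = c(0, 100))
  graphics::legend("topleft", legend = MAGQC_CATEGORY_LABELS,
                   col = cols[MAGQC_CATEGORIES], pch = 19, cex = 0.7,
                   bty = "n")
  graphics::barplot(x$report$counts, names.arg = c("High", "Near", "Med",
                                                   "Low", "Fail"),
                    col = cols[MAGQC_CATEGORIES], ylab = "MAGs",
                    main = "Quality categories")
  invisible(x)
}
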