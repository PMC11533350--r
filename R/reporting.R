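## Metadata CSV rows, per-quality output directories, and per-run /
## cross-run summary reports (static HTML + versioned JSON sidecar).

MAGQC_SCHEMA_VERSION <- 1L

yes_no <- function(x) ifelse(x, "Yes", "No")

#' Build the per-bin metadata rows
#'
#' One row per bin with the recommended MIMAG metadata: quality category,
#' completeness/contamination scores and software, 16S recovery, tRNA
#' coverage out of 20, the completeness approach (always marker-gene based
#' for CheckM-style estimates) and assembly statistics. 5S/23S recovery is
#' carried in trailing columns so the high-quality rule is auditable.
#'
#' @param bins named list of [bin_record()] objects.
#' @param qualities named list of [quality_estimate()] objects.
#' @param censuses named list of [rna_census()] objects (missing entries
#'   are treated as empty censuses).
#' @param classifications named list from [classify_all()].
#' @param stats named list of [contig_stats()] objects; computed from
#'   `bins` when omitted.
#' @param provenance list with entries `completeness_software` and
#'   `annotation_software`, carried verbatim into the CSV (e.g.
#'   `"CheckM v1.0.13"`, `"Bakta v1.7.0 (db light v5.x)"`).
#' @return data frame with the documented column order, one row per bin,
#'   in `names(bins)` order.
#' @export
build_metadata_rows <- function(bins, qualities, censuses, classifications,
                                stats = NULL,
                                provenance = list(
                                  completeness_software = "CheckM",
                                  annotation_software = "Bakta")) {
  ids <- names(bins)
  if (is.null(stats))
    stats <- lapply(bins, function(b) contig_stats(b$contig_lengths))
  for (what in list(list("qualities", qualities),
                    list("classifications", classifications),
                    list("stats", stats))) {
    missing <- setdiff(ids, names(what[[2L]]))
    if (length(missing))
      magqc_stop("build_metadata_rows: ", what[[1L]], " missing for bin(s) ",
                 paste(missing, collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    q <- qualities[[id]]
    cen <- if (id %in% names(censuses)) censuses[[id]] else empty_rna_census()
    cl <- classifications[[id]]
    st <- stats[[id]]
    data.frame(
      bin_id = id,
      assembly_quality = MAGQC_CATEGORY_LABELS[[cl$category]],
      completeness = q$completeness,
      contamination = q$contamination,
      completeness_software = provenance$completeness_software,
      rrna_16s_recovered = yes_no(cen$rrna_16s),
      rrna_16s_software = provenance$annotation_software,
      trna_extracted = sprintf("%d/20", cen$trna_count),
      trna_software = provenance$annotation_software,
      completeness_approach = "Marker gene",
      size_bp = st$size_bp,
      n50_bp = st$n50_bp,
      max_contig_bp = st$max_contig_bp,
      n_contigs = st$n_contigs,
      rrna_5s_recovered = yes_no(cen$rrna_5s),
      rrna_23s_recovered = yes_no(cen$rrna_23s),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sort bin files into per-quality directories
#'
#' Creates the five quality subdirectories (`high_quality`, `near_complete`,
#' `medium_quality`, `low_quality`, `failed`) under `out_dir` — empty
#' categories included — and places each bin file in exactly one of them.
#'
#' @param classifications named list from [classify_all()].
#' @param bin_paths named character vector of source FASTA paths, keyed by
#'   bin id.
#' @param out_dir output directory (created if needed).
#' @param mode `"copy"` (default) or `"link"` (symlink back to the
#'   originals).
#' @return named list, category -> character vector of placed file paths.
#' @export
sort_bins_by_quality <- function(classifications, bin_paths, out_dir,
                                 mode = c("copy", "link")) {
  mode <- match.arg(mode)
  for (d in MAGQC_CATEGORIES)
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  base_names <- basename(bin_paths)
  if (anyDuplicated(base_names))
    magqc_stop("filename collision across bins: ",
               paste(unique(base_names[duplicated(base_names)]),
                     collapse = ", "))
  placed <- stats::setNames(vector("list", length(MAGQC_CATEGORIES)),
                            MAGQC_CATEGORIES)
  placed[] <- list(character())
  for (id in names(classifications)) {
    if (!id %in% names(bin_paths))
      magqc_stop("no source file recorded for bin '", id, "'")
    src <- bin_paths[[id]]
    cat_ <- classifications[[id]]$category
    dest <- file.path(out_dir, cat_, basename(src))
    ok <- if (mode == "copy") file.copy(src, dest, overwrite = TRUE)
          else file.symlink(normalizePath(src), dest)
    if (!ok) magqc_stop("could not place '", src, "' into '", dest, "'")
    placed[[cat_]] <- c(placed[[cat_]], dest)
  }
  placed
}

#' Summarise one run
#'
#' Category counts plus the bases/contigs-binned summary and the per-bin
#' metadata rows, bundled as one run report — the unit the cross-run
#' comparison report is built from.
#'
#' @param classifications named list from [classify_all()].
#' @param binned a [binned_summary()], or `NULL` when no assembly was given.
#' @param prefix run identifier, e.g. `"magqc_20260925"`.
#' @param rows metadata data frame from [build_metadata_rows()], or `NULL`.
#' @return an object of class `magqc_run_report`.
#' @export
summarize_run <- function(classifications, binned = NULL,
                          prefix = default_run_prefix(), rows = NULL) {
  cats <- vapply(classifications, `[[`, "", "category")
  counts <- stats::setNames(integer(length(MAGQC_CATEGORIES)),
                            MAGQC_CATEGORIES)
  tab <- table(factor(cats, levels = MAGQC_CATEGORIES))
  counts[names(tab)] <- as.integer(tab)
  structure(list(run_prefix = prefix, counts = counts,
                 binned_summary = binned, rows = rows),
            class = "magqc_run_report")
}

#' Default run prefix
#'
#' `"magqc_YYYYMMDD"` with today's date.
#'
#' @param date a `Date`; defaults to today.
#' @return string.
#' @export
default_run_prefix <- function(date = Sys.Date()) {
  paste0("magqc_", format(date, "%Y%m%d"))
}

#' @export
print.magqc_run_report <- function(x, ...) {
  cat(sprintf("<magqc_run_report> %s: %d MAG(s)\n", x$run_prefix,
              sum(x$counts)))
  for (cat_ in MAGQC_CATEGORIES)
    cat(sprintf("  %-22s %d\n", MAGQC_CATEGORY_LABELS[[cat_]],
                x$counts[[cat_]]))
  invisible(x)
}

run_report_to_list <- function(run) {
  list(run_prefix = run$run_prefix,
       counts = as.list(run$counts),
       binned_summary = if (!is.null(run$binned_summary))
         run$binned_summary[c("bases_binned", "contigs_binned",
                              "assembly_bases", "assembly_contigs",
                              "fraction_bases", "fraction_contigs")],
       rows = run$rows)
}

run_report_from_list <- function(x) {
  counts <- stats::setNames(integer(length(MAGQC_CATEGORIES)),
                            MAGQC_CATEGORIES)
  for (nm in names(x$counts)) counts[[nm]] <- as.integer(x$counts[[nm]])
  binned <- NULL
  if (!is.null(x$binned_summary)) {
    binned <- lapply(x$binned_summary, function(v) as.numeric(unlist(v)))
    binned$warnings <- character()
    class(binned) <- "binned_summary"
  }
  rows <- NULL
  if (!is.null(x$rows) && length(x$rows)) {
    ## x$rows is a list of per-bin named lists (one JSON object per row)
    rows <- do.call(rbind, lapply(x$rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    rows <- rows[, intersect(MAGQC_METADATA_COLUMNS, names(rows))]
    rownames(rows) <- NULL
  }
  structure(list(run_prefix = x$run_prefix, counts = counts,
                 binned_summary = binned, rows = rows),
            class = "magqc_run_report")
}

#' Write a run's JSON sidecar
#'
#' A versioned, machine-readable serialisation of a [summarize_run()]
#' report. Sidecars dropped in a shared output directory are how later
#' cross-run reports discover previous runs.
#'
#' @param run a `magqc_run_report`.
#' @param path output path; conventionally `<prefix>.magqc.json`.
#' @return `path`, invisibly.
#' @export
write_run_sidecar <- function(run, path) {
  payload <- list(magqc_schema = MAGQC_SCHEMA_VERSION,
                  runs = list(run_report_to_list(run)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read run reports back from a JSON sidecar
#'
#' @param path a sidecar written by [write_run_sidecar()] or
#'   [render_report()].
#' @return list of `magqc_run_report` objects.
#' @export
read_run_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$magqc_schema))
    magqc_stop("'", path, "' is not a magqc run sidecar")
  lapply(x$runs, run_report_from_list)
}

#' Discover run sidecars in a directory
#'
#' @param dir directory to scan for `*.magqc.json` files.
#' @return list of `magqc_run_report` objects, ordered by file name.
#' @export
discover_runs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.magqc\\.json$",
                           full.names = TRUE))
  out <- list()
  for (f in files) out <- c(out, read_run_sidecar(f))
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, caption = NULL) {
  cells <- function(tag, v)
    paste0("<", tag, ">", html_escape(as.character(v)), "</", tag, ">",
           collapse = "")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr>", cells("td", unlist(df[i, ], use.names = FALSE)), "</tr>"),
    "")
  paste0("<table>",
         if (!is.null(caption)) paste0("<caption>", html_escape(caption),
                                       "</caption>"),
         "<thead><tr>", cells("th", names(df)), "</tr></thead>",
         "<tbody>", paste(body, collapse = ""), "</tbody></table>")
}

five_number <- function(x) {
  if (!length(x)) return("-")
  q <- stats::quantile(as.numeric(x), c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  paste(formatC(q, format = "g", digits = 6), collapse = " / ")
}

#' Render the cross-run comparison report
#'
#' Writes a static, self-contained HTML report and a machine-readable JSON
#' sidecar covering every run given: the category-count comparison table,
#' bases/contigs binned per run, per-bin metadata, and per-run distribution
#' summaries (min/Q1/median/Q3/max) of completeness, contamination, N50,
#' size and tRNA coverage. Output bytes are a pure function of the inputs
#' and the package version — no timestamps, no network assets.
#'
#' @param runs non-empty list of `magqc_run_report` objects.
#' @param out_path path of the HTML file; the JSON sidecar is written next
#'   to it with extension `.json`.
#' @return named list with elements `html` and `json` (the paths),
#'   invisibly.
#' @export
render_report <- function(runs, out_path) {
  if (length(runs) == 0L)
    magqc_stop("render_report: no runs to report")
  json_path <- paste0(tools::file_path_sans_ext(out_path), ".json")
  payload <- list(magqc_schema = MAGQC_SCHEMA_VERSION,
                  runs = lapply(runs, run_report_to_list))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  prefixes <- vapply(runs, `[[`, "", "run_prefix")
  counts_df <- data.frame(Quality = unname(MAGQC_CATEGORY_LABELS),
                          stringsAsFactors = FALSE)
  for (i in seq_along(runs))
    counts_df[[prefixes[[i]]]] <- unname(runs[[i]]$counts)
  total_row <- counts_df[1L, , drop = FALSE]
  total_row$Quality <- "Total"
  for (i in seq_along(runs)) total_row[[prefixes[[i]]]] <- sum(runs[[i]]$counts)
  counts_df <- rbind(counts_df, total_row)

  binned_df <- data.frame(
    Run = prefixes,
    `Bases binned (bp)` = vapply(runs, function(r)
      if (is.null(r$binned_summary)) NA_real_
      else r$binned_summary$bases_binned, 0),
    `Contigs binned` = vapply(runs, function(r)
      if (is.null(r$binned_summary)) NA_real_
      else r$binned_summary$contigs_binned, 0),
    `Fraction of assembly bases` = vapply(runs, function(r)
      if (is.null(r$binned_summary)) NA_real_
      else round(r$binned_summary$fraction_bases, 4), 0),
    check.names = FALSE, stringsAsFactors = FALSE)

  dist_metric <- function(run, col) {
    if (is.null(run$rows)) return(numeric())
    if (col == "trna") as.numeric(sub("/20$", "", run$rows$trna_extracted))
    else run$rows[[col]]
  }
  dist_df <- data.frame(
    Run = prefixes,
    `Completeness (%)` = vapply(runs, function(r)
      five_number(dist_metric(r, "completeness")), ""),
    `Contamination (%)` = vapply(runs, function(r)
      five_number(dist_metric(r, "contamination")), ""),
    `N50 (bp)` = vapply(runs, function(r)
      five_number(dist_metric(r, "n50_bp")), ""),
    `Size (bp)` = vapply(runs, function(r)
      five_number(dist_metric(r, "size_bp")), ""),
    `tRNA /20` = vapply(runs, function(r)
      five_number(dist_metric(r, "trna")), ""),
    check.names = FALSE, stringsAsFactors = FALSE)

  per_bin <- lapply(runs, function(r) {
    if (is.null(r$rows)) return(NULL)
    html_table(r$rows, caption = paste0("Per-bin metadata - ",
                                        r$run_prefix))
  })

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>MAG quality report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:75em}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:0.3em 0.6em;text-align:left}",
    "caption{font-weight:bold;text-align:left;margin-bottom:0.3em}",
    "</style></head><body>",
    "<h1>MAG quality report</h1>",
    sprintf("<p>magqc %s; %d run(s) compared.</p>",
            as.character(utils::packageVersion("magqc")), length(runs)),
    "<h2>MAG quality categories per run</h2>",
    html_table(counts_df),
    "<h2>Bases and contigs binned</h2>",
    html_table(binned_df),
    "<h2>Per-run metric distributions (min / Q1 / median / Q3 / max)</h2>",
    html_table(dist_df),
    "<h2>Per-bin metadata</h2>",
    unlist(per_bin),
    "</body></html>")
  writeLines(html, out_path)
  invisible(list(html = out_path, json = json_path))
}
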