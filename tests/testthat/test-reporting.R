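# Metadata rows, quality directories, run summaries and the report.

run_on_fixture <- function(d, outdir = NULL, prefix = "run1",
                           write_outputs = !is.null(outdir)) {
  fx <- demo_fixture(d)
  magqc_run(bins_dir = fx$bins_dir, assembly = fx$assembly,
            quality_table = fx$quality_table,
            annotations = fx$annotations_dir, outdir = outdir,
            prefix = prefix, write_outputs = write_outputs)
}

test_that("build_metadata_rows carries the recommended metadata", {
  d <- withr::local_tempdir()
  res <- run_on_fixture(d)
  rows <- res$rows
  expect_equal(nrow(rows), 5)
  expect_true(all(rows$completeness_approach == "Marker gene"))
  expect_true(all(grepl("^\\d+/20$", rows$trna_extracted)))
  expect_true(all(rows$rrna_16s_recovered %in% c("Yes", "No")))
  hq <- rows[rows$assembly_quality == "High-quality draft", ]
  expect_true(all(as.integer(sub("/20", "", hq$trna_extracted)) >= 18))
  expect_true(all(hq$rrna_16s_recovered == "Yes" &
                    hq$rrna_5s_recovered == "Yes" &
                    hq$rrna_23s_recovered == "Yes"))
})

test_that("build_metadata_rows errors on key mismatches", {
  d <- withr::local_tempdir()
  res <- run_on_fixture(d)
  bins <- scan_bin_directory(file.path(d, "bins"))
  expect_error(
    build_metadata_rows(bins, res$qualities[-1], res$censuses,
                        res$classifications),
    "qualities missing")
})

test_that("sort_bins_by_quality places every bin in exactly one directory", {
  d <- withr::local_tempdir()
  out <- file.path(d, "out")
  res <- run_on_fixture(d, outdir = out)
  qdirs <- file.path(out, "bins_by_quality",
                     c("high_quality", "near_complete", "medium_quality",
                       "low_quality", "failed"))
  expect_true(all(dir.exists(qdirs)))
  placed <- list.files(file.path(out, "bins_by_quality"), recursive = TRUE)
  expect_length(placed, 5)  # one file per bin, 5 bins
  expect_setequal(tools::file_path_sans_ext(basename(placed)),
                  res$rows$bin_id)
  # each bin appears once and in the directory of its category
  for (id in names(res$classifications))
    expect_equal(sum(grepl(paste0("^", res$classifications[[id]]$category,
                                  "/"),
                           placed) & grepl(id, placed)), 1)
})

test_that("sort_bins_by_quality link mode leaves originals in place", {
  skip_on_os("windows")
  d <- withr::local_tempdir()
  fa <- file.path(d, "binZ.fa")
  writeLines(c(">c1", "ACGTACGT"), fa)
  cls <- list(binZ = classify_bin(quality_estimate("binZ", 40, 2)))
  out <- file.path(d, "sorted")
  placed <- sort_bins_by_quality(cls, c(binZ = fa), out, mode = "link")
  expect_true(file.exists(fa))
  link <- placed$low_quality[[1]]
  expect_equal(normalizePath(Sys.readlink(link)), normalizePath(fa))
})

test_that("empty runs still create the five quality directories", {
  d <- withr::local_tempdir()
  placed <- sort_bins_by_quality(list(), character(), d)
  expect_length(list.files(d, recursive = TRUE), 0)
  expect_length(list.dirs(d, recursive = FALSE), 5)
})

test_that("summarize_run counts categories and always sums to n bins", {
  cls <- list(a = classify_bin(quality_estimate("a", 95, 2),
                               census_of(20, TRUE, TRUE, TRUE)),
              b = classify_bin(quality_estimate("b", 95, 2),
                               census_of(20, TRUE, TRUE, TRUE)),
              c = classify_bin(quality_estimate("c", 60, 2)))
  rep_ <- summarize_run(cls, prefix = "x")
  expect_equal(rep_$counts[["high_quality"]], 2)
  expect_equal(rep_$counts[["medium_quality"]], 1)
  expect_equal(sum(rep_$counts), 3)
  expect_equal(sum(summarize_run(list(), prefix = "x")$counts), 0)
})

test_that("render_report writes HTML plus a round-trippable JSON sidecar", {
  d <- withr::local_tempdir()
  out <- file.path(d, "out")
  res <- run_on_fixture(d, outdir = out)
  expect_true(file.exists(res$paths$report_html))
  expect_true(file.exists(res$paths$report_json))

  runs <- read_run_sidecar(res$paths$report_json)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$counts, res$report$counts)
  expect_equal(runs[[1]]$rows, res$report$rows, ignore_attr = TRUE)
  expect_equal(runs[[1]]$binned_summary$bases_binned,
               res$binned_summary$bases_binned)
  # report totals equal the sum over per-bin rows
  expect_equal(sum(runs[[1]]$counts), nrow(runs[[1]]$rows))

  html <- readLines(res$paths$report_html)
  expect_true(any(grepl("MAG quality categories per run", html)))
  expect_error(render_report(list(), file.path(d, "r.html")), "no runs")
})

test_that("cross-run reports compare all sidecars in a directory", {
  d <- withr::local_tempdir()
  out <- file.path(d, "shared_out")
  res1 <- run_on_fixture(file.path(d, "a"), outdir = out, prefix = "runA")
  res2 <- run_on_fixture(file.path(d, "b"), outdir = out, prefix = "runB")
  runs <- discover_runs(out)
  expect_length(runs, 2)
  expect_equal(vapply(runs, `[[`, "", "run_prefix"), c("runA", "runB"))
  rpt <- render_report(runs, file.path(out, "combined.html"))
  html <- paste(readLines(rpt$html), collapse = "\n")
  expect_true(grepl("runA", html) && grepl("runB", html))
})
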