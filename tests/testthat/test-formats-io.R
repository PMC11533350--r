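# Readers and writers: FASTA bin directories, CheckM-dialect tables,
# Bakta TSV, GFF3, metadata CSV.

write_fasta <- function(path, seqs) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
}

test_that("scan_bin_directory finds fasta/fna/fa files only, sorted by id", {
  d <- withr::local_tempdir()
  write_fasta(file.path(d, "binB.fna"), c(c1 = "ACGTACGT"))
  write_fasta(file.path(d, "binA.fa"), c(c1 = strrep("A", 100)))
  write_fasta(file.path(d, "binC.FASTA"), c(c1 = "ACGT", c2 = "ACGTAC"))
  writeLines("not a bin", file.path(d, "notes.txt"))

  bins <- scan_bin_directory(d)
  expect_named(bins, c("binA", "binB", "binC"))
  expect_equal(unname(bins$binA$contig_lengths), 100)
  expect_equal(bins$binC$contig_lengths, c(c1 = 4, c2 = 6))

  # idempotent and order-stable
  expect_equal(names(scan_bin_directory(d)), names(bins))
})

test_that("scan_bin_directory errors on empty dirs and bad FASTA", {
  d <- withr::local_tempdir()
  writeLines("x", file.path(d, "notes.txt"))
  expect_error(scan_bin_directory(d), "no bins found")
  expect_error(scan_bin_directory(file.path(d, "nope")), "does not exist")

  writeLines("this is not fasta at all", file.path(d, "bad.fa"))
  expect_error(scan_bin_directory(d), "bad.fa")
})

test_that("bin_record enforces its invariants", {
  expect_error(bin_record("", c(c1 = 10)), "non-empty")
  expect_error(bin_record("b", c(c1 = 0)), ">= 1")
  expect_error(bin_record("b", c(c1 = 10, c1 = 20)), "duplicate contig")
  expect_error(bin_record("b", numeric()), "no contigs")
})

test_that("parse_quality_table reads the CheckM qa dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Bin Id\tMarker lineage\tCompleteness\tContamination\tStrain heterogeneity",
    "binA.fa\tk__Bacteria (UID203)\t95.0\t2.0\t0.0",
    "binB\to__Clostridiales\t60.5\t8.25\t12.5"), f)
  q <- parse_quality_table(f, software = "CheckM v1.0.13")
  expect_named(q, c("binA", "binB"))  # extension stripped to match stems
  expect_equal(q$binA$completeness, 95)
  expect_equal(q$binB$contamination, 8.25)
  expect_equal(q$binA$software, "CheckM v1.0.13")
})

test_that("parse_quality_table sniffs comma-separated re-saves", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Bin Id,Completeness,Contamination",
               "binA,95.0,2.0"), f)
  q <- parse_quality_table(f)
  expect_equal(q$binA$completeness, 95)
})

test_that("parse_quality_table rejects bad tables with useful messages", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Bin Id\tFoo\tBar", "binA\t1\t2"), f)
  expect_error(parse_quality_table(f), "found headers.*Foo")

  writeLines(c("Bin Id\tCompleteness\tContamination",
               "binA\tnot_a_number\t2.0"), f)
  expect_error(parse_quality_table(f), "row 2.*non-numeric")

  writeLines(c("Bin Id\tCompleteness\tContamination",
               "binA\t101.0\t2.0"), f)
  expect_error(parse_quality_table(f), "out of \\[0, 100\\]")

  writeLines(c("Bin Id\tCompleteness\tContamination",
               "binA\t90\t2", "binA.fa\t80\t1"), f)
  expect_error(parse_quality_table(f), "duplicate bin id")
})

test_that("parse_annotation_tsv reads Bakta-style tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#Annotated with Bakta v1.7.0",
    "#Sequence Id\tType\tStart\tStop\tStrand\tLocus Tag\tGene\tProduct",
    "c1\ttRNA\t10\t85\t+\tL1\t\ttRNA-Ala",
    "c1\tcds\t100\t400\t-\tL2\tdnaA\treplication initiator",
    "c2\trRNA\t1\t1500\t-\tL3\trrs\t16S ribosomal RNA"), f)
  x <- parse_annotation_tsv(f)
  expect_equal(nrow(x), 3)
  expect_equal(x$feature_type, c("tRNA", "other", "rRNA"))
  expect_equal(x$product[1], "tRNA-Ala")
  expect_equal(x$stop[3] - x$start[3] + 1, 1500)  # 1-based inclusive
  expect_false(any(x$pseudo))
})

test_that("parse_annotation_tsv flags malformed coordinates by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#Sequence Id\tType\tStart\tStop\tStrand\tLocus Tag\tGene\tProduct",
               "c1\ttRNA\tten\t85\t+\tL1\t\ttRNA-Ala"), f)
  expect_error(parse_annotation_tsv(f), "malformed coordinates.*line 1")
})

test_that("parse_annotation_gff3 reads standard GFF3 and stops at ##FASTA", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tBakta\ttRNA\t10\t85\t.\t+\t.\tID=t1;product=tRNA-Gly",
    "c1\tBakta\trRNA\t200\t1699\t.\t-\t.\tID=r1;gene=rrs;product=16S ribosomal RNA",
    "##FASTA",
    ">c1", "ACGTACGT"), f)
  x <- parse_annotation_gff3(f)
  expect_equal(nrow(x), 2)
  expect_equal(x$product, c("tRNA-Gly", "16S ribosomal RNA"))
  expect_equal(x$gene[2], "rrs")
  expect_equal(x$strand, c("+", "-"))
})

test_that("parse_annotation_gff3 errors on malformed feature lines", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tBakta\ttRNA\t10\t85\t.\t+\t."), f)  # 8 columns
  expect_error(parse_annotation_gff3(f), "line 2 has 8 columns")
})

test_that("gff3 parser agrees with rtracklayer on a fixture", {
  skip_if_not_installed("rtracklayer")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tBakta\ttRNA\t10\t85\t.\t+\t.\tID=t1;product=tRNA-Gly",
    "c2\tBakta\trRNA\t5\t1504\t.\t-\t.\tID=r1;product=16S ribosomal RNA"), f)
  mine <- parse_annotation_gff3(f)
  ref <- rtracklayer::import(f)
  expect_equal(mine$contig_id,
               as.character(GenomicRanges::seqnames(ref)))
  expect_equal(mine$start, GenomicRanges::start(ref))
  expect_equal(mine$stop, GenomicRanges::end(ref))
  expect_equal(mine$product, ref$product)
})

test_that("unknown strand is stored as '?', never rejected", {
  x <- annotation_features(contig_id = "c1", feature_type = "tRNA",
                           start = 1, stop = 70, strand = ".",
                           product = "tRNA-Ala")
  expect_equal(x$strand, "?")
})

test_that("metadata CSV round-trips field-exactly", {
  d <- withr::local_tempdir()
  fx <- demo_fixture(d)
  res <- magqc_run(bins_dir = fx$bins_dir, assembly = fx$assembly,
                   quality_table = fx$quality_table,
                   annotations = fx$annotations_dir,
                   write_outputs = FALSE)
  path <- file.path(d, "meta.csv")
  write_metadata_csv(res$rows, path)
  back <- read_metadata_csv(path)
  expect_equal(back, res$rows, ignore_attr = TRUE)
  expect_equal(length(readLines(path)), nrow(res$rows) + 1L)
})

test_that("write_metadata_csv rejects empty input", {
  expect_error(write_metadata_csv(data.frame(), tempfile()), "no metadata")
})
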