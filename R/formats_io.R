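## Readers and writers for every external format the tool touches:
## bin FASTA directories, CheckM-dialect quality tables, Bakta-style TSV and
## GFF3 annotation files, and the metadata CSV.

#' Strip one recognised FASTA extension from a bin identifier
#'
#' Bin identifiers are filename stems. CheckM variously reports bin ids with
#' and without the file extension, so the same stripping rule is applied to
#' quality-table ids to make the inputs joinable.
#'
#' @param x character vector of file names or bin ids.
#' @return character vector with exactly one trailing `.fasta`/`.fna`/`.fa`
#'   (case-insensitive) removed, if present.
#' @export
#' @examples
#' strip_bin_extension(c("binA.fa", "binB.fasta.fa", "binC"))
strip_bin_extension <- function(x) {
  sub(MAGQC_FASTA_EXT_RE, "", x, ignore.case = TRUE)
}

#' Construct a bin record
#'
#' A `bin_record` holds one MAG: its identifier, source file path and the
#' lengths of its contigs.
#'
#' @param bin_id non-empty string, the filename stem.
#' @param contig_lengths named integer/numeric vector of contig lengths in
#'   bp; names are contig ids, unique within the bin, every length >= 1.
#' @param source_path path the record was read from (may be `NA` for
#'   in-memory records).
#' @return an object of class `bin_record`.
#' @export
bin_record <- function(bin_id, contig_lengths, source_path = NA_character_) {
  if (!is_string(bin_id) || !nzchar(bin_id))
    magqc_stop("bin_id must be a non-empty string")
  lens <- as.numeric(contig_lengths)
  names(lens) <- names(contig_lengths)
  if (length(lens) == 0L)
    magqc_stop("bin '", bin_id, "': no contigs")
  if (is.null(names(lens)) || anyNA(names(lens)) || any(!nzchar(names(lens))))
    magqc_stop("bin '", bin_id, "': contig_lengths must be named")
  if (anyDuplicated(names(lens)))
    magqc_stop("bin '", bin_id, "': duplicate contig ids")
  if (anyNA(lens) || any(lens < 1))
    magqc_stop("bin '", bin_id, "': every contig length must be >= 1")
  structure(list(bin_id = bin_id, source_path = source_path,
                 contig_lengths = lens),
            class = "bin_record")
}

#' @export
print.bin_record <- function(x, ...) {
  cat(sprintf("<bin_record> %s: %d contigs, %s bp\n", x$bin_id,
              length(x$contig_lengths),
              format(sum(x$contig_lengths), big.mark = ",")))
  invisible(x)
}

#' Read one FASTA file into a bin record
#'
#' @param path FASTA file (`.fasta`, `.fna` or `.fa`).
#' @param bin_id identifier; defaults to the filename stem.
#' @return a [bin_record()].
#' @export
read_bin_fasta <- function(path, bin_id = strip_bin_extension(basename(path))) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     magqc_stop("unparseable FASTA '", path, "': ",
                                conditionMessage(e)))
  if (length(seqs) == 0L)
    magqc_stop("unparseable FASTA '", path, "': no sequences")
  ## FASTA headers may carry descriptions after the id token
  ids <- sub("\\s.*$", "", names(seqs))
  lens <- Biostrings::width(seqs)
  names(lens) <- ids
  bin_record(bin_id, lens, source_path = path)
}

#' Scan a directory of metagenome bins
#'
#' Finds every file with extension `.fasta`, `.fna` or `.fa`
#' (case-insensitive) and parses it into a [bin_record()]. The result is
#' sorted by bin id, so repeated scans of the same directory are
#' order-stable.
#'
#' @param dir_path directory containing the bin FASTA files.
#' @return named list of `bin_record` objects, sorted by bin id.
#' @export
scan_bin_directory <- function(dir_path) {
  if (!dir.exists(dir_path))
    magqc_stop("bin directory '", dir_path, "' does not exist")
  files <- list.files(dir_path, full.names = TRUE)
  files <- files[grepl(MAGQC_FASTA_EXT_RE, files, ignore.case = TRUE)]
  if (length(files) == 0L)
    magqc_stop("no bins found: no .fasta/.fna/.fa files in '", dir_path, "'")
  bins <- lapply(files, read_bin_fasta)
  names(bins) <- vapply(bins, `[[`, "", "bin_id")
  if (anyDuplicated(names(bins)))
    magqc_stop("duplicate bin ids after extension stripping: ",
               paste(unique(names(bins)[duplicated(names(bins))]),
                     collapse = ", "))
  bins[order(names(bins))]
}

#' Construct a completeness/contamination estimate
#'
#' @param bin_id bin identifier.
#' @param completeness percent in `[0, 100]`.
#' @param contamination percent `>= 0`; CheckM contamination can exceed 100.
#' @param software name and version of the software that produced the
#'   estimate, e.g. `"CheckM v1.0.13"`.
#' @return an object of class `quality_estimate`.
#' @export
quality_estimate <- function(bin_id, completeness, contamination,
                             software = "CheckM") {
  if (!is_string(bin_id) || !nzchar(bin_id))
    magqc_stop("bin_id must be a non-empty string")
  completeness <- as.numeric(completeness)
  contamination <- as.numeric(contamination)
  if (is.na(completeness) || completeness < 0 || completeness > 100)
    magqc_stop("bin '", bin_id, "': completeness ", completeness,
               " out of [0, 100]")
  if (is.na(contamination) || contamination < 0)
    magqc_stop("bin '", bin_id, "': contamination ", contamination,
               " must be >= 0")
  structure(list(bin_id = bin_id, completeness = completeness,
                 contamination = contamination, software = software),
            class = "quality_estimate")
}

#' Parse a CheckM-dialect completeness/contamination table
#'
#' Accepts the tab-separated table written by `checkm qa` (and comma-separated
#' re-saves of it, sniffed from the header line): a header row containing a
#' bin-id column plus `Completeness` and `Contamination` columns
#' (case-insensitive), any number of extra columns (marker lineage, strain
#' heterogeneity, ...) and one data row per bin. Bin ids are normalised by
#' [strip_bin_extension()] so they join against FASTA filename stems.
#'
#' @param path the table file.
#' @param software provenance string attached to every estimate.
#' @return named list of [quality_estimate()] objects, keyed by bin id.
#' @export
parse_quality_table <- function(path, software = "CheckM") {
  if (!file.exists(path))
    magqc_stop("quality table '", path, "' does not exist")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    magqc_stop("quality table '", path, "' has no data rows")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_row <- function(l) {
    if (sep == ",") scan(text = l, what = "", sep = ",", quiet = TRUE,
                         strip.white = TRUE)
    else trimws(strsplit(l, "\t", fixed = TRUE)[[1L]])
  }
  header <- split_row(sub("^#\\s*", "", lines[[1L]]))
  comp_col <- grep("^completeness", header, ignore.case = TRUE)[1L]
  cont_col <- grep("^contamination", header, ignore.case = TRUE)[1L]
  if (is.na(comp_col) || is.na(cont_col))
    magqc_stop("quality table '", path, "' is missing a Completeness or ",
               "Contamination column; found headers: ",
               paste(header, collapse = ", "))
  id_col <- grep("bin.?id|^bin$|genome|^id$|^name$", header,
                 ignore.case = TRUE)[1L]
  if (is.na(id_col)) id_col <- 1L

  out <- list()
  for (i in seq(2L, length(lines))) {
    fields <- split_row(lines[[i]])
    if (length(fields) < max(comp_col, cont_col, id_col))
      magqc_stop("quality table '", path, "' row ", i, " has ",
                 length(fields), " fields, expected >= ",
                 max(comp_col, cont_col, id_col))
    id <- strip_bin_extension(fields[[id_col]])
    comp <- suppressWarnings(as.numeric(fields[[comp_col]]))
    cont <- suppressWarnings(as.numeric(fields[[cont_col]]))
    if (is.na(comp) || is.na(cont))
      magqc_stop("quality table '", path, "' row ", i, " (bin '", id,
                 "'): non-numeric completeness/contamination")
    if (id %in% names(out))
      magqc_stop("quality table '", path, "': duplicate bin id '", id, "'")
    out[[id]] <- quality_estimate(id, comp, cont, software = software)
  }
  out
}

#' Construct an annotation-feature table
#'
#' Features are held as a plain data frame with one row per feature and
#' columns `contig_id`, `feature_type` (`"tRNA"`, `"rRNA"` or `"other"`),
#' `start`, `stop` (1-based inclusive), `strand` (`"+"`, `"-"` or `"?"`),
#' `product`, `gene`, `pseudo`.
#'
#' @param contig_id,feature_type,start,stop,strand,product,gene,pseudo
#'   column vectors, recycled to a common length.
#' @return a data frame of class `annotation_features`.
#' @export
annotation_features <- function(contig_id = character(),
                                feature_type = character(),
                                start = integer(), stop = integer(),
                                strand = character(), product = character(),
                                gene = NA_character_, pseudo = FALSE) {
  n <- length(contig_id)
  if (n == 0L) { gene <- character(); pseudo <- logical() }
  df <- data.frame(contig_id = as.character(contig_id),
                   feature_type = as.character(feature_type),
                   start = as.integer(start), stop = as.integer(stop),
                   strand = as.character(strand),
                   product = as.character(product),
                   gene = as.character(gene), pseudo = as.logical(pseudo),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad <- which(df$start < 1L | df$stop < df$start)
    if (length(bad))
      magqc_stop("invalid feature coordinates (need 1 <= start <= stop) ",
                 "in row(s) ", paste(bad, collapse = ", "))
    df$feature_type[!df$feature_type %in% c("tRNA", "rRNA")] <- "other"
    df$strand[!df$strand %in% c("+", "-")] <- "?"
  }
  class(df) <- c("annotation_features", "data.frame")
  df
}

normalize_feature_type <- function(type) {
  out <- rep("other", length(type))
  out[grepl("^trna$", type, ignore.case = TRUE)] <- "tRNA"
  out[grepl("^rrna$", type, ignore.case = TRUE)] <- "rRNA"
  out
}

#' Parse a Bakta-style TSV annotation file
#'
#' Reads the tab-separated feature table Bakta writes: `#`-prefixed comment
#' lines, a (possibly `#`-prefixed) header with columns `Sequence Id`,
#' `Type`, `Start`, `Stop`, `Strand`, `Locus Tag`, `Gene`, `Product`, and
#' one row per feature. Rows typed `tRNA`/`rRNA` keep that type; everything
#' else becomes `other`. A feature whose product mentions a pseudogene is
#' flagged `pseudo`.
#'
#' @param path the TSV file.
#' @return an [annotation_features()] data frame.
#' @export
parse_annotation_tsv <- function(path) {
  if (!file.exists(path))
    magqc_stop("annotation file '", path, "' does not exist")
  lines <- readLines(path, warn = FALSE)
  ## Bakta writes the column header as the last '#'-prefixed line
  header <- NULL
  comment <- grepl("^#", lines)
  header_lines <- lines[comment & grepl("sequence\\s*id", lines,
                                        ignore.case = TRUE)]
  data_lines <- lines[!comment & nzchar(trimws(lines))]
  if (length(header_lines)) {
    header <- trimws(strsplit(sub("^#+\\s*", "", header_lines[[length(header_lines)]]),
                              "\t", fixed = TRUE)[[1L]])
  } else if (length(data_lines) &&
             grepl("sequence\\s*id", data_lines[[1L]], ignore.case = TRUE)) {
    header <- trimws(strsplit(data_lines[[1L]], "\t", fixed = TRUE)[[1L]])
    data_lines <- data_lines[-1L]
  }
  col_of <- function(re, default) {
    if (is.null(header)) return(default)
    i <- grep(re, header, ignore.case = TRUE)[1L]
    if (is.na(i)) default else i
  }
  ci <- col_of("sequence\\s*id", 1L); ti <- col_of("^type$", 2L)
  si <- col_of("^start$", 3L);        ei <- col_of("^stop$|^end$", 4L)
  di <- col_of("^strand$", 5L);       gi <- col_of("^gene$", 7L)
  pri <- col_of("^product$", 8L)

  rows <- lapply(seq_along(data_lines), function(k) {
    fields <- strsplit(data_lines[[k]], "\t", fixed = TRUE)[[1L]]
    grab <- function(i) if (i <= length(fields)) trimws(fields[[i]]) else ""
    start <- suppressWarnings(as.integer(grab(si)))
    stop_ <- suppressWarnings(as.integer(grab(ei)))
    if (is.na(start) || is.na(stop_))
      magqc_stop("annotation file '", path, "': malformed coordinates on ",
                 "data line ", k)
    list(contig_id = grab(ci), type = grab(ti), start = start, stop = stop_,
         strand = grab(di), gene = grab(gi), product = grab(pri))
  })
  features_from_rows(rows)
}

features_from_rows <- function(rows) {
  if (!length(rows)) return(annotation_features())
  product <- vapply(rows, `[[`, "", "product")
  annotation_features(
    contig_id = vapply(rows, `[[`, "", "contig_id"),
    feature_type = normalize_feature_type(vapply(rows, `[[`, "", "type")),
    start = vapply(rows, function(r) r$start, 1L),
    stop = vapply(rows, function(r) r$stop, 1L),
    strand = vapply(rows, `[[`, "", "strand"),
    product = product,
    gene = vapply(rows, `[[`, "", "gene"),
    pseudo = grepl("pseudo", product, ignore.case = TRUE))
}

#' Parse a GFF3 annotation file
#'
#' Standard GFF3: 9 tab-separated columns, 1-based inclusive coordinates,
#' feature type in column 3, `product=`/`gene=` read from the attributes
#' column. `#`-prefixed comments and directives are skipped and parsing
#' stops at a `##FASTA` trailer. A feature is flagged `pseudo` when the
#' attributes carry `pseudo=true`/`pseudogene=` or the product mentions a
#' pseudogene.
#'
#' @param path the GFF3 file.
#' @return an [annotation_features()] data frame.
#' @export
parse_annotation_gff3 <- function(path) {
  if (!file.exists(path))
    magqc_stop("annotation file '", path, "' does not exist")
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(grepl("^##FASTA", lines))[1L]
  if (!is.na(fasta_at)) lines <- lines[seq_len(fasta_at - 1L)]
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs,
                                   ignore.case = TRUE))
    if (!length(m)) return("")
    utils::URLdecode(sub(paste0("^(;)?\\s*", key, "="), "", m,
                         ignore.case = TRUE))
  }
  rows <- lapply(idx, function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L)
      magqc_stop("GFF3 file '", path, "': line ", i, " has ",
                 length(fields), " columns, expected 9")
    start <- suppressWarnings(as.integer(fields[[4L]]))
    stop_ <- suppressWarnings(as.integer(fields[[5L]]))
    if (is.na(start) || is.na(stop_))
      magqc_stop("GFF3 file '", path, "': malformed coordinates on line ", i)
    attrs <- fields[[9L]]
    product <- attr_field(attrs, "product")
    pseudo <- grepl("(^|;)\\s*(pseudo=true|pseudogene=)", attrs,
                    ignore.case = TRUE) ||
      grepl("pseudo", product, ignore.case = TRUE)
    list(contig_id = fields[[1L]], type = fields[[3L]], start = start,
         stop = stop_, strand = fields[[7L]],
         gene = attr_field(attrs, "gene"), product = product,
         pseudo = pseudo)
  })
  out <- features_from_rows(rows)
  if (nrow(out))
    out$pseudo <- out$pseudo | vapply(rows, `[[`, FALSE, "pseudo")
  out
}

#' Parse an annotation file of either supported dialect
#'
#' Dispatches on extension: `.gff`, `.gff3` go to [parse_annotation_gff3()],
#' everything else to [parse_annotation_tsv()].
#'
#' @param path annotation file.
#' @return an [annotation_features()] data frame.
#' @export
parse_annotation_file <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    parse_annotation_gff3(path)
  else parse_annotation_tsv(path)
}

## Metadata CSV column order. The first 14 columns follow the recommended
## MIMAG metadata table; the trailing 5S/23S recovery columns are carried so
## the high-quality rule is auditable from the CSV alone.
MAGQC_METADATA_COLUMNS <- c(
  "bin_id", "assembly_quality", "completeness", "contamination",
  "completeness_software", "rrna_16s_recovered", "rrna_16s_software",
  "trna_extracted", "trna_software", "completeness_approach",
  "size_bp", "n50_bp", "max_contig_bp", "n_contigs",
  "rrna_5s_recovered", "rrna_23s_recovered")

#' Write the per-bin metadata CSV
#'
#' One header line plus one line per bin, in input order, RFC 4180 quoting.
#' [read_metadata_csv()] reproduces every field value exactly.
#'
#' @param rows data frame from [build_metadata_rows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    magqc_stop("no metadata rows to write")
  missing <- setdiff(MAGQC_METADATA_COLUMNS, names(rows))
  if (length(missing))
    magqc_stop("metadata rows are missing columns: ",
               paste(missing, collapse = ", "))
  utils::write.csv(rows[, MAGQC_METADATA_COLUMNS], path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a metadata CSV back
#'
#' @param path file written by [write_metadata_csv()].
#' @return data frame with the documented columns and types.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trna_extracted = "character"))
  missing <- setdiff(MAGQC_METADATA_COLUMNS, names(df))
  if (length(missing))
    magqc_stop("metadata CSV '", path, "' is missing columns: ",
               paste(missing, collapse = ", "))
  df[, MAGQC_METADATA_COLUMNS]
}
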