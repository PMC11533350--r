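## Reduce a bin's annotation features to the tRNA amino-acid coverage and
## 5S/16S/23S rRNA presence required by the high-quality criterion.

#' Amino acids covered by annotated tRNA genes
#'
#' Collects the set of standard amino acids for which at least one
#' non-pseudogene tRNA feature carries a product parseable as
#' `"tRNA-<Aaa>"`. Duplicates collapse; `tRNA-fMet` counts as Met (it is an
#' initiator methionine tRNA); selenocysteine (`Sec`/`SeC`), pyrrolysine
#' (`Pyl`) and undetermined (`tRNA-Xxx`) products are outside the 20
#' standard amino acids and are excluded. tRNA features whose product cannot
#' be parsed at all are skipped with a warning.
#'
#' @param features an [annotation_features()] data frame.
#' @return character vector of three-letter amino-acid codes (a subset of
#'   the 20 standard ones), sorted.
#' @export
#' @examples
#' f <- annotation_features(contig_id = "c1", feature_type = "tRNA",
#'                          start = 1, stop = 75, strand = "+",
#'                          product = "tRNA-Ala")
#' trna_coverage(f)
trna_coverage <- function(features) {
  f <- features[features$feature_type == "tRNA" & !features$pseudo, ,
                drop = FALSE]
  if (nrow(f) == 0L) return(character())
  has <- grepl("tRNA-([A-Za-z]{2,4})", f$product)
  codes <- sub("^tRNA-", "", regmatches(f$product,
                                        regexpr("tRNA-[A-Za-z]{2,4}",
                                                f$product)))
  if (any(!has))
    magqc_warn(sum(!has), " tRNA feature(s) with unparseable product ",
               "skipped (e.g. '", f$product[!has][1L], "')")
  codes[tolower(codes) == "fmet"] <- "Met"
  ## normalise case to Xxx form before matching the standard 20
  codes <- paste0(toupper(substr(codes, 1, 1)),
                  tolower(substr(codes, 2, nchar(codes))))
  keep <- codes %in% MAGQC_AMINO_ACIDS
  sort(unique(codes[keep]))
}

#' Presence of the 5S, 16S and 23S rRNA genes
#'
#' A flag is true when at least one non-pseudogene rRNA feature's product
#' contains the `5S`/`16S`/`23S` token (case-insensitive), with a gene-name
#' fallback (`rrf`/`rrs`/`rrl`), and the feature is long enough:
#' `stop - start + 1 >= min_len_fraction` times the reference gene length
#' (5S 120 bp, 16S 1500 bp, 23S 2900 bp). The default `min_len_fraction = 0`
#' disables the length filter, i.e. presence only.
#'
#' @param features an [annotation_features()] data frame.
#' @param min_len_fraction minimum feature length as a fraction of the
#'   reference rRNA length, in `[0, 1]`; default 0.
#' @return named logical vector `c("5S" = , "16S" = , "23S" = )`.
#' @export
rrna_presence <- function(features, min_len_fraction = 0) {
  stopifnot(min_len_fraction >= 0, min_len_fraction <= 1)
  f <- features[features$feature_type == "rRNA" & !features$pseudo, ,
                drop = FALSE]
  out <- c(`5S` = FALSE, `16S` = FALSE, `23S` = FALSE)
  if (nrow(f) == 0L) return(out)
  len <- f$stop - f$start + 1L
  gene_re <- c(`5S` = "^rrf", `16S` = "^rrs", `23S` = "^rrl")
  for (sub_unit in names(out)) {
    hit <- grepl(paste0("(^|[^0-9.])", sub_unit, "([^0-9]|$)"), f$product,
                 ignore.case = TRUE) |
      grepl(gene_re[[sub_unit]], f$gene, ignore.case = TRUE)
    long_enough <- len >= min_len_fraction * MAGQC_RRNA_REF_LEN[[sub_unit]]
    out[[sub_unit]] <- any(hit & long_enough)
  }
  out
}

#' Census a bin's tRNA and rRNA annotation
#'
#' Composition of [trna_coverage()] and [rrna_presence()]: the distinct
#' standard amino acids with an annotated tRNA (out of 20) and the presence
#' flags for the three rRNA genes.
#'
#' @inheritParams rrna_presence
#' @return an object of class `rna_census` with fields `trna_amino_acids`,
#'   `trna_count`, `rrna_5s`, `rrna_16s`, `rrna_23s`.
#' @export
rna_census <- function(features, min_len_fraction = 0) {
  aas <- trna_coverage(features)
  rrna <- rrna_presence(features, min_len_fraction)
  structure(list(trna_amino_acids = aas, trna_count = length(aas),
                 rrna_5s = rrna[["5S"]], rrna_16s = rrna[["16S"]],
                 rrna_23s = rrna[["23S"]]),
            class = "rna_census")
}

#' An empty RNA census
#'
#' Used for bins with no annotation file: no tRNA coverage, no rRNA genes.
#'
#' @return an `rna_census` with count 0 and all rRNA flags false.
#' @export
empty_rna_census <- function() rna_census(annotation_features())

#' @export
print.rna_census <- function(x, ...) {
  rr <- c("5S", "16S", "23S")[c(x$rrna_5s, x$rrna_16s, x$rrna_23s)]
  cat(sprintf("<rna_census> tRNA %d/20; rRNA: %s\n", x$trna_count,
              if (length(rr)) paste(rr, collapse = ", ") else "none"))
  invisible(x)
}
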