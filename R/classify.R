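## MIMAG-style quality classification with the near-complete extension.
## Five categories, rules evaluated in strict order, first match wins:
##
##   high_quality    completeness > 90 AND contamination <= 5 AND
##                   >= 18 tRNA amino acids AND 5S+16S+23S rRNA present
##   near_complete   completeness > 90 AND contamination <= 5
##   medium_quality  completeness >= 50 AND contamination <= 10
##   low_quality     completeness < 50 AND contamination <= 10
##   failed          otherwise (contamination > 10)
##
## The published category table prints Medium/Low contamination as "<= 10%"
## and Failed as ">= 10%", overlapping at exactly 10%: first-match order
## resolves the tie, so 10.0% with completeness >= 50 is Medium. Likewise
## exactly 5% contamination is still eligible for High/Near-complete (the
## table's inclusive bound). Completeness/contamination are compared exactly
## as parsed; no rounding is applied.

#' Classification thresholds
#'
#' The category boundaries, default-locked to the MIMAG standard values.
#' Completeness bounds are percentages; `hq_completeness` is exclusive
#' (a bin must *exceed* it), `mq_completeness` inclusive. Contamination
#' bounds are inclusive.
#'
#' @param hq_completeness completeness a bin must exceed for
#'   high-quality/near-complete status; default 90 (%).
#' @param hq_contamination maximum contamination for
#'   high-quality/near-complete; default 5 (%).
#' @param hq_min_trna minimum number of distinct standard amino acids with
#'   an annotated tRNA for high-quality; default 18 (of 20).
#' @param mq_completeness minimum completeness for medium-quality;
#'   default 50 (%).
#' @param mq_contamination maximum contamination for medium/low quality;
#'   beyond it a bin fails; default 10 (%).
#' @return an object of class `magqc_thresholds`.
#' @export
classification_thresholds <- function(hq_completeness = 90,
                                      hq_contamination = 5,
                                      hq_min_trna = 18,
                                      mq_completeness = 50,
                                      mq_contamination = 10) {
  th <- list(hq_completeness = as.numeric(hq_completeness),
             hq_contamination = as.numeric(hq_contamination),
             hq_min_trna = as.integer(hq_min_trna),
             mq_completeness = as.numeric(mq_completeness),
             mq_contamination = as.numeric(mq_contamination))
  if (!(th$mq_completeness >= 0 && th$mq_completeness <= th$hq_completeness &&
        th$hq_completeness <= 100))
    magqc_stop("need 0 <= mq_completeness <= hq_completeness <= 100")
  if (!(th$hq_contamination <= th$mq_contamination))
    magqc_stop("need hq_contamination <= mq_contamination")
  if (th$hq_min_trna < 0 || th$hq_min_trna > 20)
    magqc_stop("hq_min_trna must be in [0, 20]")
  structure(th, class = "magqc_thresholds")
}

#' Classify one bin
#'
#' Applies the five category rules in strict order to a completeness /
#' contamination estimate and an RNA census; the first rule that matches
#' determines the category. The returned object carries the full rule
#' trace so a classification can be audited.
#'
#' @param quality a [quality_estimate()].
#' @param census an [rna_census()]; `NULL` means no annotation was
#'   available and is treated as an empty census.
#' @param thresholds a [classification_thresholds()] object.
#' @return an object of class `magqc_classification` with fields `bin_id`,
#'   `category` (one of `"high_quality"`, `"near_complete"`,
#'   `"medium_quality"`, `"low_quality"`, `"failed"`) and `trace`, a data
#'   frame of the rule checks in evaluation order with their outcomes.
#' @export
#' @examples
#' q <- quality_estimate("binA", 95, 2)
#' classify_bin(q, empty_rna_census())$category  # "near_complete"
classify_bin <- function(quality, census = NULL,
                         thresholds = classification_thresholds()) {
  stopifnot(inherits(quality, "quality_estimate"),
            inherits(thresholds, "magqc_thresholds"))
  if (is.null(census)) census <- empty_rna_census()
  stopifnot(inherits(census, "rna_census"))
  comp <- quality$completeness
  cont <- quality$contamination
  th <- thresholds

  checks <- list(
    high_quality = c(
      completeness_above_90 = comp > th$hq_completeness,
      contamination_at_most_5 = cont <= th$hq_contamination,
      trna_at_least_18 = census$trna_count >= th$hq_min_trna,
      all_rrna_present = census$rrna_5s && census$rrna_16s && census$rrna_23s),
    near_complete = c(
      completeness_above_90 = comp > th$hq_completeness,
      contamination_at_most_5 = cont <= th$hq_contamination),
    medium_quality = c(
      completeness_at_least_50 = comp >= th$mq_completeness,
      contamination_at_most_10 = cont <= th$mq_contamination),
    low_quality = c(
      completeness_below_50 = comp < th$mq_completeness,
      contamination_at_most_10 = cont <= th$mq_contamination),
    failed = c(contamination_above_10 = TRUE))

  trace <- data.frame(rule = character(), check = character(),
                      passed = logical(), stringsAsFactors = FALSE)
  category <- NA_character_
  for (rule in names(checks)) {
    cc <- checks[[rule]]
    trace <- rbind(trace,
                   data.frame(rule = rule, check = names(cc),
                              passed = unname(cc),
                              stringsAsFactors = FALSE))
    if (all(cc)) { category <- rule; break }
  }
  structure(list(bin_id = quality$bin_id, category = category,
                 trace = trace),
            class = "magqc_classification")
}

#' @export
print.magqc_classification <- function(x, ...) {
  cat(sprintf("<magqc_classification> %s: %s\n", x$bin_id,
              MAGQC_CATEGORY_LABELS[[x$category]]))
  invisible(x)
}

#' Classify every bin in a run
#'
#' @param qualities named list of [quality_estimate()] objects, keyed by
#'   bin id (as returned by [parse_quality_table()]).
#' @param censuses named list of [rna_census()] objects; a bin with no
#'   census entry is scored against an empty census with a warning.
#' @param thresholds a [classification_thresholds()] object.
#' @param bin_ids the bins that must be classified; defaults to the quality
#'   table's bins. Bins listed here but absent from `qualities` are a hard
#'   error (FASTA present but no quality estimate).
#' @return named list of `magqc_classification` objects, sorted by bin id.
#' @export
classify_all <- function(qualities, censuses = list(),
                         thresholds = classification_thresholds(),
                         bin_ids = names(qualities)) {
  bin_ids <- sort(bin_ids)
  missing_q <- setdiff(bin_ids, names(qualities))
  if (length(missing_q))
    magqc_stop("bins without a completeness/contamination estimate: ",
               paste(missing_q, collapse = ", "))
  missing_c <- setdiff(bin_ids, names(censuses))
  if (length(missing_c))
    magqc_warn("no annotation for bin(s) ",
               paste(missing_c, collapse = ", "),
               "; using an empty RNA census (high-quality unreachable)")
  out <- lapply(bin_ids, function(id)
    classify_bin(qualities[[id]],
                 if (id %in% names(censuses)) censuses[[id]] else NULL,
                 thresholds))
  names(out) <- bin_ids
  out
}
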