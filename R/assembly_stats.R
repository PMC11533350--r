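## Per-bin assembly statistics and the run-level bases/contigs-binned summary.

#' Assembly statistics for a set of contig lengths
#'
#' Computes total size, N50, longest contig and contig count. N50 uses the
#' common convention: the largest observed contig length `L` such that
#' contigs of length `>= L` together cover at least half the total size.
#'
#' @param lengths numeric vector of positive contig lengths in bp.
#' @return an object of class `contig_stats` with fields `size_bp`,
#'   `n50_bp`, `max_contig_bp`, `n_contigs`.
#' @export
#' @examples
#' contig_stats(c(40, 30, 20, 10))  # N50 = 30
contig_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L)
    magqc_stop("contig_stats: empty length list")
  if (anyNA(lengths) || any(lengths <= 0))
    magqc_stop("contig_stats: every contig length must be a positive number")
  sorted <- sort(lengths, decreasing = TRUE)
  total <- sum(sorted)
  n50 <- sorted[[which(cumsum(sorted) >= total / 2)[1L]]]
  structure(list(size_bp = total, n50_bp = n50,
                 max_contig_bp = sorted[[1L]],
                 n_contigs = length(lengths)),
            class = "contig_stats")
}

#' @export
print.contig_stats <- function(x, ...) {
  cat(sprintf("<contig_stats> size %s bp, N50 %s bp, max %s bp, %d contigs\n",
              format(x$size_bp, big.mark = ","),
              format(x$n50_bp, big.mark = ","),
              format(x$max_contig_bp, big.mark = ","), x$n_contigs))
  invisible(x)
}

#' Bases and contigs binned, relative to the source assembly
#'
#' Sums bases and contigs over all bins and expresses them as fractions of
#' the source assembly, the run-level summary used to compare binning tools.
#' Bin contigs absent from the assembly, and contigs shared between bins
#' (competing binners legitimately overlap), are counted with a recorded
#' warning rather than rejected; overlaps are double-counted in the totals.
#'
#' @param assembly a [bin_record()] holding the full assembly.
#' @param bins list of [bin_record()] objects.
#' @return an object of class `binned_summary` with fields `bases_binned`,
#'   `contigs_binned`, `assembly_bases`, `assembly_contigs`,
#'   `fraction_bases`, `fraction_contigs` and a `warnings` character vector.
#' @export
binned_summary <- function(assembly, bins) {
  if (!inherits(assembly, "bin_record"))
    magqc_stop("assembly must be a bin_record")
  warnings <- character()
  all_ids <- unlist(lapply(bins, function(b) names(b$contig_lengths)),
                    use.names = FALSE)
  missing <- setdiff(unique(all_ids), names(assembly$contig_lengths))
  if (length(missing))
    warnings <- c(warnings,
                  paste0(length(missing), " bin contig id(s) absent from the",
                         " assembly: ",
                         paste(utils::head(missing, 5L), collapse = ", "),
                         if (length(missing) > 5L) ", ..."))
  n_overlap <- sum(duplicated(all_ids))
  if (n_overlap > 0L)
    warnings <- c(warnings,
                  paste0(n_overlap, " contig assignment(s) shared between ",
                         "bins; bases/contigs binned double-count them"))
  bases <- sum(vapply(bins, function(b) sum(b$contig_lengths), 0))
  contigs <- length(all_ids)
  asm_bases <- sum(assembly$contig_lengths)
  asm_contigs <- length(assembly$contig_lengths)
  for (w in warnings) magqc_warn(w)
  structure(list(bases_binned = bases, contigs_binned = contigs,
                 assembly_bases = asm_bases, assembly_contigs = asm_contigs,
                 fraction_bases = if (asm_bases > 0) bases / asm_bases else 0,
                 fraction_contigs = if (asm_contigs > 0)
                   contigs / asm_contigs else 0,
                 warnings = warnings),
            class = "binned_summary")
}

#' @export
print.binned_summary <- function(x, ...) {
  cat(sprintf(paste0("<binned_summary> %s / %s bp (%.1f%%), ",
                     "%d / %d contigs (%.1f%%) binned\n"),
              format(x$bases_binned, big.mark = ","),
              format(x$assembly_bases, big.mark = ","),
              100 * x$fraction_bases, x$contigs_binned, x$assembly_contigs,
              100 * x$fraction_contigs))
  invisible(x)
}
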