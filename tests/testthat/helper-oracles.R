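# Independent oracles and small builders shared across the suite.

# Shortcut: one annotation feature row.
feat <- function(product, type = "tRNA", contig = "c1", start = 1,
                 len = 80, strand = "+", gene = NA_character_,
                 pseudo = FALSE) {
  annotation_features(contig_id = contig, feature_type = type,
                      start = start, stop = start + len - 1,
                      strand = strand, product = product, gene = gene,
                      pseudo = pseudo)
}

feats <- function(...) do.call(rbind, list(...))

# Census with the first k standard amino acids and given rRNA flags,
# built through the real feature path.
census_of <- function(k, r5 = FALSE, r16 = FALSE, r23 = FALSE) {
  aa20 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val")
  rows <- list()
  for (aa in aa20[seq_len(k)])
    rows <- c(rows, list(feat(paste0("tRNA-", aa))))
  if (r5) rows <- c(rows, list(feat("5S ribosomal RNA", type = "rRNA",
                                    len = 120)))
  if (r16) rows <- c(rows, list(feat("16S ribosomal RNA", type = "rRNA",
                                     len = 1500)))
  if (r23) rows <- c(rows, list(feat("23S ribosomal RNA", type = "rRNA",
                                     len = 2900)))
  if (!length(rows)) return(empty_rna_census())
  rna_census(do.call(rbind, rows))
}

# Fast census builder for fuzzing: constructs the input container directly
# (first k amino acids), bypassing the feature path exercised elsewhere.
census_from <- function(k, r5, r16, r23) {
  aa20 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val")
  structure(list(trna_amino_acids = aa20[seq_len(k)], trna_count = k,
                 rrna_5s = r5, rrna_16s = r16, rrna_23s = r23),
            class = "rna_census")
}

# Brute-force N50 by definition: the largest observed length L such that
# contigs of length >= L cover at least half the total.
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  ok <- vapply(sort(unique(lengths)),
               function(L) sum(lengths[lengths >= L]) >= total / 2, TRUE)
  max(sort(unique(lengths))[ok])
}

# Independent first-match classifier: all five category predicates tested
# separately, winner is the first that holds.
classify_oracle <- function(comp, cont, trna, r5, r16, r23) {
  preds <- c(
    high_quality = comp > 90 && cont <= 5 && trna >= 18 && r5 && r16 && r23,
    near_complete = comp > 90 && cont <= 5,
    medium_quality = comp >= 50 && cont <= 10,
    low_quality = comp < 50 && cont <= 10,
    failed = TRUE)
  names(preds)[which(preds)[1L]]
}

category_of <- function(comp, cont, census = empty_rna_census(),
                        thresholds = classification_thresholds()) {
  classify_bin(quality_estimate("x", comp, cont), census,
               thresholds)$category
}

# Deterministic small fixture used by several reporting/CLI tests.
demo_fixture <- function(dir, seed = 7) {
  spec <- random_fixture_spec(c("high_quality", "near_complete",
                                "medium_quality", "low_quality", "failed"),
                              seed = seed)
  make_fixture(spec, dir)
}
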