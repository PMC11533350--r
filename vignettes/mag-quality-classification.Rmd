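---
title: "Classifying metagenome-assembled genomes under the MIMAG standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metagenome-assembled genomes under the MIMAG standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magqc)
```

## The problem

Metagenomic binning groups assembly contigs into putative genomes
(metagenome-assembled genomes, MAGs). Because a MAG has no reference to
compare against, its quality is assessed indirectly: completeness and
contamination are estimated from lineage-specific single-copy marker genes
(CheckM being the de facto tool), and assembly quality is judged from the
presence of the ribosomal machinery — tRNA genes covering the standard
amino acids and the three prokaryotic rRNA genes (5S, 16S, 23S). The MIMAG
reporting standard turns these into draft-quality tiers, and the
near-complete extension adds a tier for bins that are essentially complete
but missing the rRNA/tRNA complement — a common situation with short-read
metagenomes, where rRNA operons assemble poorly.

`magqc` consumes what a practitioner already has on disk — bin FASTA files,
a CheckM-dialect quality table, Bakta-style annotation files — and assigns
each bin exactly one of five categories, emits the recommended MIMAG
metadata as CSV, sorts the bins into per-quality directories, and renders
per-run and cross-run comparison reports. It deliberately does not run
CheckM or Bakta itself: its scope starts downstream of those tools, which
keeps it dependency-light, fast and fully testable offline.

## The classification rules

Each bin is scored on completeness $C$ (%), contamination $X$ (%), the
number $t$ of distinct standard amino acids with at least one annotated
tRNA gene (out of 20), and presence of the 5S/16S/23S rRNA genes. Rules are
evaluated in strict order; the first that matches wins:

| rank | category       | rule |
|------|----------------|------|
| 1 | High-quality draft  | $C > 90$, $X \le 5$, $t \ge 18$, all of 5S, 16S, 23S present |
| 2 | Near complete       | $C > 90$, $X \le 5$ |
| 3 | Medium-quality draft| $C \ge 50$, $X \le 10$ |
| 4 | Low-quality draft   | $C < 50$, $X \le 10$ |
| 5 | Failed              | otherwise ($X > 10$) |

Two boundary points deserve a note, because the published tier table leaves
them ambiguous:

* **Contamination exactly 10%.** The medium/low tiers are printed as
  "$\le 10\%$" and the failed tier as "$\ge 10\%$", which overlap at
  exactly 10. First-match order resolves the tie: a bin at $X = 10$ with
  $C \ge 50$ is medium-quality, preserving both printed inclusive bounds.
* **Contamination exactly 5%.** The tier table prints "$\le 5\%$" for the
  top two tiers while the prose defines near-complete as "< 5%
  contaminated". We treat the table as normative: $X = 5.0$ remains
  eligible for high-quality/near-complete status.

Completeness and contamination are compared exactly as parsed — CheckM
reports two decimals and no additional rounding policy is imposed, so a bin
at $C = 90.01$ clears the 90% bar and a bin at $C = 90.00$ does not.

The thresholds are exposed as `classification_thresholds()` arguments (and
`--hq-*`/`--mq-*` CLI flags) but default-locked to the standard values;
with defaults the behaviour is bit-identical to the table above. Every
classification carries a rule trace (`classify_bin(...)$trace`) so the
decision for any bin can be audited check by check.

## The RNA census

The high-quality criterion needs a census, not a gene count:

* **tRNA coverage** is the number of *distinct* standard amino acids with
  at least one annotated, non-pseudogene tRNA whose product parses as
  `tRNA-<Aaa>`. Duplicate isoacceptors collapse. `tRNA-fMet` counts toward
  Met (it is an initiator methionine tRNA); selenocysteine, pyrrolysine and
  undetermined (`tRNA-Xxx`) products fall outside the 20-amino-acid
  denominator and are excluded. This reading is fixed by the metadata
  schema itself, which reports "tRNA extracted" as `N/20`.
* **rRNA presence** is matched on the `5S`/`16S`/`23S` token in the product
  string (case-insensitive), with a gene-name fallback (`rrf`/`rrs`/`rrl`).
  The standards speak of "presence and completeness" without
  operationalising completeness, so partial-gene handling is exposed as an
  explicit knob: `min_len_fraction` requires a feature to reach that
  fraction of the reference gene length (5S 120 bp, 16S 1500 bp, 23S
  2900 bp). The default is 0 — presence only — which matches how annotation
  tables are usually consumed; set `min_rrna_len_fraction = 0.8` in
  `magqc_run()` to demand near-full-length genes.

Both reductions are monotone: adding annotation can only raise the tRNA
count or set an rRNA flag, never the reverse, and the classifier inherits
that monotonicity (more annotation never demotes a bin). The suite fuzzes
these properties alongside an independent first-match oracle.

## Assembly statistics

Per bin, the package reports total size, N50, the longest contig, and the
contig count. N50 follows the common convention: the largest observed
contig length $L$ such that contigs of length $\ge L$ together cover at
least half the total size. The tie convention matters only on degenerate
inputs (e.g. `c(50, 50)` has N50 50); the tests pin it against a
brute-force enumeration of all candidate lengths and against `seqkit`.

Run-level, `binned_summary()` totals bases and contigs across bins and
divides by the assembly totals — the comparison axis used when evaluating
binning tools against one another. Bins produced by competing binners may
legitimately share contigs, so overlaps are summed with double counting and
a recorded warning rather than rejected; bin contigs absent from the
assembly likewise warn but never abort a run.

## Input conventions

* **Bin identifiers** are filename stems. Exactly one recognised extension
  (`.fasta`/`.fna`/`.fa`, case-insensitive) is stripped, and the same rule
  is applied to quality-table ids, since CheckM variously reports ids with
  and without extensions. This makes the three inputs joinable with no
  mapping file.
* **Quality tables** may be tab- or comma-separated (sniffed from the
  header). Extra columns are ignored. A bin with a FASTA file but no
  quality row is a hard error; completeness outside $[0, 100]$, non-numeric
  scores and duplicate ids are rejected with row-level messages.
  Contamination above 100% is legal (CheckM can report it).
* **Annotations** may be one file per bin (stem = bin id, Bakta-style TSV
  or GFF3) or one concatenated file, in which case features are assigned to
  bins by contig-id membership. A bin with no annotation gets an empty
  census — it can still reach near-complete, never high-quality — with a
  warning rather than an error, since that is the correct reading of
  missing evidence. Strand is irrelevant to the census, so unknown strands
  are stored as `"?"` and never rejected.

## Reports and determinism

`magqc_run()` writes, under one output directory: the metadata CSV (the
recommended MIMAG fields, plus trailing 5S/23S recovery columns so the
high-quality rule is auditable from the CSV alone), the five per-quality
bin directories, a versioned JSON sidecar (`magqc_schema: 1`) and a static
HTML report. Cross-run comparison works by dropping sidecars in a shared
directory: every `*.magqc.json` found there is folded into the report, so
re-running different binners into the same output root yields a side-by-side
category-count table, bases/contigs binned, and per-run metric
distributions.

All outputs are pure functions of the inputs and the package version: no
timestamps, no network assets, no environment-dependent formatting. Two
runs on the same inputs produce byte-identical CSV and JSON; the suite
asserts this at the byte level. The HTML report uses static tables (the
interactive-figure styling of pipeline-embedded reports is a non-goal);
`plot()` on the run object draws the completeness/contamination scatter and
category counts with base graphics.

## The synthetic-fixture generator

`make_fixture()` fabricates a complete, seeded input set: random-A/C/G/T
bin FASTAs, an assembly containing every bin contig plus a configurable
unbinned fraction (default 0.25 of the binned contig count, a realistic
leftover for real binning runs), a CheckM-dialect quality table carrying
the *requested* completeness/contamination, per-bin annotation files with
exactly the requested number of distinct tRNA amino acids and rRNA genes,
and a JSON manifest of ground-truth categories. Default bins have 3 contigs
of 500–2000 bp — large enough to exercise every parser and statistic,
small enough that a hundred end-to-end round trips run in seconds.

Scores are injected, not simulated from marker genes, because the tool's
scope starts downstream of the estimator; and the sequence content is
random, not biological. Passing fixture round trips therefore demonstrates
that parsing, joining, censusing and classification are correct — they say
nothing about CheckM's or Bakta's accuracy on real data, which this package
treats as given inputs. A `fixture_spec` is validated at construction: the
requested scores and census must actually classify to the target category
under default thresholds, so an inconsistent spec fails loudly rather than
silently producing a mislabelled ground truth.

## Verification strategy and problem sizes

The test suite pins every rule boundary by sweep (completeness in 0.1%
steps, contamination in 0.1% steps, tRNA coverage 0–20), fuzzes classifier
totality, monotonicity and equivalence with an independently written
first-match oracle on 10,000 random score/census triples, checks N50
against brute-force enumeration on 1,000 random length multisets (plus
`seqkit` on a generated FASTA), round-trips the CSV and JSON outputs
field-exactly, and classifies 100 random single-bin fixtures (20 per
category) end-to-end from files back to their ground-truth categories.
These sizes keep the whole suite under a couple of minutes on one CPU while
leaving the boundary behaviour fully enumerated rather than sampled.

## Known limitations

* Completeness/contamination are taken at face value from the input table;
  no model-based re-estimation (CheckM2-style) and no composite quality
  score (e.g. $C - 5X$) is computed — both are deliberate non-goals.
* rRNA matching is string-based on products/gene names. Annotations that
  encode the subunit some other way (e.g. only in a `note` field) would
  need the gene-name fallback or pre-processing.
* The fixed-width pretty-table that `checkm lineage_wf` prints to stdout is
  not parsed; use the tab-separated `qa` output.
* Eukaryotic MAGs (18S/28S) are out of scope; the census universe is
  prokaryotic.
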