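# magqc

Quality classification of metagenome-assembled genomes (MAGs) under the
MIMAG standards, with the near-complete extension.

## What it does, and for whom

Metagenomic binning produces putative genomes with no reference to compare
against, so their quality is judged indirectly: **completeness** and
**contamination** estimated from single-copy marker genes (CheckM), and the
presence of the ribosomal machinery — tRNA genes covering the standard
amino acids and the 5S/16S/23S rRNA genes — from annotation (Bakta).
`magqc` is for anyone who has those outputs on disk and needs standardised,
submission-ready quality tiers and metadata: it reads a directory of bin
FASTAs, a CheckM-dialect quality table and Bakta-style TSV/GFF3
annotations, and assigns each bin exactly one of five categories by
first-match rule order:

| category | completeness *C* | contamination *X* | RNA requirement |
|---|---|---|---|
| High-quality draft | *C* > 90% | *X* ≤ 5% | ≥ 18 of 20 tRNA amino acids and 5S, 16S, 23S rRNA |
| Near complete | *C* > 90% | *X* ≤ 5% | none |
| Medium-quality draft | *C* ≥ 50% | *X* ≤ 10% | none |
| Low-quality draft | *C* < 50% | *X* ≤ 10% | none |
| Failed | — | *X* > 10% | none |

The near-complete tier catches bins that are essentially complete but lack
the rRNA/tRNA complement — common with short-read assemblies, where rRNA
operons collapse. Alongside the classification, `magqc` computes assembly
statistics (size, N50, longest contig, contig count), writes the
recommended MIMAG metadata as CSV, sorts the bin files into per-quality
directories, and renders deterministic per-run and cross-run comparison
reports (category counts, bases/contigs binned, metric distributions) so
competing binning runs can be compared side by side. It does **not** run
CheckM or Bakta itself — its scope starts downstream of those tools.

## Worked example

Every input can be fabricated by the built-in fixture generator, so the
full pipeline runs with no external data:

```r
library(magqc)

fx_dir <- file.path(tempdir(), "fx"); out <- file.path(tempdir(), "out")
spec <- random_fixture_spec(c("high_quality", "near_complete",
                              "medium_quality", "low_quality", "failed"),
                            seed = 42)
make_fixture(spec, fx_dir)

res <- magqc_run(bins_dir      = file.path(fx_dir, "bins"),
                 assembly      = file.path(fx_dir, "assembly.fa"),
                 quality_table = file.path(fx_dir, "quality.tsv"),
                 annotations   = file.path(fx_dir, "annotations"),
                 outdir = out, prefix = "demo")
summary(res)
#> magqc run 'demo'
#>
#>               quality n
#>    High-quality draft 1
#>         Near complete 1
#>  Medium-quality draft 1
#>     Low-quality draft 1
#>                Failed 1
#>
#> 5 MAG(s); median completeness 97.8%, median contamination 4.7%, median N50 1,872 bp
```

Each count is the number of bins landing in that tier. The per-bin
metadata rows show why: `bin02_near_complete` is 98.39% complete and 3.21%
contaminated but covers only 17/20 tRNA amino acids, so it misses the
high-quality tier; `bin05_failed` is 97.82% complete yet 13.97%
contaminated, and contamination above 10% fails a bin regardless of
completeness.

```r
res$rows[, c("bin_id", "assembly_quality", "completeness",
             "contamination", "trna_extracted")]
#>                bin_id     assembly_quality completeness contamination trna_extracted
#>    bin01_high_quality   High-quality draft        99.19          4.69          18/20
#>   bin02_near_complete        Near complete        98.39          3.21          17/20
#>  bin03_medium_quality Medium-quality draft        68.31          7.19           6/20
#>     bin04_low_quality    Low-quality draft        12.75          4.62           4/20
#>          bin05_failed               Failed        97.82         13.97          17/20
```

`out/` now holds `demo_metadata.csv`, `bins_by_quality/<category>/` with
the sorted bin files, `demo.magqc.json` (machine-readable run sidecar) and
`report.html`/`report.json`. Re-running other binners with the same
`outdir` folds every sidecar found there into one cross-run comparison
report. The same pipeline is scriptable from a shell via the thin wrapper
`inst/cli/magqc` (`run`, `report` and `fixture` subcommands).

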