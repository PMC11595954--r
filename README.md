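# mitomarker

Screening mitochondrial core protein-coding genes as DNA barcode
markers for fungal genera — an R package plus a reproducible analysis
workflow.

## What it does and for whom

Mycologists comparing strains within a genus (medicinal *Ganoderma*-like
groups being the motivating case) need a short, standardized gene whose
sequence alone separates species the same way whole-mitogenome evidence
does. Fungal mitogenomes share 15 core protein-coding genes (atp6,
atp8, atp9, cob, cox1–3, nad1–6, nad4L, rps3) and two intron-bearing
rRNAs (rrnL, rrnS); only some of them make usable barcodes. This
package implements the full screen:

- parse annotated mitogenomes (GenBank flat files) and extract named
  genes, strand-resolved, with synonym-aware symbol normalization;
- align genes natively (Needleman–Wunsch with affine gaps; progressive
  profile MSA over an NJ guide tree when lengths differ) and count
  SNPs/InDels with `ref→alt at N` position labels;
- build per-gene and concatenated-supermatrix neighbor-joining trees
  (Saitou–Nei, p-distance, deterministic tie-breaking) and compare them
  by Robinson–Foulds distance;
- score each candidate gene: a marker is **selected** iff its gene tree
  is topologically identical to the 15-gene reference tree (RF = 0), it
  carries ≥ 1 clade-diagnostic site, its annotated length is stable
  across records, and its median length is ≤ 300 bp; genes fail as
  `excluded_length_unstable` (intron-bearing rRNAs),
  `excluded_too_long_variable` (InDel-laden/hypervariable), or
  `excluded_insufficient_resolution` (discordant tree or no variation);
- group taxa into zero-SNP clades over the selected markers, report
  each clade's SNPs against a chosen barcode standard, and render the
  standard's markers as four-color barcodes (A green, T red, G black,
  C blue) with FASTA-shaped QR payloads;
- simulate annotated mitogenome collections with known ground truth
  (true tree, complete mutation log, planted diagnostic sites,
  synonymous-only mode, rRNA introns) so the whole pipeline is testable
  offline.

## The statistic at the core

For gene *g* with alignment *A_g* over taxa *S*, p-distances
*d_ij = (mismatching comparable sites)/(comparable sites)* feed
Saitou–Nei neighbor joining; the reference tree *T\** comes from the
concatenation of all 15 core-gene alignments. The marker score is the
tuple (RF(*T_g*, *T\**), diagnostic-site count, length stability,
median length), with RF the size of the symmetric difference of
nontrivial bipartition sets of the unrooted trees. Clades are the
connected components of the zero-SNP relation over both selected
markers jointly.

## Worked example

The analysis scripts build a 12-taxon, 4-clade synthetic genus with all
17 genes, clade-diagnostic substitutions planted in the informative
genes, a hypervariable nad5, intron-bearing rRNAs, and an untouched
atp8 as zero-variation control:

```sh
Rscript analysis/01_simulate_collection.R
Rscript analysis/02_screen_markers.R
Rscript analysis/03_diagnostic_snps.R
Rscript analysis/04_barcodes.R
```

`02_screen_markers.R` prints the ranked verdict table (abridged):

```
  gene median_length_bp rf_vs_reference interspecies_diagnostic_sites verdict
  atp9              222               0                             3 selected
 nad4l              267               0                             3 selected
  nad3              360               0                             3 candidate
  ...
  cox1             1587               0                             3 candidate
  atp8              159               2                             0 excluded_insufficient_resolution
  nad5             1983              NA                            NA excluded_too_long_variable
  rrns             2028              NA                            NA excluded_length_unstable
  rrnl             2671              NA                            NA excluded_length_unstable

selected markers: atp9, nad4l
```

Only the two short, length-stable, tree-concordant, diagnostic genes
are selected; the medium and long concordant genes are graded
`candidate` (reliable for phylogenetics, too long for a barcode), and
the three exclusion rules each fire on their intended target.
`03_diagnostic_snps.R` then reports the per-clade SNPs against the
barcode standard:

```
barcode standard: SIM0009.1 (clade 1)
4 clades over markers atp9+nad4l
clade 1 (3 taxa): identical to standard
clade 2 (3 taxa): A→C at 211 | C→A at 254
clade 3 (3 taxa): C→A at 111 | C→A at 134
clade 4 (3 taxa): C→A at 11; C→A at 111 | C→A at 13; C→A at 134
```

— the SNP load grows with divergence from the standard's clade, the
gradient that makes these markers informative. `04_barcodes.R` writes
`results/barcode_atp9.svg` (222 bars × 3 px), its PNG twin, verifies
each image by decoding it back to the exact sequence, and emits the QR
payload text (`>SIM0009.1|Fungus syntheticus SIM0009|atp9` + sequence).

Everything above is also available as one call:

```r
library(mitomarker)
manifest <- run_pipeline(run_config(mode = "genbank_dir",
                                    input_dir = "results/data"),
                         out_dir = "results/run")
```

which writes `marker_scores.tsv`, `clades.tsv`, per-gene `*.nwk`,
barcodes, a log with every exclusion reason, and a checksummed
`manifest.json` (byte-identical across reruns at a fixed seed).

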