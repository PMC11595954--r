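---
title: "Screening mitochondrial core genes as DNA barcode markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitochondrial core genes as DNA barcode markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fungal mitochondrial genomes carry a conserved set of 15 core
protein-coding genes (atp6, atp8, atp9, cob, cox1–cox3, nad1–nad6,
nad4L, rps3) plus the two rRNA genes (rrnL, rrnS). Within a genus these
genes are short, nearly identical in length across species, and carry
only a handful of substitutions — which makes some of them attractive as
DNA barcodes: short standardized regions whose sequence alone
discriminates species. The question this package operationalizes is
*which* core gene to use. A good barcode must (1) place every sample in
the same clade that the full mitogenome signal does, (2) actually carry
species-diagnostic variation, (3) be short enough to amplify, sequence
by routine Sanger reads, and render as a compact visual barcode, and
(4) have a stable annotated length across records, so that alignment
and position-based SNP reporting stay trivial.

`mitomarker` implements that screen end to end: GenBank parsing and
gene extraction, native pairwise and progressive multiple alignment,
p-distance matrices, Saitou–Nei neighbor joining, Robinson–Foulds
topology comparison, the marker scoring rules, zero-SNP clade
assignment with per-clade SNP reports against a barcode standard, and
four-color barcode rendering — plus a sequence-evolution simulator so
that every stage is testable offline against known ground truth.

## The screening procedure

For a collection of annotated mitogenomes the screen proceeds as
follows.

1. **Reference tree.** Every record containing all 15 core genes is
   retained (others are dropped with a logged message). Per-gene
   alignments are concatenated into a supermatrix and a
   neighbor-joining tree is built on p-distances. This tree is the
   yardstick: it summarizes the joint signal of ~15 kb of coding
   sequence.
2. **Per-gene scoring.** Each candidate (15 core genes + 2 rRNAs) gets
   a score row:
   - *rRNA exclusion.* rrnL and rrnS are excluded whenever their
     annotated lengths differ between records or any record lacks the
     annotation. In this genus group the rRNAs carry one to four
     introns whose presence varies by strain, so their lengths are
     inherently unstable, and incomplete rRNA annotations are common.
   - *InDel/hypervariability exclusion.* A protein-coding gene whose
     alignment contains any gap column (default threshold 0), or whose
     variable-column fraction exceeds 10%, is excluded as too long and
     variable to serve as a stable barcode. The threshold is a config
     knob because the underlying judgment ("long sequence and numerous
     SNP/InDel sites") is qualitative; 10% is far above the within-genus
     divergence of usable markers (which sit near 1–3%) and far below
     hypervariable load.
   - *Concordance.* The single-gene NJ tree must equal the reference
     tree exactly (Robinson–Foulds distance 0). Tree agreement was
     historically judged by eye; exact topological identity is the
     strictest faithful operationalization, and with deterministic
     tie-breaking (below) it is reproducible.
   - *Diagnostic variation.* At least one alignment column must be
     fixed within every zero-distance group of the concatenated
     alignment and different between at least two groups. A gene with
     zero variation can never be selected no matter how concordant its
     (star-like) tree is.
   - *Length.* Selected barcodes must have median length at or below
     300 bp (config), which keeps the three short candidates (159, 222,
     267 bp) in range and every medium or long gene out. Concordant,
     diagnostic genes above the cap are graded `candidate` — reliable
     phylogenetic markers, but not recommended as barcodes.
3. **Clades and SNP reports.** Taxa are grouped into *clades* defined
   as maximal sets with zero pairwise SNPs in **both** selected
   markers (connected components, so an ambiguous base cannot split a
   clade). One representative per clade is aligned to the barcode
   standard and SNPs are reported as `ref→alt at N`, 1-based on the
   standard's ungapped sequence.
4. **Barcodes.** The standard's marker sequences are rendered as
   four-color barcodes (A = green, T = red, G = black, C = blue, one
   vertical bar per base in sequence order) as SVG (canonical) and PNG,
   with a decoder used to verify every rendering. The companion QR
   payload is a single FASTA entry, `>accession|organism|gene` plus the
   sequence; rendering the QR image itself is delegated to any standard
   QR encoder, since the payload text is the contract.

Species labels are carried through all reports as metadata but never
used by any algorithm: collections genuinely contain mislabeled
strains, and the clade structure must be free to contradict the labels.

## Alignment model and scoring

Pairwise alignment is global Needleman–Wunsch with affine gaps (Gotoh's
three-state recursion), implemented in C++ for speed. A gap run of
length L costs `gap_open + L·gap_extend`. Defaults: match +2,
mismatch −1, gap open −1, gap extend −1.

These values resolve a genuine tension. When two low-divergence genes
from different genera are compared, a window of two adjacent mismatches
often admits an alternative reading as two single-base InDels with an
extra match (the classic `ATAT-TA` vs `AT-TCTA` presentation of the
sequences ATATTA/ATTCTA). Any scoring that makes the InDel reading
*strictly* better also gaps every transposed-mismatch pair in long
alignments — the two situations are structurally identical — littering
substitution-only data with spurious indels and breaking the guarantee
that SNP counts equal true substitution counts when no indels occurred.
The chosen defaults make the two readings exactly co-optimal: the InDel
presentation achieves the optimal score (checkable with
`alignment_score()`), while the deterministic traceback — prefer
diagonal, then a gap in the second sequence, then the first — reports
the substitution reading and never invents gaps. All outputs are
bit-reproducible.

Multiple alignment takes a fast exact path when all inputs are
equal-length and the ungapped column stack already achieves the optimal
pairwise score for every pair — the common case for core genes, whose
lengths are identical across a genus. Optimality is *decided*, not
assumed: an alignment using G gap bases per row can score at most
`(L−G)·match + 2(gap_open + G·gap_extend)`, which caps the gap budget
any improving alignment could use as a function of the pair's mismatch
count; a banded affine search over exactly that budget settles the
question. Otherwise sequences are aligned progressively: an NJ guide
tree over k-mer distances (k = 4), profiles merged post-order with
affine-gap profile–profile alignment (column pairs score the average
substitution score; gaps and N are neutral).

Columns with N in either row are excluded from SNP counts and tallied
separately as ambiguous. Gap runs at alignment termini count toward
InDel sites and gap bases — end-inclusive counting matches how total
"gap bases" are reported for cross-genus comparisons.

## Trees

Distances default to the p-distance (proportion of differing comparable
sites, pairwise deletion). Within a genus the divergence involved is a
handful of substitutions per gene, where every substitution model
collapses onto the p-distance; Jukes–Cantor is available
(`model = "jc"`) for deeper comparisons. Neighbor joining is the
Saitou–Nei agglomeration with two fixed rules: negative branch-length
estimates are clamped to zero, and ties in the Q criterion join the
pair whose representative labels (the lexicographically smallest leaf
of each subtree) sort first. Tie-breaking matters here more than in
most NJ applications because identical within-clade sequences produce
exactly tied Q values; the lexicographic rule makes every tree of every
gene resolve those ties the same way, which is what lets "Robinson–
Foulds = 0 against the reference" be a meaningful criterion for
zero-distance leaf groups. Trees are compared unrooted via nontrivial
bipartition sets; the normalized form divides by 2(n−3).

## The simulator and what it does (not) show

`simulate_collection()` evolves each configured gene independently
along a shared true tree under a continuous-time Jukes–Cantor process:
per branch, a Poisson number of substitution events (rate × sites ×
branch length), each at a uniform site to a uniform different base.
Gene defaults are the conserved core-gene lengths (atp9 222 bp, nad4L
267 bp, atp8 159 bp, nad5 1983 bp, …). Every event is logged, and
replaying the log from the root sequences reproduces every leaf exactly
— the anchor for planted-truth tests. Optional features:

- *Synonymous-only mode* restricts proposals to amino-acid-preserving
  changes under the configured genetic code (default NCBI table 4,
  mold mitochondrial — the conventional fungal mitochondrial code; the
  printed products, 73 aa for a 222 bp CDS and 88 aa for a 267 bp CDS,
  are the same under tables 1 and 4 for these genes). This emulates the
  striking real phenomenon of cross-genus marker pairs with ~20
  nucleotide SNPs and byte-identical proteins.
- *Per-gene InDel events* (length 1–3, insertion/deletion equally
  likely) for the InDel-laden-gene exclusion scenario.
- *rRNA introns*: each taxon's rRNA genes receive 1–4 introns (counts
  and lengths configurable), so annotated rRNA lengths vary between
  taxa as they do in real strain collections.
- *Clade structure*: `clade_tree()` builds a ladder of clades with
  near-zero within-clade branch lengths, the pattern of a genus where
  conspecific strains are identical at these markers;
  `plant_diagnostics()` overwrites chosen bases clade-wide so that
  diagnostic sites exist at known positions (e.g. the A→G at atp9
  position 69 used as the canonical fixture).

Default study conditions: random bifurcating topologies with uniform
(0.1–0.5) branch lengths, substitution rate 0.01 per site per unit
branch length — which yields the one-to-six substitutions per short
gene that motivate the whole enterprise — genome GC target 27%,
intergenic spacers of 100–400 bp, genes on both strands, circular
genomes emitted through the same GenBank writer/parser pair as real
records.

What passing simulations do **not** show: the generator plants no
rearrangements, no duplicated tRNAs, no homing endonuclease ORFs, no
annotation errors beyond missing genes, and its intron model is a
uniform insertion, not a homology-aware one. Conclusions about real
collections still require the accession-dependent checks on deposited
records, which are deliberately outside the default offline test suite.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive at every interface (GenBank
  convention); strand-resolved sequences are extracted at parse time.
- GC content excludes N from numerator and denominator and refuses
  empty or all-N input.
- `translate_cds()` in complete mode demands one terminal stop and
  reports the codon index of any premature stop; length not divisible
  by three is a frame error, not a warning.
- NJ requires ≥ 3 taxa; a pair with zero comparable columns is an
  error naming the pair; Jukes–Cantor refuses p ≥ 0.75.
- Zero-distance taxa are kept as distinct leaves, never collapsed;
  clade grouping happens downstream and is reported, not imposed.
- Barcode decoding requires solid single-color bars within a
  per-channel tolerance of 0.2 of a palette color; a single corrupted
  pixel is an error naming the pixel column.
- The simulator has no fixed genome length: genomes are assembled from
  genes plus spacers, so gene packing is always feasible by
  construction.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path repeatedly: exhaustive
alignment enumeration up to length 6, all unrooted binary topologies to
6 leaves, 100 random additive matrices for NJ consistency, 50
nine-taxon 15-gene collections for concatenated-tree recovery, and
single collections up to 52 taxa for clade assignment. The analysis
scripts use a 12-taxon, 4-clade collection with all 17 genes.

## Known limitations

- "Concordance" is exact topological identity; near-misses (one
  rotated shallow node) are excluded rather than scored on a gradient.
- The hypervariability threshold (10% variable columns) and the
  barcode length cap (300 bp) encode qualitative judgments as numbers;
  both are config fields, and different choices move borderline genes
  between `candidate` and excluded verdicts.
- The progressive MSA is a plain profile aligner — adequate for genes
  differing by a few short indels or introns, not a replacement for a
  dedicated aligner on deeply diverged rRNAs.
- Whether the deposited records' own annotation idiosyncrasies
  (joined features, nonstandard gene symbols beyond the shipped synonym
  table) parse cleanly can only be verified against those records.
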