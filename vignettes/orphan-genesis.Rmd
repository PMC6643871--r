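---
title: "Classifying orphan genes and diagnosing their origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying orphan genes and diagnosing their origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylorphan` studies how new genes arise in a clade with a ladder-like
phylogeny around one focal species. This vignette is the package's account
of the underlying models and the design decisions behind them; the README
shows the worked example.

## The classification model

Homology is operationalised as a local alignment whose Karlin–Altschul
E-value clears a threshold. The engine computes exact Smith–Waterman
affine-gap optima (BLOSUM62 with gap costs 11 + k for proteins, +2/−3 with
gaps 5 + 2k for nucleotides) and converts a raw score *S* to

E = K · m · n · exp(−λS),

with the published gapped constants (λ = 0.267, K = 0.041 for BLOSUM62;
λ = 0.625, K = 0.41 for +2/−3), query length *m* and total database length
*n*. Two deliberate simplifications: no effective-length correction (the
package operates at desk scale, where the correction is small and its
omission keeps E-values reproducible from the formula), and an optional
exact-word seed (3 aa / 11 nt) that only prunes query–subject pairs and
never alters a reported score. Low-complexity masking exists but is off by
default: the classification cascade runs unfiltered, so repeat-rich
proteins are searched as-is.

The cascade is strict: a gene is tested against the outgroup genomes
(translated, E ≤ 10⁻⁵) only if it failed against the outgroup proteins
(E ≤ 10⁻³), and against the curated database (E ≤ 10⁻³) only after both;
step-3 survivors are flagged horizontal-transfer candidates rather than
removed. All thresholds are inclusive. Orphans are split into
taxon-restricted and species-specific classes by *protein* homology only —
a translated hit against a sister genome may be a pseudogene or a chance
open frame, so it deliberately does not count. Outgroup genomes are
searched unmasked, consistent with running the cascade unfiltered.

Phylostrata follow the parsimony argument that a gene shared with a more
distant relative is older: the stratum of an orphan is the ladder index of
the most distant hit-bearing ingroup species (1 = sister), species-specific
orphans form stratum 0, and conserved genes sit beyond the ingroup. Hits
are aggregated at the gene level (any isoform counts for the gene), and
self or within-species paralog hits never affect the class.

## Noise-aware relaxed searches

An E-value threshold of 10 admits, by construction, roughly ten random
hits per search — the expected maximum random score in a search space of
size m·n is ln(K·m·n)/λ. Measured on random 50-aa queries against six-frame
80-kb genomes, maxima of 35–47 (raw E 0.5–14) appear in every search. Two
consequences for automation:

* The trace-matrix genome cell uses the translated search at E ≤ 10⁻⁵ (the
  cascade's own genome-level threshold). At E < 10 every gene, including
  genuinely untraceable ones, would show spurious genomic traces.
* The mechanism detectors keep a relaxed threshold (`e_relaxed = 10`) but
  additionally require the raw score to exceed ln(K·m·n)/λ by
  `noise_margin` (default 15, an effective per-search false-hit rate of
  about 2%). Weak-confidence calls therefore come from structural
  conditions — a missing complementary neighbor, a closed alternative
  frame, a single alignable sister, unknown transcription evidence — not
  from marginal E-values, which an automated caller cannot distinguish
  from noise.

## Gene-structure validation

Spliced read support is counted per coding exon and per junction: a read
supports an exon when one of its aligned blocks covers at least 80% of the
exon's coding span or when the read's splice junction matches one of the
exon's boundaries exactly (junction reads support both flanking exons);
junctions accept no tolerance, since splice sites are base-precise and a
shifted edge indicates a different isoform. Full confirmation needs two
supporting reads for every coding exon and every junction — read here as
*per junction*, the stricter reading of "spliced reads straddling such
exons". With strand-specific data, two or more supporting reads on the
wrong strand cap the status at partially confirmed.

Single-exon genes are excluded from validation. The exclusion keys on the
total exon count, not the coding exon count: a multi-exon gene whose entire
coding sequence sits in one exon still has verifiable splice junctions, and
the intergenic de novo exemplar has exactly this architecture. An empty
read set yields an unconfirmed status with zeroed counts, not an error.

The high-confidence candidate set is the intersection of traceable (not
untraceable — an untraceable locus offers nothing to investigate) and fully
confirmed species-specific orphans.

## Origin-mechanism detectors

Detectors run in a fixed priority order — artifact screen (a re-run
structure validation), heuristic-failure rescue, overprinting, chimera,
gene split, strand switch, frame shift, de novo — and the first supported
call wins, with modifiers preserved. Artifacts and search failures must be
excluded before any evolutionary claim, and divergence-based calls, which
retain ancestral frame or strand evidence, outrank de novo; that ordering
implements a conservative stance toward de novo birth.

Design notes per detector:

* **Chimera** searches each coding exon's peptide separately (per-species
  protein databases, relaxed + noise gate) and fires only when two or more
  exons match *distinct* source genes, no single source matches more than
  one exon, and the summed per-exon scores beat the best single
  whole-protein hit by a margin of 10 — a raw coverage test is unreliable
  because a local alignment can drag a weak gapped shoulder beyond its
  true exon. The physical distance between the sources is reported but
  does not gate the call.
* **Gene split** requires a nucleotide-level match of the candidate to a
  prefix or suffix (< 80% coverage) of an annotated gene in the orthologous
  sister region, plus an adjacent focal gene covering the complementary
  part of that protein (absent neighbor: weak call). Exons with no homology
  gain a `de-novo-exon` modifier; a multi-frame alignment of the shared
  exon gains `frame-shift`.
* **Frame shift** assigns each protein position to one of the three
  same-strand frames of the orthologous coding sequence with a small-state
  dynamic program (moves of +3 nucleotides keep the frame, +2/+4 switch it
  at a penalty of 8), reporting switch points and implicated indel lengths
  in 1-based codon units.
* **Strand switch** fires only when a gated translated hit overlaps an
  annotated CDS exon on the strand opposite to that gene's coding strand;
  antisense matches to introns or intergenic sequence do not qualify (they
  are the signature of de novo birth inside a host intron, not of an
  antisense-recycled exon).
* **Overprinting** needs a plus-strand within-species transcript paralog
  (E ≤ 10⁻³) whose annotated ORF runs in a different same-strand frame,
  with the candidate's frame open in both copies; a stop closing that frame
  in the paralog downgrades the call to weak.
* **Heuristic-failure rescue** re-runs a full, unseeded translated
  alignment restricted to the syntenic interval, repeats retained. The
  desk-scale mechanism is explicit in the E-value formula: the same raw
  score that is insignificant against a whole genome (large n) clears the
  threshold inside a few-kilobase interval. The in-interval hit must cover
  at least half of the candidate protein — a fragment match is evidence of
  a split, not of a missed full-length homolog — and nothing comparable may
  exist genome-wide. Success reclassifies the gene as taxon-restricted; the
  final classification table records both the cascade class and the
  post-rescue class, and the class partition remains exhaustive.
* **De novo** extracts the candidate's reading frame from each orthologous
  region by per-exon nucleotide alignment and reports each species as
  intact, disrupted (stop positions in 1-based codon units), or
  unalignable. It fires when at least one species is disrupted or
  unalignable while the region aligns somewhere in the ingroup and the
  alignable regions show no transcription evidence (a transcriptome or read
  signal vetoes the call; a missing database makes evidence unknown and
  caps confidence). The birth node is the most recent common ancestor of
  the intact-ORF species; the intronic/intergenic subtype comes from the
  focal annotation context. Orthologous regions come from synteny anchors
  (best-reciprocal protein hits chained by longest increasing subsequence,
  ≥ 3 anchors per block) or, for candidates inside another gene's intron,
  from the host ortholog's corresponding intron.

## Selection analysis

Candidate ORFs and their extracted orthologous frames (in-frame stops
included, as extracted) are globally aligned (center-star progressive
alignment under BLOSUM62, lexicographic tie-break so input order is
irrelevant) and back-translated to codons. In-frame stops cannot enter a
codon substitution model, so they are masked as missing data with their
positions recorded — the stop evidence is preserved in the report while the
likelihood stays well-defined.

The model is MG94×HKY with F1x4 codon frequencies estimated from the
alignment. κ and branch lengths are estimated jointly by maximum
likelihood; the species-tree topology is fixed but branch lengths are
re-estimated because lengths in substitutions/site are the wrong scale for
a codon model. With a single sister sequence one ω is shared across the
tree; with more, each branch gets its own ω. The null hypothesis of the
likelihood-ratio test is neutrality (ω = 1) on the tested branches — the
natural reference when asking whether an ω estimate is meaningful — with
df = the number of freed ω parameters and significance at p < 0.05.

Numerical choices: transition probabilities come from the symmetric
eigendecomposition of the reversible rate matrix (the matrix is scaled to
one expected substitution per codon per unit branch length); optimisation
is bounded L-BFGS-B on log-parameters (bounds e⁻⁴…50), two starts (ω = 0.5
and 2) in single-ω mode and one start (ω = 0.8) in per-branch mode, where
the parameter count makes restarts expensive; alignments with fewer than 20
usable codon columns, fewer than two taxa, or zero substitutions return a
typed insufficient-data result rather than an unidentifiable estimate. The
NG86 pathway-counting estimator (paths through stop codons excluded,
Jukes–Cantor correction, ω undefined at dS = 0) is kept as an independent
sanity check on the direction of selection.

## What the simulator emulates — and what it does not

`simulate_dataset()` builds a ten-species ladder (all branches 0.03
substitutions/site) of one-contig genomes: conserved families born at the
root (with outgroup copies at 0.12 extra divergence; a few families are
visible only in the outgroup genome or only in the curated database, to
exercise cascade steps 2 and 3), taxon-restricted families born at every
internal node, species-specific orphans, and one exemplar of each origin
mechanism plus an assembly-gap trace exemplar. Genes are 2–4 exons with
coding exons of 60–93 bp (so a 75-bp read can cover 80% of a coding span),
60-bp UTR padding (so tiled reads reach full depth over terminal coding
bases), GT..AG introns of 47–61 bp, and stranded 75-bp reads tiled to at
least 5× coverage of every focal coding base.

Sequence evolution is an HKY-biased per-site substitution process (κ = 2)
with acceptance–rejection that keeps protected reading frames open —
coding frames for genes, both frames for the dual-ORF overprinting family —
plus geometric indels in intergenic sequence only. Divergence of the
planted mechanism exemplars is tuned by bounded rejection sampling into
explicit detectability windows derived from the E-value formula: strong
enough for the targeted search (per-exon, in-interval, antisense) to find,
weak enough that the genome-wide protein cascade does not. For example, the
chimera's exon pieces are diverged nonsynonymously (first two codon
positions) so the protein score falls below the cascade threshold while
third positions keep the nucleotide trace alive. The generator then
verifies all planted contracts — orphans invisible at the cascade
thresholds, taxon-restricted genes detectable exactly up to their birth
node, untraceable genes silent in all three databases — with the package's
own engine and redraws offending random genes, so the ground truth holds by
construction for any seed.

The simulator does not model sequencing error, paired-end fragments, codon
usage, rate heterogeneity across sites, gene loss, rearrangements, or
assembly artifacts beyond the single planted assembly-gap exemplar; reads
are emitted pre-aligned (SAM) because structure validation operates on
alignments. Passing tests therefore demonstrate that the pipeline's logic
recovers planted signals under clean conditions, not that the thresholds
are optimal for any particular real clade.

## Reference parameters and problem sizes

The pipeline defaults are the reference configuration: cascade thresholds
10⁻³ / 10⁻⁵ / 10⁻³, ingroup protein threshold 10⁻³, read support 2 with 80%
exon overlap, relaxed detector threshold 10 with noise margin 15, LRT at
p < 0.05. Every threshold used is written to `log.txt`, and all outputs are
byte-deterministic given a seed.

The shipped test suite runs the full default dataset (10 species, 65
conserved families, 790 genes) once and a reduced configuration (30
conserved families) for the double-execution determinism check; the
selection calibration uses 500-codon pairwise alignments for ω recovery,
200 replicates of 300 codons for the neutral rejection rate, and 40 mutated
pairs for the NG86 concordance check. These sizes are the package's chosen
study conditions and are shared by `scripts/acceptance.R`.

## Known limitations

* E-values use raw m·n; against databases of real-genome scale they will be
  conservative relative to BLAST's corrected statistics, and the engine is
  quadratic — for real genomes, import external tabular results through
  `read_outfmt6()` and keep the engine for the targeted searches.
* The center-star aligner is adequate for the few closely related
  sequences a selection analysis uses, not a general MSA tool.
* Orthologous-region extraction assumes collinear, indel-light regions;
  large rearrangements inside a region defeat the per-exon block mapping.
* Mechanism confidence is rule-based; it encodes the structural
  corroboration described above, not a calibrated posterior.
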