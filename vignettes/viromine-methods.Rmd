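---
title: "viromine: methods and design notes"
author: "viromine maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{viromine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`viromine` is a desk-scale, fully testable reimplementation of a gut-virome
analysis workflow for pooled fecal sequencing libraries: cleaning of raw
reads, greedy overlap assembly, translated homology triage against a viral
proteome database with a competitive non-virus filter and a profile
fallback, community ecology of the resulting abundance tables, hallmark-gene
annotation and phylogenetics, and quantification of phage-encoded
antibiotic-resistance genes (ARGs) and functional genes. This vignette
explains the models and algorithms, the tunable parameters, what the
synthetic-community generator does and does not emulate, and the design
decisions taken where the underlying procedure left genuine freedom.

## The synthetic community

`simulateVirome()` generates everything the pipeline consumes, with a
ground-truth manifest of every read's origin. Its defaults are the study
conditions the package targets:

* **Six virome libraries plus a blank control.** Libraries are named
  `species_site` for two lizard host species (PE, PT) across Qinghai–Tibet
  Plateau sites; `groupLabels` carries the host-species factor used by
  ANOSIM and the ARG exclusivity analysis. The blank control draws a small
  number of reads (default 60) from the cellular background only.
* **Family panel.** Tailed dsDNA phages (Siphoviridae, Myoviridae,
  Podoviridae, and Ackermannviridae restricted to PT libraries), the ssDNA
  phage family Microviridae, Parvoviridae (parvo-rich in the PE_NMC
  library), two CRESS DNA virus families, two RNA virus families (emitted as
  cDNA; no U anywhere), and a bacterial/host background that accounts for
  roughly half of each library. Each viral category carries its hallmark
  marker gene: TerL (Caudovirales), MCP (Microviridae), NS1 (Parvoviridae),
  Rep (CRESS), RdRp (Riboviria).
* **Gene-dense genomes.** Every genome is laid down as
  spacer | in-frame stop pad | `ATG`…stop-free codon body…stop | spacer, so
  each planted ORF's coordinates are exact ground truth and every ORF
  predictor segment starts at the planted `ATG`. Viral genomes embed exactly
  one hallmark ORF plus backbone genes; tailed-phage genomes additionally
  carry planted ARGs (thirteen "core" genes spread over the three ubiquitous
  families, five genes only in the PT-restricted family) and auxiliary
  metabolic genes. Bacterial genomes carry their own ARGs — these must never
  surface in phage ARG tables — and one phage genome carries mutated copies
  of bacterial genes (prophage-like decoys) to exercise the competitive
  filter in the reverse direction.
* **Reads.** 250-nt mate pairs from fragments of 400 ± 50 nt, opposite
  strands; downstream stages treat mates independently. Per-position Phred
  means decay linearly (36 at cycle 1 to 24 at cycle 250, sd 3) and
  substitution errors are drawn at the rate the qualities imply, so quality
  trimming and the 95%-identity mapping thresholds act on realistic data.
  A configurable fraction of reads (default 5%) has Nextera adapter
  read-through at the 3' end, and `duplicateRate` (default 10%) of each
  library's reads are re-emitted as exact full-length copies
  (`partialDuplicates = TRUE` restricts the identity to bases 5–55 to
  stress the positional rule).
* **Databases.** The viral proteome database holds the translation of every
  viral ORF with its lineage; the non-virus non-redundant (NVNR) database
  holds all bacterial/host proteins plus a controlled fraction (default
  20%) of decoy homologs of viral proteins; the ARG and functional-gene
  catalogues hold canonical proteins with drug class/mechanism and pathway
  metadata. Genome copies of catalogue genes diverge from the canonical
  sequence (92% identity), as horizontally transferred genes do — this is
  what lets the competitive filter separate a bacterial ARG read (exact
  NVNR hit) from a phage-borne copy.

Mock protein sequences are sampled from the Robinson–Robinson background
frequencies that the gapped BLOSUM62 Karlin–Altschul constants assume, which
keeps null E-values interpretable.

What the simulator does **not** emulate: realistic Illumina error profiles
(substitutions only, no indels), barcode demultiplexing, strand-specific
library artifacts, within-species population variation, and genome sizes
(kilobases rather than the tens-to-hundreds of kilobases of real phage and
host genomes). Passing recovery tests on this community therefore
demonstrates the correctness of the pipeline's logic and statistics at desk
scale, not its performance on a real 86-million-read survey.

## Read cleaning

Reads are duplicates when bases 5–55 (1-based, inclusive; a 51-nt key) are
identical; identical keys are grouped transitively and one uniformly random
member survives, under the pipeline seed. Reads shorter than 55 nt are keyed
on bases 5 to their end — the window rule is silent about short reads, and
this grouping is conservative and never indexes past the read.

Quality tails are trimmed at Phred threshold 10 with the standard
suffix-maximization rule: remove the 3' suffix maximizing
$\sum_i (10 - q_i)$. Adapters are found by an ungapped local scan
(+1 match / −3 mismatch, both strands, all offsets); a best score of at
least 16 — the weak-match analog of VecScreen's terminal threshold —
truncates the read at the match start when the match lies in the 3' half and
masks the span with N otherwise. Reads shorter than 50 nt after trimming are
dropped. The cleaning report reconciles exactly:
input − duplicates − dropped = output.

## Greedy assembly

`greedyAssemble()` repeatedly merges the pair of sequences (either
orientation, head-to-head joins included) with the highest-scoring
suffix–prefix overlap of ≥ 35 nt at ≥ 98% identity, scoring overlaps by
matching bases, breaking ties lexicographically by sequence id, until no
merge qualifies; leftovers are singlets. Candidate overlaps are anchored on
an exact 12-mer of the right sequence's prefix hashed against all suffixes —
an overlap whose first 12 bases all differ is invisible, a deliberate
desk-scale trade-off that is exact for error-free reads. Mismatches within
an overlap keep the extending sequence's base (majority of two). Chimeras
are flagged when a contig's 5'-half and 3'-half best hits belong to
different families with non-overlapping spans, both below the E-value
cutoff; this split-hit rule is a stand-in aimed exactly at the artifact
class greedy merging can create.

## Translated homology triage

The discovery logic is a seeded protein local aligner plus Karlin–Altschul
statistics:

1. **Six-frame translation** under the standard code (stops as `*`, fuzzy
   codons as X, no initiator-codon special-casing).
2. **Seeding.** 3-mer words expanded to a BLOSUM62 neighbourhood at word
   score ≥ 11; two non-overlapping word hits within 40 diagonals trigger an
   ungapped X-drop extension; extensions with raw score ≥ 38 shortlist the
   query/subject pair.
3. **Gapped alignment.** Full affine Smith–Waterman (BLOSUM62, gap open 11,
   extend 1) with traceback on shortlisted pairs.
4. **Statistics.** Bits $S' = (\lambda S - \ln K)/\ln 2$ with the published
   gapped BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$, and
   $E = m\,n\,2^{-S'}$ with $m$ the query frame length (aa) and $n$ the
   total database residues. Hits with $E < 10^{-5}$ are reported.

These fixed constants make E-values reproducible bit-for-bit, at a price:
for short translated reads the formula is conservative (stop codons litter
five of six frames, and no effective-length correction is applied), so the
measured null hit rate sits well *below* the asymptotic expectation — the
same direction real translated searches err for short queries. The
acceptance checks therefore bound the null rate from above at the stated
cutoff and verify two-sided order-of-magnitude agreement on stop-free
protein nulls at a depth where counting statistics exist.

**Competitive filter.** Queries with viral hits are searched against the
NVNR database; the viral assignment is discarded when the best NVNR bit
score strictly exceeds the best viral bit score. Ties favour the viral
assignment — the standard competitive-filter reading; `removeOnAnyHit`
switches to the stricter "any NVNR hit removes" variant for users who want
it.

**Profile fallback.** Contigs left unassigned are scanned in six frames
against per-hallmark position-specific score matrices (log-odds of observed
column frequencies over background). Windows may overlap the profile
partially; scores are compared per column so windows of different coverage
are commensurable, a reported window must cover at least 60% of the
profile, and the threshold is calibrated as the 1st percentile of a
true-positive panel built by degrading the hallmark instances down to 35%
identity. Calibrating on undegraded self-scores would be useless — log-odds
scores of 35%-identity homologs sit hundreds of bits below any self-score —
so the panel construction is what preserves the fallback's remote-homology
role while keeping the random-sequence false-positive rate near zero.
Profile hits map to placeholder lineage rows ("unclassified …"), as
profile-level evidence cannot support a species call. The fallback is
applied to contigs, not to singlet reads, matching the workflow it
reimplements.

**Counting.** The species of a query is its best hit's species (ties broken
by higher identity, then lexicographic subject id); a contig contributes its
member-read count, a singlet contributes 1. Tabulation produces the
libraries × taxa `AbundanceMatrix` underlying all ecology outputs, with
optional row normalization for percentage tables.

## Community ecology

Bray–Curtis dissimilarity ($d = 1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i +
y_i)$, via vegan), UPGMA (average-linkage; ultrametric heights at half the
cluster distance), principal-coordinate analysis (Gower double-centering,
eigendecomposition, positive axes scaled by $\sqrt{\lambda}$, negative
eigenvalues reported and dropped without correction, axis signs fixed by
making the first non-negligible loading positive), and shared-species
accounting over all observed library subsets with per-group exclusives. The
presence threshold for "species identified in a virome" is ≥ 1 assigned
read.

ANOSIM is implemented in-package because its contract here is specific: the
rank-based statistic $R = (\bar r_B - \bar r_W)/(M/2)$ over all
$M = n(n-1)/2$ pairwise distances, label permutations drawn with a caller
seed, and $p = (1 + \#\{R^* \ge R\})/(1 + n_{perm})$. (The vegan
implementation, used as an independent cross-check in the tests, switches to
complete enumeration for small designs and would not honour the sampling
contract.) A sobering arithmetic fact documented here because it shapes
validation: with two groups of three, 2 of the 20 distinct label
arrangements preserve the partition and always tie the observed statistic,
so the permutation p-value is floored near 0.1 — no effect size whatsoever
can reach $p \le 0.05$ at n = 3+3. Size is therefore validated at n = 6+6
(where rejection at 5% is attainable) and power at n = 3+3 is reported both
at the nominal 5% level (where it is structurally zero) and at the
attainable 15% level.

## Annotation and phylogenetics

ORFs are predicted in all six frames: within each stop-delimited frame
segment, the ORF runs from the first `ATG` (so nested starts sharing a stop
are suppressed, matching common predictor behaviour) to the stop, with
minimum size 300 nt *including* the stop codon — the usual gene-predictor
convention; `unit = "aa"` switches to the amino-acid reading. ORFs hitting a
contig edge without a stop are reported with `has_stop = FALSE`. Hallmark
calls take the best profile at or above threshold; a call is a complete CDS
only with start, stop and ≥ 90% profile coverage, the guard that keeps
fragments from being selected for phylogenetics.

Multiple alignment is progressive: a 3-mer-distance UPGMA guide tree, then
profile–profile merging by global affine alignment (BLOSUM62 11/1, terminal
gaps penalized) over expected-substitution-score column matrices. Columns
with strictly more than 50% gaps are removed (a column with exactly half
gaps stays). Distances are Poisson-corrected p-distances over mutually
ungapped columns, $d = -\ln(1-p)$, clamped at 10 with a warning near
saturation — the minimal closed-form correction, chosen for testability.
Trees are neighbor-joining (via ape), with negative branch lengths clamped
to zero and the deficit moved to the sister branch. Bootstrapping is off by
default; `bootstrapSupport()` resamples alignment columns and attaches
per-node support fractions. Bayesian and maximum-likelihood tree inference
are deliberately out of scope; distance trees operate on the same filtered
alignments and preserve the pipeline's shape.

## Phage gene quantification

Phage-classified sequences (families flagged as phage in the lineage table)
feed ORF prediction; ORFs are searched against the ARG and functional
catalogues by protein–protein alignment at $E < 10^{-5}$, best hit per ORF.
Raw reads are mapped back to ORFs by exact 31-mer anchoring and ungapped
evaluation (a read maps when ≥ 90% of its bases align at ≥ 95% identity;
each read counts once, for its best ORF). Abundances are reported both ways
the field normalizes: ppm = hits × 10⁶ / N and
FPKM = hits × 10⁹ / (L × N), with N the raw (pre-cleaning) library read
count and L the coding length — the two factors are deliberately split into
two columns rather than coupled. Class tables sum ppm per drug class,
resistance mechanism or pathway category and normalize per library; a gene
is exclusive to a host-species group when detected (ppm > 0) in at least
one of its libraries and nowhere else, and core when detected in every
library.

At desk scale a library of 10⁴ reads cannot tile multi-kilobase genome
pools, so the orchestrator (`runPipeline()`) reconstructs phage ORFs by
*taxon-binned subassembly*: cleaned reads are first classified as singlets,
phage reads are binned by (library, assigned species), and each bin —
capped at `binCap` reads (default 200) to keep the greedy assembler's
quadratic cost bounded — is assembled separately, concentrating coverage
where ORF reconstruction is needed. The classic order (assemble each
library fully, then triage contigs, with the profile fallback) is available
via `assembleAll = TRUE` and is the natural choice for small libraries.
Quantification then maps every library's raw reads against the union ORF
catalogue in a single pass, so a gene reconstructed in any library is
quantified in all of them.

## Numerical choices and degenerate inputs

* Dedup survivor choice, ANOSIM permutations and every simulator draw come
  from seeds fanned out of one master seed (`deriveSeeds()`); no hidden
  global RNG state.
* Tie-breaks are deterministic everywhere: assembly merges by id pair,
  best hits by bit score, then identity, then subject id; UPGMA/NJ ties
  follow the underlying agglomeration order on continuous data.
* Empty inputs return empty, typed results (cleaning, search, ORF
  prediction); undefined quantities raise errors (Bray–Curtis on an
  all-zero row, PCoA below three items, NJ below three taxa, a saturated
  alignment pair with no shared ungapped column).
* Problem sizes used by the validation suite — 10⁴ reads per library for
  recovery, 10⁵ null queries for calibration, 2 × 10³ null data sets for
  ANOSIM size, 100 planted configurations/trees for ordination and NJ, 20
  seeded replicates for quantification linearity — were chosen as the
  smallest sizes at which the assertions have comfortable statistical
  margins.

## Known limitations

* The greedy assembler is exact only for overlaps whose leading 12-mer is
  error-free; at the simulated error rates this loses a small fraction of
  true overlaps and is not a replacement for a production assembler.
* E-values are conservative for short translated queries (see above); no
  composition-based statistics or effective-length correction.
* The profile fallback uses additive PSSM windows, not profile HMMs with
  insert states; remote homologs with indels relative to the profile are
  penalized more than HMMER would penalize them.
* Read mapping is ungapped at its anchor; indel-containing reads (absent
  from the simulator) would be under-mapped.
* `sharedSpecies()` enumerates observed intersection patterns, which is
  exact, but its output grows with 2^L only in the worst case of many
  libraries; it is intended for the handful of libraries this design uses.
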