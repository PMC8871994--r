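---
title: "Characterizing proto-genes: models, parameters and design choices"
author: "protogenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing proto-genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules behind each analysis stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology left room.

## The question

De novo gene birth produces *proto-genes*: open reading frames that have
recently gained transcription from previously non-coding DNA, together
with their transcript context (UTRs, exons, introns). Their properties are
expected to depend on *where* they emerged — overlapping an existing exon
(**exonic**, overprinting), inside an intron (**intronic**, exonisation),
or in intergenic sequence (**intergenic**, from scratch) — and on *when*,
encoded as age classes `I0` (lineage-specific) to `I5` (oldest stratum).
The pipeline characterizes four property families across these strata:
intron structure and origin, upstream regulatory-motif content, 5′-UTR
composition and folding, and hydrophobic clusters in the encoded
proto-proteins.

## Coordinates, classification and filtering

All internal coordinates are 0-based half-open; GTF I/O converts to and
from the 1-based inclusive convention. This makes interval arithmetic
(gaps between exons, block splitting at splice junctions) exact and
unambiguous.

An ORF enters the analysis only if (i) its genome-extracted,
splice-concatenated, strand-corrected sequence equals the claimed spliced
sequence — anything else, including any `N`, is treated as a mapping
artifact (conservative, since `N` never matches); (ii) it starts with
`ATG` and ends with a stop codon; and (iii) its expression is strictly
above 0.5 RPM (reads per million mapped reads; an ORF at exactly 0.5 is
removed).

Classification is interval overlap against established protein-coding
genes only: at least 1 bp of overlap with an exon makes an ORF exonic,
else intron overlap makes it intronic, else it is intergenic. Two choices
here were genuinely open. Overlap is **strand-agnostic**, because
overprinting explicitly includes emergence on the complementary strand of
an existing exon. And the precedence **exonic > intronic > intergenic**
resolves ORFs straddling a splice junction; the categories are meant to be
exclusive and the exon signal is the stronger claim. Antisense exon
overlap counting as exonic is flagged as an assumption in the
documentation.

## Intron analysis

Introns are the gaps between consecutive exons of the unspliced
transcript. An ORF on a multi-exon transcript is an *OutORF* when all of
its genomic blocks lie within a single exon (closed containment, so an
ORF coterminal with an exon still counts) — such an ORF is untouched by
splicing — and an *InORF* otherwise.

The recycling question — does an intron of an intergenic proto-gene
derive from an existing established intron? — is answered by local
alignment. The package implements Smith–Waterman with affine gaps
(match +2, mismatch −3, gap open 5, gap extend 2, the classic nucleotide
defaults) searching both subject strands, and Karlin–Altschul E-values
`E = K·m·n·e^(−λS)`. `K` and `λ` are not hard-coded: they are estimated
once per scoring scheme by aligning shuffled sequence pairs and fitting a
Gumbel law by the method of moments, cached, and fixed by an internal
seed — the estimate is part of the scoring scheme, not of the analysis
randomness. A query is recycled when at least one database hit passes all
of: E ≤ 0.01, identity strictly > 0.80, and **query** coverage ≥ 0.80.
Coverage is computed on the query because the question is whether the new
intron derives from an existing one; a subject-coverage variant would ask
the converse. The query subsample for this search is seeded and
reproducible. A score-only pass bounds each query/subject pair before the
full traceback, so only pairs that could clear the E-value filter are
aligned in full; the score pass is the same dynamic program, so results
are identical to aligning everything.

## Motif scanning

A JASPAR position frequency matrix becomes a probability matrix with a
background-distributed pseudocount,
`p[b,j] = (n[b,j] + 0.8·bg[b]) / (N_j + 0.8)`, and a log-odds PSSM
`s[b,j] = log2(p[b,j]/bg[b])`. The default pseudocount 0.8 is a common
PSSM convention; the methodology names none. Background frequencies
default to the scanned dataset's overall base composition (symmetrized,
since both strands are scanned), configurable to uniform.

"Similarity with the reference matrix" is interpreted as the max–min
normalized relative score, `(S − S_min)/(S_max − S_min)`; both thresholds
act on this scale: stage 1 keeps positions with relative score ≥ 0.7 (a
deliberately wide gate), stage 2 keeps hits at ≥ 0.95 (main run) or
≥ 0.80 (secondary run). Columns where `S_max = S_min` define relative
score 1 to avoid dividing by zero. Both strands are scanned and all
(possibly overlapping) occurrences are counted — the analysis counts
motifs found, with no greedy masking.

Windows are TSS-anchored: 200 bp upstream (`[tss−200, tss)` on the plus
strand, mirrored and reverse-complemented on the minus strand) and a
200-bp core window centred on the TSS. Six window datasets are compared:
proto-gene upstream, established upstream, pseudogene upstream, lncRNA
upstream, and random intergenic / random intronic background regions,
sampled disjointly, away from proto-genes, under a seed. The motif set is
partitioned by ranking motifs on their mean hit count per established
upstream window: the top half (ties broken by motif id, so the split is
deterministic) is promoter-specific, the rest enhancer-specific. The
split point — "most present" — is not pinned by the methodology; the
median default is a labelled assumption, and the quantile is exposed.

## UTR folding

The 5′ UTR is the spliced-transcript prefix before the ORF, the 3′ UTR
the suffix after the stop; transcription direction is assessed by exact
substring search in both orientations. GC content excludes `N` from the
denominator.

Folding uses a simplified nearest-neighbour model rather than a full
Turner parameter set: stacking energies for the six canonical pair types
(the stack of pairs a and b costs −(w_a + w_b) with w = 1.5 kcal/mol for
GC/CG, 0.9 for AU/UA, 0.5 for GU/UG — Turner-like magnitudes, symmetric
under reverse complement), linear hairpin (4.0 + 0.1·size), internal/bulge
(2.0 + 0.3·unpaired) and multiloop (3.4 + 0.4·branches + 0.1·unpaired)
penalties, minimum hairpin size 3, internal loops capped at 30 unpaired
bases, no dangles or coaxial stacking, 37 °C (RT ≈ 0.6163 kcal/mol). The
claims the pipeline makes are *comparative* (established vs proto vs
lncRNA), so the model needs to rank foldability consistently, not
reproduce absolute human free energies; every ensemble quantity is instead
pinned *exactly* against an internal oracle (below).

The MFE structure comes from a Zuker-style dynamic program with a
deterministic traceback (fixed scan order: hairpin, then internal loops,
then multiloops; the exterior prefers the unpaired extension on ties).
The partition function and base-pair probabilities come from McCaskill
inside–outside recursions over the *same* structure space, so
`G = −RT ln Z ≤ E_mfe` always, the MFE frequency is
`exp(−(E_mfe − G)/RT)`, and the ensemble diversity is the expected
base-pair distance between two independent ensemble draws, which equals
`2·Σ_{i<j} p_ij (1 − p_ij)`. The factor-of-2 convention is pinned by the
enumeration oracle, which computes the weighted mean pairwise distance
over all enumerated structures directly.

The oracle (`enumerate_structures`) generates every nested,
h-respecting structure of a short sequence (guard: length ≤ 16), scores
each with an independent loop-decomposition evaluator, and produces exact
`Z`, `p_ij`, MFE, `G`, frequency and diversity. The dynamic programs are
required to match it to 1e−6 across random sequences at three GC levels;
they actually agree to ~1e−12 (floating-point noise).

lncRNA controls are whole transcripts restricted to the UTR length range
(range containment); the matching tolerance is not specified anywhere, so
the rule is deliberately the simplest defensible one and is implemented as
a separate, visible step (`match_length_range`).

## Proto-proteins

ORFs are translated with the standard code. A hydrophobic cluster is a
maximal set of strong hydrophobic residues ({V, I, L, F, M, Y, W}) in
which consecutive hydrophobic residues are separated by fewer than 4
non-hydrophobic residues, none a proline; either a ≥ 4 gap or any proline
terminates the cluster. These are the standard hydrophobic-cluster-
analysis conventions; the source methodology names the tool but not its
parameters, so both the alphabet and the breaker rules are configurable.
Cluster size counts hydrophobic residues (the span-length alternative is a
flag). Only cluster counts and sizes are reported — the full
foldable-segment statistic of segmentation tools is out of scope, so
counts are method-faithful but not guaranteed numerically identical to any
specific external program. The oldest stratum `I5` is excluded from the
cluster summary by default because it is dominated by annotated domains.
External domain-scan results are only *read* (tabular reader + fraction
per stratum); running the scan itself is out of scope.

## Statistics

Two-sample comparisons are routed by a Fisher variance test: equal
variances go to the Student test, unequal to Welch, and an undefined
variance ratio defaults to Welch. Normality pre-tests are intentionally
omitted (group sizes in this design are in the hundreds). Multi-group
comparisons use Kruskal–Wallis with tie correction; age trends use OLS on
the age rank 0–5. No multiple-testing correction is applied by default,
matching the analysis design; a Benjamini–Hochberg option exists on the
report side via `stats::p.adjust` if wanted. All test wrappers delegate to
the base R implementations and are verified against hand-computed
formulas to 1e−10.

## The synthetic generator: what it emulates, and what not

The generator is first-class, tested code. Its defaults *are* the study
conditions the pipeline is validated under:

- 4 contigs × 700 kb of iid background at GC 0.41 (human-like bulk
  composition); 130 established genes with 5–7 exons, CDS of 80–260
  codons, 5′/3′ UTRs at GC 59.26 % / 45.20 %, canonical `GT…AG` intron
  ends, four long "host" introns per gene (1.5–2.1 kb, the human-typical
  intron scale) that can accommodate intronic proto-genes, plus 40
  pseudogene and 40 lncRNA loci.
- 40 proto-genes per (position × age) stratum = 720 total, half on the
  minus strand. Intron-presence probabilities rise with age within each
  position (exonic 0.75→1.00, intronic 0.10→0.30, intergenic 0.026→0.30 —
  the reported per-stratum ranges, linearly interpolated between the
  endpoints), single-exon-ORF fractions fall with age (exonic 0.378→0.039,
  intronic 0.735→0.492, intergenic 0.762→0.181), 41 % of intergenic
  proto-gene introns are windows of established introns mutated at 10 %
  per base (substitutions only, splice dinucleotides pinned), 5′ UTRs are
  longer in the youngest strata (90–150 nt at `I0` shrinking to 30–80 nt
  at `I5`) with GC 0.58 (exonic) vs 0.51 (intronic/intergenic), 3′ UTRs at
  GC 0.4719, and RPM is log-normal(0.5, 1) so that roughly one ORF in
  eight falls below the 0.5 filter.
- Planted motifs are PFM consensus sequences (guaranteeing relative score
  1.0, which makes recovery tests sharp): promoter-like motifs at high
  rates upstream of established genes (0.60/motif) and exonic proto-genes
  (0.45), enhancer-like motifs at high rates upstream of intronic and
  intergenic proto-genes (0.45), low rates elsewhere, and a TATA-box-like
  motif at position −30 in a fraction of core windows. Occurrences never
  overlap within a window; about 30 % are planted on the reverse strand.
- Each component (genome, established genes, proto-genes, motifs) draws
  from its own stream derived from the master seed, so identical spec and
  seed give byte-identical FASTA/GTF/TSV/JSON outputs.

Planting order is intergenic → intronic → exonic so that the source
regions of recycled introns can be frozen before any later planting could
overwrite them; every placement additionally avoids established UTR
blocks and all upstream windows, keeping the planted GC targets and motif
occurrences intact.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: genomic sequence is iid within GC strata (no
repeats, no transposable elements, no isochores), expression is a scalar
draw (no read-level noise, no tissue specificity), recycled introns
diverge by substitutions only (an indel mode exists behind the mutation
utilities but is off by default, keeping identity and coverage
analytically predictable), ORF amino-acid composition is age-independent
(so hydrophobic-cluster counts show no planted age trend; the
cluster-vs-age regression is validated separately by parameter recovery
on simulated Poisson counts), and lncRNA-origin proto-genes are not
modelled. Planted-truth recovery therefore demonstrates correctness of
the *operations*, not robustness to the full messiness of a real genome.

## Problem sizes and numerical choices

The bundled analyses run at a deliberate desk scale: a ~2.8-Mb genome,
720 proto-genes (≈ 620 after validation and expression filtering, ≥ 600
so every stratum stays populated), 250 background windows per control
dataset, an intron-recycling search of all intergenic proto-gene introns
against all ~650 established introns (the subsample cap of 500 only binds
on larger inputs), and up to 100 folded 5′ UTRs per group (seeded
subsample, sequences of 5–160 nt). Headline numbers from the original
human-scale analysis (23,135 proto-genes against GRCh38) depend on that
external dataset and are not reproduced here; the synthetic run reproduces
the *qualitative structure* — rising intron presence with age, a ~41 %
recycled fraction, promoter-motif enrichment upstream of exonic
proto-genes and established genes, enhancer enrichment for
intronic/intergenic ones, and the established > proto 5′-UTR GC gap — with
the corresponding test decisions at α = 0.01.

Numerical determinism: all report tables are written with fixed column
order, fixed stratum order (explicit factor levels, radix sorting, never
locale collation) and fixed numeric formatting, so two runs on the same
fixture and seed are byte-identical. Degenerate inputs are handled
explicitly: empty UTRs are reported missing rather than zero, strata with
no members appear as `NA` rows, sequences that cannot pair fold to the
open chain at 0 kcal/mol with MFE frequency 1 and diversity 0, and
fully-degenerate two-sample tests return t = 0, p = 1.

## Known limitations

- The folder's absolute energies are not comparable to full
  Turner-parameter implementations; only within-model comparisons are
  meaningful. (An external folder can be used as a sanity cross-check,
  but no test depends on one.)
- Karlin–Altschul parameters from moment-fitted Gumbel simulations carry
  a few-percent calibration error; the E ≤ 0.01 filter is robust to this
  because planted positives pass it by orders of magnitude and the
  identity/coverage filters dominate specificity.
- The alignment search is exhaustive (all query/subject pairs); there is
  no word-indexed heuristic, so genome-scale databases are out of scope by
  design.
- The promoter/enhancer split is a ranking on one dataset; with motif sets
  whose frequencies are nearly tied, membership near the split point is
  decided by the id tie-break.
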