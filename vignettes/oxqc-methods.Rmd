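---
title: "Assembly QC with oxqc: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly QC with oxqc: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxqc)
```

oxqc packages the bespoke computations that surround a long-read genome
assembly project once the assembler and polisher have done their work:
estimating the residual error rate, auditing gene completeness at exon
resolution, screening for contamination and nuclear-mitochondrial
insertions, validating the mitochondrion, assigning contigs to chromosomes
by synteny, reconciling the karyotype against an ancestral segment set, and
summarising variant-call diversity. This vignette explains the models, the
parameters that matter, and the design decisions, in that order. Everything
quantitative shown here is computed by the chunks themselves.

## The spurious-stop error model

A substitution error inside an annotated coding region will, occasionally,
create a premature termination codon. That gives an observable handle on
the residual error rate of a polished assembly even when no reference of
known sequence exists. The model assumes errors are independent across
bases and uniform across the three wrong bases. A codon is read correctly
with probability $A^3$, where $A$ is the per-base accuracy; conditional on
being wrong, it is uniform over the 63 incorrect codons, of which 3 are
stops. Hence the per-codon spurious-stop probability

$$T = (1 - A^3)\,\frac{3}{63}.$$

`spuriousStopProb()` implements the forward map, and
`simulateStopInjection()` validates it by actually drawing uniform
codon replacements rather than reusing the algebra:

```{r}
sim <- simulateStopInjection(2e5, A = 0.99, replicates = 5, seed = 1)
c(expected = sim$expected, mean_observed = mean(sim$observed))
```

Observing zero internal stops across $N$ codons bounds $T < 1/N$, and
inverting gives the accuracy lower bound
$A = (1 - 21\,T)^{1/3}$ (`accuracyBound()`):

```{r}
b <- accuracyBound(782521)
b
```

Three numerical choices deserve a note.

* **Truncation, not rounding.** The reported percent and bases-per-error
  figures are *truncated* at the printed precision (5 decimals and integer
  respectively). The quantity is a lower bound, and truncation keeps the
  printed figure on the conservative side of the exact value
  (99.999105…% prints as 99.99910, and 111,787.8 bases per error prints as
  111,787). Rounding would overstate the bound in the last digit. Full
  precision is retained in the object.
* **The accuracy complement is first-class.** A double near 1 cannot
  represent its own complement to better than about $10^{-10}$ relative
  error, so the object carries $1-A$ at full relative precision (computed
  with `log1p`/`expm1`) and derives the Phred score and bases-per-error
  from it. Composing `accuracyBound()` with `spuriousStopProb()` on the
  bound object round-trips $T$ to better than $10^{-12}$ relative error;
  going through the scalar accuracy value is limited to about $10^{-9}$ by
  representation.
* **Stops > 0 are an extension.** The zero-stop case is the principled
  bound; for catalogues with internal stops the point estimate
  $T = n_\text{stops}/N$ is used and documented as such.

The model covers substitutions only — indels shift the frame and are the
business of the polisher, not of this estimator — and treats $N$ as an
input: assembling the codon catalogue from a genuine annotation is
`countOrfCodons()`'s job, which also excludes genes whose CDS length is not
a codon multiple and flags ORF-structure violations.

## Exon walking and the completeness rule

Profile-based completeness tools balance sensitivity across all mammals and
therefore occasionally miss genes whose orthologs sit far from the
consensus, or whose introns are simply enormous. The walker re-examines
such genes directly. Its search engine is seeded local alignment: short
exact probe k-mers (16-mers, four per exon, both strands) locate candidate
regions via a constant-width dictionary scan, and an affine-gap
Smith–Waterman (match +1, mismatch −1, open 2, extend 0.5 — all
configurable) scores the full exon there. The probe index is built once per
query set, so assemblies are scanned once regardless of gene count.

The *seed exon* is the highest-scoring hit among the gene's exon probes;
ties break deterministically (longer alignment, then leftmost, then `+`
strand). From the seed, each adjacent exon is sought in a window that
starts at 10 kb and grows by one window per failed attempt up to
`maxExtension` (default 1 Mb per intron — single introns beyond 100 kb are
real: the largest mammalian genes span megabases over ~90 exons). A hit is
accepted only when its length preserves the query exon's frame modulo 3 and
the implied intron boundaries read GT…AG (configurable; non-canonical
boundaries fail the check, by design). A gene is **complete** when every
exon is found under those rules, the assembled CDS has an initiation codon,
a terminal stop and no internal stop, and its translation is at least 70%
identical to the full-length query protein under a global alignment whose
denominator is the full query length (so end gaps against the query are
penalised). **Missing** means no seed at all; everything else is
**fragmented**, with a reason code, and frameshifts are reported rather
than raised.

```{r}
g <- makeGenome(synthConfig(genomeLength = 2e5, nGenes = 5), seed = 7)
tab <- verificationTable(verifyGenes(g$assembly, exonQueriesFromTruth(g)))
table(tab$status)
```

Identity for completeness is protein-level only; nucleotide identity at the
exon level is recorded per hit but does not gate the classification. The
minimum seed score (half the exon length by default) and the extension cap
are exposed because no principled universal value exists for either.

## Screens

**Contamination.** Contigs are tiled into non-overlapping 5-kb windows (the
final window truncated; a short contig is one truncated window) and each
window is aligned against the contaminant database, again with k-mer
seeding so clean windows cost almost nothing. A window is positive at ≥ 95%
identity over at least 100 aligned bases — the identity default mirrors the
match range one actually observes for genuine contaminants — and a contig is
*removed* when two or more positive windows are adjacent or when positives
make up half of a short contig, *flagged* on any isolated positive, else
kept. The adjacency generalisation (the canonical removed contig had five
adjacent positives) errs toward flagging rather than deleting.

**NUMT scan.** The mitochondrion is aligned against the nuclear assembly;
anchor clusters are verified by local alignment against the matched
mitochondrial interval only, and loci closer than 50 bp merge. The
threshold is expressed as an E-value and translated to a minimum score by
the ungapped Karlin–Altschul formula for ±1 scoring (λ = ln 3, K ≈ 0.35).
The conventional printed threshold "1E4" is ambiguous; both readings are
selectable and the default reads it as E ≤ 1e−4. The mitochondrial contig
itself is excluded by id.

**Circularization and tiling.** `circularize()` trims exactly one copy of
the longest terminal direct repeat (≥ 50 bp by default, ungapped, with a
mismatch tolerance), reports the junction, and refuses to trim an
already-trimmed sequence. `tilingValidation()` counts, for every 50-bp
window advanced by 1 bp, the reads that cover the window *entirely* —
uninterrupted tiling semantics, not partial overlap — wrapping across the
origin for circular sequences; validation passes when no window is
uncovered and the minimum depth exceeds the threshold (the conventional
short-read depth of 7500 for a mitochondrion is a dataset property and
lives in the pipeline configuration, not in code).

## Synteny and karyotype

Alignment records carry PAF semantics; divergence is
$1 - \text{matches}/\text{block}$, and the standard filter keeps records at
≤ 20% divergence (the asm20 convention). Assignment is a weighted vote:
per contig, aligned-base support per target label, with a ranked-reference
override for multi-reference runs and a painting-map-style label remap hook
(`labelMap`) for refinements that come from external cytogenetic evidence.
A runner-up within 0.1 of the winner's support fraction flags a conflict.
Contigs order within a chromosome by weighted median target coordinate and
orient by strand majority; input contigs are never split or edited, and
gaps are emitted as 100-bp AGP 2.1 "U" rows (standard convention where no
evidence says otherwise). `consistencyCheck()` abstracts the assembler's
repeat-graph review into an allowed-adjacency set; an empty set means
"no constraints", not "nothing allowed".

Karyotype reconciliation needs only the chromosome → ancestral-segment
correspondence: each extra segment on a chromosome is a fusion, each extra
chromosome carrying a segment is a fission, and the counts obey
$\#\text{segments} - \#\text{chromosomes} = \text{fusions} -
\text{fissions}$. The fundamental number comes from the morphology
annotation, $FN = 2(2\,n_\text{biarmed} + n_\text{acro})$. Inversions are
deliberately out of scope: a correspondence table carries no within-segment
orientation, so inversion counts belong to painting or alignment evidence.
The packaged muskox correspondence (`muskoxKaryotype()`) encodes the six
fusions (N1+A2, R+B2, T+C2, V+C1, W+S, U+Q) and the single fission (U):

```{r}
reconcileKaryotype(muskoxKaryotype())
```

## Variant diversity

Hard filtering follows the conventional germline thresholds, partitioned by
SNV/indel via the size class. Two readings matter: the annotation sometimes
printed as "SQR" is treated as the single annotation SOR (accepted under
either name), and missing annotations never fire a rule — discarding sites
for lacking an annotation would bias against well-behaved homozygous-rich
regions. Heterozygosity spectra normalise by *total reference length*, not
callable length (a flag exists for the latter), bin by
$\lvert\text{alt}\rvert - \lvert\text{ref}\rvert$ and clip at ±k.
Variant profiles are sets of single-base substitutions within a gene's exon
intervals; indels are excluded (coding-region tabulations of this kind are
single-base in practice), profile identity is set identity, and empty
profiles are excluded from unique-profile counts by default because a blank
row means "no variants", not a countable profile — both choices are
toggleable. Multi-allelic records split into biallelic calls before
filtering.

## The synthetic generator

The generator exists so every stage above can be scored against known
truth. It builds ancestral segments, derives chromosomes by applying
configured fusions/fissions/inversions, cuts contigs, then *overwrites*
windows of the derived sequence with planted features — genes with intact
ORFs and GT/AG boundaries, NUMT copies of a synthetic mitochondrion mutated
at a configured divergence, heterozygous variants with truth-labelled
INFO annotations drawn from two-component mixtures that straddle each
filter threshold. Overwriting (never inserting) keeps every recorded
coordinate exact. Alignment records are constructed from the recorded
provenance at a configured divergence — they stand in for a mapper's
output, which is exactly what the assignment logic consumes.

Defaults are chosen once to caricature a muskox-scale project: per-base
accuracy 0.999991, 0.5 heterozygous SNVs/Mb (a very low-diversity
ungulate), indel rates an order of magnitude lower with a symmetric size
spectrum, a 16,431-bp mitochondrion, NUMTs of 200–2000 bp at 10%
divergence, and a 26-kb contaminant contig. Test and example genomes are
hundreds of kilobases to a few megabases with tens to two hundred genes —
sizes at which every property below has comfortable statistical power while
the full suite runs in minutes. What the generator does *not* emulate:
read-level error profiles and quality scores, repeats and low-complexity
sequence, diploid assembly graphs, GC and mutational spectra, or linkage
between variants. Passing tests therefore demonstrate the *logic* of each
stage under its stated model, not performance on real data — in particular,
random background sequence is maximally easy for alignment screens, and
real repeat families would produce candidate hits the synthetic genomes
never exhibit.

Sensitivity boundaries worth knowing: the NUMT and marker screens anchor on
exact 13-mers, so recall is effectively complete down to ~15% divergence
for loci ≥ 200 bp (the anchoring probability decays steeply beyond that);
the walker's seed probes are exact 16-mers, four per exon, so heavily
mutated exons lose their seeds before they lose alignability — which only
hastens the fragmented/missing classification that such genes deserve.

## Reproducibility

Every stochastic function takes an explicit integer seed, and identical
configuration + seed gives byte-identical artifacts, including file output.
The pipeline (`runPipeline()`) logs each stage's key numbers into a single
JSON summary; two runs at the same seed produce identical summaries. The
command-line wrapper is a thin veneer over the same functions.
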