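---
title: "Measuring codon usage bias with cubkit: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Synonymous codons encode the same amino acid but are not used at random.
Two forces shape the departure from uniformity: directional mutation
pressure, which drags nucleotide composition (most visibly the third codon
position) toward AT or GC, and natural selection, typically translational
selection favouring codons matched to the abundant tRNA pool of highly
expressed genes. cubkit computes the standard battery of per-gene and
per-genome statistics used to weigh these forces against each other in
coding-sequence (CDS) collections — for instance the macronuclear gene sets
of ciliates, whose extreme AT richness and stop-codon reassignments make
them a stress test for this kind of analysis. A seeded synthetic-CDS
generator with known mutation and selection knobs lets every stage of the
pipeline be validated against ground truth without any genome downloads.

The central entry point is `cub_analysis()`, which returns a classed object
with `print()`, `summary()` and `plot()` methods; every index is also
exported as a standalone function.

## Input filtering

`qc_filter()` keeps a sequence only if it (i) contains no base outside
A/C/G/T, (ii) has length an exact multiple of three and strictly greater
than `min_len` (default 300 nt, so the shortest accepted CDS is 303 nt),
(iii) starts with ATG, (iv) ends with a stop codon of the active genetic
code, (v) contains no internal stop, and (vi) optionally is not an exact
duplicate of an earlier record. Records with ambiguous bases are rejected
whole rather than trimmed: trimming would break the reading frame and there
is no principled rule for it. Duplicate removal collapses exact
full-sequence matches only; near-duplicate clustering is out of scope. The
rules are tested in a fixed order and the first failure is reported per
gene, with corpus totals per rule, so QC attrition is auditable.

The genetic code is pluggable (`load_code()`): table 1 (standard) is the
default; table 6 (ciliate nuclear, TAA/TAG = Gln, TGA the only stop) is
supported for reanalysis of taxa with reassigned stops. The synonymous
family partition and degeneracy classes are always recomputed from the
codon-to-amino-acid map, never hard-coded per index, so every downstream
statistic stays consistent under a code switch. Under the standard code the
single-codon families (Met, Trp) and the three stops are excluded from
codon-usage statistics, leaving the familiar 59 analyzed codons.

## Composition statistics

For each gene, `composition_profile()` reports GC, GC1, GC2, GC3 and
GC12 = (GC1 + GC2)/2 over all sense codons (the terminal stop is excluded;
ATG and TGG are included, since whole-CDS GC content is a property of the
gene, not of its synonymous choice), and GC3s plus the third-position base
fractions A3/T3/C3/G3 over synonymously variable codons only (families of
degeneracy at least 2). Computing both GC3 and GC3s on their own codon sets
keeps each downstream formula faithful to its own symbol: the expected-ENc
curve and the ENc plot consume GC3s, while the neutrality regression
consumes GC3 and GC12. Species-level values are codon-count-weighted pools
(`pool_composition()`), equivalent to concatenating all analyzed codons —
not unweighted means of per-gene fractions — which makes them
order-invariant and independent of how genes are split across files.

## Effective number of codons

ENc summarises how evenly a gene spreads usage across each family. Each
family's homozygosity is computed with a pseudocount form,

$$F = \sum_{i=1}^{m}\left(\frac{n_i + 1}{n + m}\right)^2,$$

where $n_i$ are the codon counts of the $m$-codon family and $n$ their sum.
The pseudocounts make $F$ well defined even for unobserved families
($F = 1/m$ exactly at $n = 0$, and exactly $1/m$ whenever usage is equal),
so no family is ever dropped by default (`drop_unobserved_families` exists
for sensitivity analysis). Family values are combined Wright-style through
per-degeneracy-class means: under the standard code

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

with the leading 2 for Met and Trp. Six-fold families are treated as single
six-codon families, not 2+4 splits, because $m$ is defined as the number of
codons in the family. This aggregation reproduces the analytic range: ENc
is exactly 61 for perfectly even usage and approaches 20 as each family
collapses onto a single codon (the pseudocounts leave a deficit of order
$1/n$, about 0.008 at counts of 10,000). Values below 35 are conventionally
read as strong bias. Note that at realistic gene lengths the pseudocounts
bias ENc upward by 1–2 units relative to the infinite-length value; the
package's own neutral-limit tests therefore use long synthetic genes
(1,500–2,000 codons) when probing the 61 limit.

The mutation-only reference curve is

$$\mathrm{ENc}_{exp}(s) = 2 + s + \frac{29}{s^2 + (1-s)^2}$$

with $s$ = GC3s, and the relative deviation is
$(\mathrm{ENc}_{exp} - \mathrm{ENc}_{obs})/\mathrm{ENc}_{exp}$. A small
numerical aside: because of the linear $s$ term this curve is not exactly
maximized at $s = 0.5$ — the true optimum sits near $s \approx 0.502$ with
value $\approx 60.501$, while the curve passes through 60.5 at $s = 0.5$.
The tests assert the peak at the resolution at which that statement is
true.

## RSCU, CAI and optimal codons

RSCU is observed count over the equal-usage expectation within the family;
values sum to the degeneracy within each observed family and are
length-scale invariant. Codons are classed by the conventional thresholds,
with the two middle intervals made explicit: over-represented above 1.6,
"average-biased" in (1, 1.6], unbiased in [0.6, 1], under-represented below
0.6. Families absent from a gene yield `NA` with a flag, never NaN.

CAI is the geometric mean of relative-adaptiveness weights over a gene's
analyzed codons, $\exp(\frac{1}{L}\sum \ln \omega)$. The weights are the
Sharp–Li ratio-to-family-maximum computed from a reference pool. Because no
canonical highly-expressed reference exists for most non-model genomes, the
default reference is the entire filtered gene set itself (an external
reference FASTA is accepted via `cai_reference`). Codons absent from the
reference within an observed family receive a pseudo-frequency of 0.5
before the ratio, keeping $\ln\omega$ finite; with a self-referenced
corpus every codon a gene uses is present in the pool, so wholly absent
families can simply carry `NA` weights that `cai()` skips.

Putative optimal codons are identified per family as the codon whose
per-gene RSCU correlates most negatively with per-gene ENc (usage rising as
bias strengthens), requiring two-sided p < 0.05; Spearman correlation is
the default (Pearson selectable) since the index distributions are skewed.
Zero-variance codon columns are skipped with a flag; ties are broken by
larger mean RSCU, then lexicographic codon order, making the output
deterministic.

Gravy is the mean Kyte–Doolittle hydropathy of the residues encoded by the
analyzed codons (Met and Trp excluded, consistent with the codon
exclusions); aromaticity is the fraction of Phe/Tyr/Trp among *all*
translated residues — a property of the whole protein, so Trp deliberately
counts here despite being excluded from the codon indices.

## Mutation–selection diagnostics

**PR2.** Third-position tallies over the two-, four- and six-fold families
(the three-fold Ile family is excluded by default, selectable for
sensitivity) give the point $x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$; the
parity expectation is (0.5, 0.5). One structural caveat the tests make
explicit: the parity expectation is exact family-by-family only when a
family offers both bases of a pair. Two-fold A/G families (Lys, Gln, Glu)
contribute G but never C at the third position, so a corpus with uniform
amino-acid composition sits measurably off-centre (near 0.42) even under
perfectly symmetric mutation. The package's parity tests therefore use
four-fold-family compositions, where the expectation genuinely holds, and
treat full-code PR2 positions as what they are — composition-dependent
diagnostics, not calibrated nulls.

**P2.** Codons are classed by their first two bases (W = A/T, S = C/G) and
pyrimidine third base (Y = C/T);
$P2 = (WWC + SST)/(WWY + SSY)$ measures how often the translationally
favoured pyrimidine is chosen. Because corpus-level P2 depends on the
aggregation convention, `p2_summary()` reports both the unweighted mean of
per-gene values and P2 recomputed from pooled counts, rather than choosing
silently — the two differ whenever genes contribute unequal numbers of
qualifying codons.

**Neutrality.** `neutrality_fit()` is unweighted ordinary least squares of
per-gene GC12 on GC3 (weighting by gene length available in principle but
not the default, since the standard presentation is unweighted). The slope
is annotated with the usual reading — near 1 mutation-dominated, near 0
selection-dominated, near 0.5 balanced — as a label only; no decision is
made on the user's behalf.

## Correspondence analysis

`build_rscu_matrix()` assembles the gene-by-codon RSCU matrix (fixed
lexicographic column order; unobserved families zero-imputed with flags).
`correspondence_analysis()` is classical CA: normalize to a correspondence
table, centre by the outer product of row and column masses, scale to
standardized residuals and decompose by SVD; rows and columns are returned
in principal coordinates with per-axis inertia fractions (non-increasing,
summing to 1). RSCU values enter raw — classical CA's internal mass
normalization is the only row scaling applied. Axis signs from an SVD are
arbitrary, so each axis is deterministically oriented to give the
alphabetically first codon with a nonzero loading a positive one;
coordinates are then platform-stable. Degenerate inputs (identical row
profiles, zero totals) raise explicit errors rather than returning empty
decompositions. An independent eigen-decomposition, and `MASS::corresp`,
serve as cross-checks in the test suite.

Correlation panels cover the standard pairs (ENc–GC3s, axis-1 against
composition/CAI/ENc, CAI–ENc, CAI–GC3, Gravy/Aroma/length against GC and
ENc) with complete-case handling, and report raw p-values alongside
Benjamini–Hochberg adjusted ones.

## The synthetic-CDS generator

`generate_corpus()` implements the simplest generative model that moves the
two axes of interest independently. Amino acids are drawn i.i.d. (uniform
over the 18 multi-codon families by default, configurable to any
composition); within a family, codon probabilities are proportional to
third-position base weights tilted toward `gc3_target` (G and C share
weight `gc3_target`, A and T share the rest) — the mutation knob —
multiplied by `exp(preference)` on the family's preferred codon — the
selection knob — and renormalized. A configurable fraction of genes is
"highly expressed" with amplified preference, producing the CAI/ENc
gradient that optimal-codon detection requires. Genes get an ATG start, a
stop from the active code, and lengths that always pass QC. Everything is
deterministic under the spec's seed, with the RNG state restored
afterwards, and the planted truth (preferred codons, expression classes)
is returned alongside the sequences so tests never re-derive it.

`generate_neutrality_corpus()` targets the neutrality regression
specifically: each gene draws a latent mutational GC level $g_i$ over a
wide range, GC3 is realized as exactly `round(g_i L)` GC-ending thirds out
of $L$ codons, and GC12 as exactly `round((\beta g_i + (1-\beta) b +
\varepsilon_i) L)` codons from GC-rich amino-acid families (Ala/Gly/Pro,
first two positions all G/C) versus AT-rich ones (Lys/Asn/Phe). Realizing
the regressor by exact counts rather than per-codon sampling avoids
regression attenuation from sampling error in GC3, so $\beta = 1$ with
zero noise recovers a slope of exactly 1, and $\beta \in \{0, 0.3\}$ are
recovered within ±0.05 at 500 genes with the default noise (sd 0.02 on the
GC12 target).

What the generator does *not* emulate: phylogenetic correlation between
genes, amino-acid composition driven by protein function, length-dependent
selection strength, dinucleotide or codon-pair constraints, and intragenic
composition gradients. Passing recovery tests on this model therefore shows
the estimators are correct for data satisfying their own assumptions — not
that real genomes satisfy them.

`worked_micro_corpus()` ships five tiny hand-auditable genes whose
composition, family homozygosity, RSCU, CAI (under the corpus's own pooled
reference), Gravy, Aroma, PR2 and P2 were computed by hand from the
defining formulas and frozen; the pipeline must reproduce the table at
four-decimal precision end to end.

## Numerical choices and degenerate inputs

- ENc family homozygosity uses the +1 pseudocount form exactly as defined;
  no additional smoothing anywhere.
- RSCU of a zero-total family is `NA` + flag; CA drops all-zero rows with a
  warning and all-zero columns silently; identical-profile matrices raise.
- Zero PR2 denominators flag the affected coordinate as undefined and the
  pipeline records `NA` for that gene rather than failing the run.
- Correlations with zero variance return flagged `NA`s; fewer than three
  complete cases is an error.
- Singular values are thresholded at `100 * eps * max(dim) * d_max` to
  decide the CA rank.
- All tie-breaks (optimal codons) and axis orientations are deterministic.

Test problem sizes are chosen to make each property visible at desk scale:
1,000 random genes for the RSCU/CAI oracle sweeps, 500-gene corpora for
neutrality recovery, 100 seeded replicates of 30-gene corpora for
optimal-codon recovery, and 20×59 matrices for the CA oracle checks.

## Worked example

```{r example}
spec <- synthetic_spec(n_genes = 30, gc3_target = 0.3,
                       preference_strength = 1.5,
                       expression_gradient = 0.5, seed = 42)
fit <- cub_analysis(generate_corpus(spec))
fit
head(summary(fit))
```

```{r plots, fig.width = 5, fig.height = 4}
plot(fit, which = "enc")
```

## Limitations

The package analyses codon usage only: it does not infer orthology, build
trees, predict expression beyond CAI, or compute tAI/codon-pair scores.
Per-species results on real genomes depend on upstream CDS curation
(annotation quality, paralog collapse) that no index can repair, and the
CAI default of a self-referenced weight set measures internal usage
consistency, not adaptation to an independently defined highly expressed
set.
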