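---
title: "Inferring genotype-specific gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring genotype-specific gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsgrn)
library(dplyr)
```

## The problem

Most disease-associated genetic variants are noncoding, and a large share
of them are thought to act by changing how transcription factors (TFs)
bind regulatory DNA. Standard network-inference methods estimate one
TF→gene regulatory network per condition or tissue and ignore the
genotypes of the individuals behind the data, so they cannot say *whose*
regulation a variant disturbs. gsgrn infers a separate bipartite TF→gene
network for every genotyped individual in a cohort, by penalizing a
motif-derived network prior exactly where that individual carries
promoter variants with converging evidence of regulatory disruption, and
then letting message passing reconcile the penalized prior with
population-level coexpression and protein–protein-interaction (PPI)
evidence.

## The model

### Reference prior and genotype penalty

The reference prior $M$ is a binary TF × gene matrix: $M_{ij} = 1$ iff at
least one occurrence of TF $i$'s motif overlaps gene $j$'s promoter
window, taken as $[-750, +250)$ bases around the TSS in transcription
direction (a 1 kb window; minus-strand windows are mirrored through the
TSS, because "upstream" is a biological, not a coordinate, notion).
Motif-scan hits are used at the scanner's $P \le 10^{-4}$ cutoff.

For one individual, a variant $s$ qualifies against edge $(i, j)$ when
it (1) falls inside an occurrence of TF $i$'s motif that lies within gene
$j$'s promoter, (2) is a statistically significant eQTL whose eGene is
gene $j$ itself, and (3) is predicted to *reduce* TF $i$'s binding
(negative effect $q$, significant at the configured threshold). The
penalized prior is

$$E_{ij} = M_{ij} - \sum_s \lvert q_{sij}\, A_{sij}\, \beta_{sij} \rvert,$$

with $A$ the individual's alternate allele count (0/1/2) and $\beta$ the
eQTL effect size. The absolute value reflects that edge weights encode
the *strength* of a regulatory connection, not its sign; only loss of
binding is modeled (positive $q$ is ignored), so no new edges are ever
created. $E$ is deliberately not clamped at zero: the penalty is a dosage
signal and the normalization step of message passing absorbs overall
scale, while a floor at zero would erase the difference between a
heterozygous and a homozygous disruption of the same site.

### Message passing

$E$ (or $M$, for the genotype-agnostic baseline) is refined against a
gene–gene Pearson coexpression matrix $C$ (genes with nonzero expression
in fewer than 50 samples are dropped first; no thresholding of the
correlations) and a TF–TF interaction matrix $P$ with unit diagonal. All
three matrices are z-score normalized once,
$Z = (Z_\text{rows} + Z_\text{cols})/\sqrt{2}$, with a whole-matrix
fallback for zero-variance rows or columns. Each iteration then updates
the regulatory matrix $W$ with a fraction $\alpha = 0.1$ of the average
of two similarity maps built from the continuous Tanimoto similarity
$T(x, y) = x \cdot y / \sqrt{\lVert x\rVert^2 + \lVert y\rVert^2 -
\lvert x \cdot y \rvert}$:

* *responsibility* $R_{ij} = T(P_{i\cdot}, W_{\cdot j})$ — how well the
  TFs targeting gene $j$ match the interaction partners of TF $i$;
* *availability* $A_{ij} = T(W_{i\cdot}, C_{\cdot j})$ — how well TF
  $i$'s targets match the genes coexpressed with gene $j$.

$P$ and $C$ are in turn nudged toward the similarity of TF target
profiles and gene regulator profiles in the current $W$, with the same
$\alpha$. Iteration stops when the mean absolute entrywise change of $W$
falls below $10^{-3}$; the converged network is complete — every TF-gene
pair carries a finite weight.

Two numerical choices deserve note, both adopted from the reference
behavior of this message-passing family and controllable via
`panda_config()`:

* **Convergence metric.** "Hamming distance" here is the mean absolute
  entrywise difference between successive $W$ matrices — scale-stable and
  continuous, unlike a literal Hamming distance on binarized networks.
* **Diagonal inflation.** After each update of $P$ and $C$ the diagonal
  is refilled with (per-row sd over off-diagonal entries) × dimension ×
  $e^{2\alpha t}$ ($t$ = 0-based iteration). Without this, trivial
  self-similarity dominates both matrices and the fixed point
  degenerates. The update is toggleable (`inflate_diagonal = FALSE`).

Both the penalized priors and the reference prior go through the same
code path, so an individual carrying no qualifying variants reproduces
the baseline network bit for bit.

### Disruption and difference scores

With $E^*_x$ the converged network of individual $x$ and $B^*$ the
baseline, the scores are

$$d_{xij}(E) = \lvert E^*_{xij} - B^*_{ij}\rvert, \qquad
  d_{xi}(TF) = \sum_j d_{xij}(E), \qquad
  d_{xj}(G) = \sum_i d_{xij}(E),$$

and between genotypes $g$ and $k$,
$R_{ij}(E) = \lvert d_{gij}(E) - d_{kij}(E)\rvert$ with the gene-level
aggregate $R_j(G) = \sum_i R_{ij}(E)$. TF disruption scores can be
z-scored within each (individual, cell type) group
(`scale_tf_disruption()`); we use the sample standard deviation ($n-1$),
record the convention in the output, and return zeros with a `degenerate`
flag when a group has no spread, so cohort tables stay rectangular.
Thresholding helpers select the top decile (ties at the quantile are all
kept, making the mask order-independent) or apply the absolute
edge-disruption cutoff of 0.35; we apply that published cutoff to raw,
not scaled, edge disruption scores, matching the context in which it was
derived.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `upstream`, `downstream` | 750, 250 | promoter window around the TSS, bases in transcription direction |
| scan `p_max` | 1e-4 | motif-scan p-value cutoff on hits |
| `qbic_p_threshold` | 0.05 | significance for binding-effect predictions; interpreted as already corrected across a variant's predictions, since effect tables typically arrive pre-aggregated |
| `min_nonzero` | 50 | samples with nonzero expression a gene needs |
| `alpha` | 0.1 | message-passing update rate, in [0, 1) |
| `tol` | 1e-3 | convergence threshold (mean absolute change) |
| `max_iter` | 200 | iteration cap; exceeding it flags non-convergence rather than erroring |
| top `fraction` | 0.10 | tail selected by `threshold_top_fraction()` |
| edge-disruption `cutoff` | 0.35 | absolute variant-impacted threshold |

Genes are expected to contribute one designated TSS each; annotations
with several TSSs per gene should be reduced to a canonical TSS upstream
(a deliberate simplification — one promoter window per gene keeps the
eGene-adjacency rule unambiguous). Coordinates are converted from the
1-based conventions of VCF/eQTL/FIMO files to 0-based half-open form once
at parse time, so all internal interval logic shares a single convention.

## What the simulator emulates

`simulate_cohort()` generates a fully self-consistent cohort: a
one-chromosome annotation (TSS 10 kb apart, alternating strands), motif
occurrences placed inside promoter windows (density 0.35), a genotyped
cohort, an expression panel, a TF-interaction edge list, and two
ChIP-style binary truth networks that differ exactly at the planted
edges. Planted variants sit inside a motif occurrence inside their
eGene's promoter, carry a significant eQTL record with effect magnitude
around `beta_scale` (0.5) and a significant negative binding effect
around `q_scale` (0.5), and are drawn as Hardy–Weinberg genotypes at
allele frequency `maf` (0.3, a common variant as eQTL panels require).
Expression follows a linear TF-activity model: gene $j$'s expression in
sample $s$ is $\sum_i M_{ij} w_{ij} a_{is} (1 - \text{attenuation}
\cdot A/2) + \varepsilon$, where the attenuation factor (0.5) applies at
planted pairs according to the sample's own genotype, inducing both
coexpression structure and a genotype–expression association at planted
sites. Six decoy classes (two variants each) are emitted so that every
pipeline filter is exercised: a non-promoter eQTL, a non-significant
eQTL, a wrong-eGene eQTL, a positive binding effect, a non-significant
binding effect, and a qualifying variant that no individual carries.

The default dimensions — 5 TFs, 40 genes, 60 expression samples, 10
individuals, 8 planted disruptions — keep a full cohort analysis in the
low seconds while leaving enough planted and background edges for stable
rank statistics; they are the problem sizes used throughout the tests
and the acceptance analysis.

What the simulator does *not* emulate: linkage disequilibrium between
variants, trans-eQTLs, population structure, multi-allelic sites or
indels, expression count noise (noise is Gaussian), and realistic motif
redundancy between TFs. Recovery results on simulated cohorts therefore
demonstrate the pipeline's internal consistency — filters, arithmetic,
score propagation — not its accuracy on real multi-omic data, where
signal-to-noise is far less favorable.

## The recovery benchmark and its permutation control

`planted_edge_auc()` pools per-individual edge disruption scores and
measures, as a Mann–Whitney AUC, how well they separate planted, carried
disruptions (a planted edge in an individual who carries the planting
variant) from all other (individual, edge) observations. On default
cohorts this exceeds 0.99.

The matching no-signal control needs care. Because the candidate filters
pin prior penalties to the planted variants, planted edges remain the
*only* disruptable edges under any genotype shuffle, so a
planted-versus-unplanted contrast cannot fall to chance under
permutation. The question a genotype permutation does answer is: do the
scores still identify *which individuals* carry each planted variant?
`permuted_carrier_auc()` therefore shuffles the genotype vectors among
individuals (a uniformly drawn permutation — forbidding fixed points
would introduce a negative without-replacement dependence of order
$1/n$ between labels and scores) and computes a carrier-versus-noncarrier
AUC *within each planted edge*, where the two groups are exactly
exchangeable under the permutation, averaging over edges and 24
permutations. Stratifying by edge matters: pooled across edges, positives
over-represent high-carrier-frequency edges, whose scores run higher
under permutation, biasing the pooled null above 0.5. The stratified
control sits at 0.5 within sampling error (±0.05 at these cohort sizes),
while the unpermuted cohort scores near 1.

## Known limitations

* Uncertainty is not quantified: edge weights are point estimates and no
  statistical testing framework accompanies the networks.
* Only biallelic SNVs are modeled; indels and structural variants are
  skipped at VCF parsing.
* Significant-eQTL input limits the method to common variants.
* The eGene-adjacency rule ties each variant to one promoter; overlapping
  promoters of bidirectional gene pairs would double-count a shared
  variant (the simulator spaces promoters to avoid this; real
  annotations may not).
* Convergence of the damped updates is empirical, not proven; the
  `max_iter` guard with an explicit non-convergence flag is the safety
  net.

## A compact walk-through

```{r walkthrough, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 1))
res <- run_pipeline(co)

glance(res$baseline)            # iterations, convergence
tidy(res) |>                    # per-individual edge disruption table
  dplyr::arrange(dplyr::desc(d_edge)) |>
  head()

planted_edge_auc(res, co)                       # ~0.999
permuted_carrier_auc(co, n_perm = 24)$auc       # ~0.5
dosage_disruption(res, co)                      # monotone in allele count
```
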