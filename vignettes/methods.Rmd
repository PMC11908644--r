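---
title: "Window-based conservation scoring on pangenome graphs: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based conservation scoring on pangenome graphs: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panconserve)
```

# Scope and assumptions

`panconserve` scores intra-species conservation on a single-chromosome
pangenome variation graph. The unit of comparison is the *window* (bin), not
the nucleotide: a variation graph has no base-level multiple alignment, so
per-base conservation is not well defined on it, but segment sharing between
haplotype paths is. The method assumes:

* one chromosome per GFA file — paths spanning several chromosomes
  (translocations) are not supported and multi-seqid W-line input is
  rejected;
* at least two haplotype paths (pairwise similarity is undefined otherwise);
* haplotypes similar enough that anchor segments shared by *all* paths exist
  at roughly the window spacing (in practice ≥ ~98 % sequence identity; on
  highly divergent graphs boundary detection degrades and the scan
  degenerates toward a single whole-chromosome bin, with a warning);
* blunt segment concatenation: P-line overlap fields must be `*` or
  all-match CIGARs.

# The score

Within a bin, each haplotype's sub-path is reduced to a multiset of segment
traversal counts. Orientation is ignored: an inverted traversal carries the
same sequence content, and treating inversions as divergence would conflate
structural polarity with loss of homologous material. For two multisets the
length-weighted Jaccard index is

$$J(A,B)=\frac{\sum_g \min(c_A(g),c_B(g))\,\mathrm{len}(g)}
               {\sum_g \max(c_A(g),c_B(g))\,\mathrm{len}(g)},$$

averaged arithmetically over all $P(P-1)/2$ unordered path pairs, and mapped
to the score $x=-\ln\max(\bar J,\varepsilon)$.

Two conventions deserve justification:

* **Empty vs empty scores 1.** Two haplotypes that both deleted a region
  carry identical (null) sequence; scoring 0 would flag shared deletions as
  divergence.
* **Boundary segments are excluded from sub-paths.** Anchors are shared by
  construction; adding identical mass to both sides of a Jaccard comparison
  can only raise it (a property the test suite checks both ways), so
  including them would compress the dynamic range of the signal in exactly
  the windows where it matters.

## The Jaccard floor

$J=0$ (fully disjoint alleles) would map to an infinite score and break any
parametric fit. The floor is
$\varepsilon = 1/(1+\max_b W_b)$, where $W_b$ is bin $b$'s across-path union
weight — just below the smallest non-zero Jaccard any bin in this dataset
could produce, so flooring never reorders non-zero scores. It is recorded in
the model dump and overridable (`jaccardFloor`).

# Binning

Boundary candidates are segments traversed **exactly once** by every path.
Mere presence would be a weaker criterion; single-copy occurrence makes the
left/right sub-path extraction unambiguous and guards against anchors inside
repeats. Mixed orientations are accepted only when explained by a path's
dominant orientation (majority flip over all shared single-copy segments),
so a globally reverse-complemented haplotype keeps its anchors while an
anchor inside a local inversion is dropped; `strictForward = TRUE` restricts
candidates to all-forward occurrences.

Selection is greedy left-to-right (first candidate, then the first candidate
starting ≥ *s* after the previous selection's end). Greedy is deterministic,
O(n), and the method only needs *approximately* regular windows — an optimal
segmentation would buy nothing measurable.

**Bin intervals are cut at boundary midpoints.** The natural convention
"from the end of the left anchor to the start of the right anchor" leaves
the anchors' own bases in no bin, so the intervals would not tile the
reference — and a score track with holes at every anchor complicates all
downstream interval arithmetic. Cutting at anchor midpoints keeps the
content convention (sub-paths exclude anchors) while the *intervals*
partition `[0, L)` exactly; each anchor's bases are split between its two
adjacent bins. Flank bins before the first and after the last anchor close
the tiling; zero-width flanks are dropped.

Window sizes of 1 000–100 000 bases are sensible; 10 000 is the default
(small windows fragment genes, large ones dilute local signal).

# The mixture null model

Scores of conserved windows concentrate in a narrow, approximately Gaussian
mode near 0. Divergent windows form a heavy right tail incompatible with
that Gaussian; it is well described by a log-normal. The null is

$$f(x)=\pi\,\phi\!\left(\frac{x-\mu}{\sigma}\right)\Big/\sigma
      +(1-\pi)\,\mathrm{LogN}(x;\mu_L,\sigma_L),\qquad \pi=0.5
      \text{ by default.}$$

The equal-weight combination treats the two fitted shapes as an average of
two candidate descriptions of the same distribution; with
`estimateWeight = TRUE`, $\pi$ is re-estimated by EM iterations that update
only the weight (component parameters frozen, stop at $|\Delta\pi|<10^{-6}$
or 200 iterations). The Gaussian mass below 0 is not truncated: $\mu$ is
typically many $\sigma$ above 0 and the residual mass is negligible.

## Fitting procedure

The two components are fitted in stages, deterministically:

1. **Gaussian bulk** (`fitGaussianCore`): iterative 3σ clipping with
   median/MAD re-estimation. Initialisation uses left-hand quantiles only —
   location Q25, scale $(Q_{25}-Q_{10})/(z_{0.25}-z_{0.10})$ — because the
   contamination is entirely on the right: for a pure Gaussian these start
   values are mildly conservative and the clipping converges to the full
   sample, while under heavy right contamination the initial window already
   excludes the tail. Simple fixed-quantile estimators cannot serve both
   regimes (under 50 % contamination the sample median sits between the
   components), which is why an iterative scheme is used. Scores of exactly
   0 ($J=1$) are kept: they are the most conserved observations, not
   artifacts. An all-equal score vector yields a machine-epsilon-scaled
   fallback σ with a warning, and every bin is then classified neutral.
2. **Log-normal tail** (`fitLognormalTail`): log-moment fit on scores above
   $\mu + k\sigma$ ($k=2$ by default; `tailK`). Gaussian observations leak
   past any such threshold (≈ 2.3 % of the Gaussian mass at $k=2$) and,
   sitting far below the tail's log-mean, would bias $\mu_L$ downward by
   roughly the leak fraction times the log-gap; they are therefore
   down-weighted by responsibility iterations with the Gaussian fixed and
   equal priors. With fewer than 10 tail points the fit falls back to all
   positive scores (warning); with no positive scores the model is
   *tail-free*: $\pi=1$ and divergence calls are disabled.

With fewer than 30 scores a warning flags the fit as unstable — at the
default window size that corresponds to a chromosome shorter than ~300 kb.

## Calibration and classification

P-values are tails of the full mixture CDF ($p_{\mathrm{cons}}=F(x)$,
$p_{\mathrm{div}}=1-F(x)$), not of the Gaussian alone: one coherent null for
both calls. Because $F$ is continuous, reclassifying draws from the fitted
model flags each tail at rate α by construction — the test suite checks this
within binomial error at $n=10^4$. The significance level α (default 0.05)
is **per tail** and uncorrected by default, favouring fidelity to common
practice for genome scans of this kind; `fdr = TRUE` applies
Benjamini–Hochberg per tail. Adjacent same-class significant bins are merged
into maximal regions annotated with the run's minimum p-value
(BED score $=-10\log_{10}p$, capped at 1000).

# The synthetic generator

`simulatePangenome()` emulates the graph structure the method assumes: a
backbone of universal anchors (`A0 … An`, default 50 bp) interleaved with
bubble regions (default 200 bp). Each region is realized as fixed-length
chunks (default 20 bp); haplotype *h* keeps each reference chunk with
probability $1-d_r$ and otherwise receives a private segment of the same
length, so the region's divergence parameter $d_r$ is the **expected
fraction of region sequence private to each haplotype**. With probability
`svProbability` (default 0.05) a haplotype's whole region allele is deleted
or duplicated — segment-level structural variants. The first haplotype is
the reference and is exempt from SV events (so ground-truth reference
intervals remain exact) but receives substitutions like any other. All
randomness derives from `seed`; identical parameters give byte-identical
GFA.

Defaults (4 haplotypes, 20 regions, divergence linearly spaced 0–0.9)
produce a ~5 kb chromosome whose bins, at `windowSize = 200` (one bin per
region — the greedy selector then picks every anchor and skips
mid-region candidates), rank by injected divergence with Spearman ρ
typically > 0.95. Ranking experiments are run with `svProbability = 0`: SV
events are a second, binary divergence source that would confound a
monotonicity check of the substitution parameter.

**What the generator does not emulate:** base-level mutation followed by
graph construction (divergence is injected at segment granularity, which is
exactly what the method consumes — it never inspects nucleotide identity),
nested bubbles, realistic coalescent structure, length-changing alleles
(private segments match the reference allele length), and translocations.
Passing tests on synthetic graphs therefore validate the algorithmic
contract — parsing, anchoring, tiling, similarity, fitting, calling — not
the biological realism of any particular graph construction pipeline.

# Numerical and degenerate-input choices

* Natural log for the score map; the base only rescales the distribution
  and the mixture fit is base-invariant.
* 0-based half-open coordinates internally and in all TSV/BED/bedGraph
  output; `GRanges` objects returned to R are 1-based as usual.
* Output numbers are formatted with fixed `sprintf` precision so identical
  runs are byte-identical.
* Ties in boundary selection cannot arise (candidates are strictly ordered
  by reference start); ties in region ranking are broken by region index.
* Degenerate inputs: all-equal scores → neutral everywhere (fallback σ);
  no candidates → one whole-chromosome bin, warning; no positive scores →
  tail-free model, divergence disabled; empty sub-path pairs → $J=1$.
* A path whose selected-boundary occurrences are neither increasing nor
  decreasing (a rearrangement the model cannot represent) aborts the run
  with an explicit error rather than silently mis-extracting sub-paths.

# Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data
chosen to exercise every code path while completing in seconds: 1000
random multiset pairs against a brute-force Jaccard oracle; 50 seeded graphs
for tiling/universality; 10 replicates of the 20-region ranking experiment;
20 replicates of mixture recovery at $n=10^4$ scores
($0.5\,N(0.05,0.02^2)+0.5\,\mathrm{LogN}(0,0.5^2)$, and weight recovery at
$\pi=0.8$); calibration at $n=10^4$ null draws.

# Known limitations

* The reference path choice (default: first in file) affects coordinates
  and boundary spacing but not the similarity values themselves.
* Windows are only approximately *s* long: anchor availability dictates the
  actual cut points, and bins in anchor-poor regions can be much longer.
* Single-copy universality is strict: in graphs where a locus is duplicated
  in even one haplotype, no anchor exists there and windows widen.
* p-values are model-based, not empirical; with few bins (< 30) the fit, and
  hence the calls, are unreliable and flagged by a warning.
* No intra-run parallelism: one chromosome is one process; bins are
  independent, so coarse parallelism across chromosomes is the intended
  scaling route.
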