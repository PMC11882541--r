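---
title: "Multi-evidence screening of cis-regulatory modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence screening of cis-regulatory modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscreen)
```

# The problem

Developmental genes are controlled by distal cis-regulatory modules (CRMs,
enhancers) that can sit hundreds of kilobases from the promoter they serve.
Before any wet-lab validation, candidate CRMs around a locus of interest are
prioritized from several independent lines of evidence:

1. **Cross-species conservation** — functional non-coding elements evolve
   slowly, so windows of high percent identity in a pairwise alignment mark
   candidates.
2. **Activation-associated chromatin marks** — H3K27ac, H3K4me2, p300,
   RNA-polymerase II and Med12 occupancy over a region suggest enhancer
   activity; H3K27me3 marks Polycomb-repressed chromatin and argues against
   it.
3. **Predicted transcription-factor binding sites** — a region with no
   binding sites cannot integrate signalling input.
4. **3-D context and accessibility** — an enhancer must share a
   topologically associating domain (TAD) with its target promoter and be
   in open chromatin in the tissue of interest.

`crmscreen` implements this cascade end to end at desk scale, together with
the downstream validation analytics a reporter-assay study needs: design of
binding-site disruptions, normalization and many-to-one testing of
fluorescence readouts, and single-cell co-expression summaries. Every stage
is testable against synthetic loci with planted ground truth.

# Conservation calling

The identity profile assigns every reference base the fraction of matches
in a `window_bp`-base window of reference bases centred on it (shifted
inward at the ends so each window holds exactly `window_bp` bases). Gaps
and `N` count as mismatches. Maximal runs at or above `min_identity`
(default 0.7 — at least 70% cross-species identity) become conserved
regions; runs separated by fewer than `window_bp / 2` sub-threshold bases
are merged so one element is not fragmented into slivers.

Filtering then removes regions that touch an annotated exon or a
blacklisted previously described element by one or more bases, and regions
outside the closed length interval `[min_len, max_len]` (defaults 150 and
2100 bp, the size range of retained candidates; the bounds are treated as
inclusive because they describe retained elements, not an exclusion rule).

The profiling window defaults to 100 bp, the granularity of classical
alignment-browser conservation displays; it is configurable. Note the
window induces *edge erosion*: for a block of internal identity $p_b$ in
spacers of identity $p_s$, the called edge sits about
$w\,(0.7 - p_s)/(p_b - p_s)$ bases inside the true edge, which is why
recovery is only asserted to half a window per edge.

# Motif scanning with exact p-values

A JASPAR-style count matrix becomes a position weight matrix with
log-odds entries

$$s_{b,j} = \log_2 \frac{(c_{b,j} + q\,\pi_b) / (\sum_b c_{b,j} + q)}{\pi_b},$$

with background $\pi$ (default uniform) and total pseudocount $q$ (default
0.8, split by background as in common JASPAR practice). The score of a
window is the sum of its per-column entries.

The null distribution of the score — a single window drawn from the
background — is computed **exactly** by convolving the four-valued
per-column score distributions, after rounding each column score to a
multiple of `granularity` bits (default 0.01). The rounding error of any
word score is bounded by $L \cdot \text{granularity}/2$. Scanning uses the
same rounded units, so scan p-values agree with the distribution exactly,
and the whole machinery is validated against brute-force enumeration of
all $4^L$ words. A p-value is the tail mass at or above the observed
score; `exact_pvalue_threshold()` returns the smallest representable score
whose tail mass is at most `alpha`. If rounding collapses the whole
distribution to a single atom the granularity is too coarse and the
computation refuses to proceed.

Both strands are scanned; a minus-strand hit is reported on the interval
of the matched window in reference coordinates with a strand flag. Windows
containing `N` are skipped. The binding-site evidence cutoff used by the
screen is `p < 1e-2` per window, the conventional track threshold for
binding-site predictions.

# Mark evidence and labelling

A mark is *present* on a region if at least one of its peaks overlaps the
region by one or more bases (no minimum overlap fraction is imposed —
peaks and regions are both hundreds of bases, so a 1 bp rule is the least
arbitrary choice). Marks count as **dataset types**, not peak instances:
two H3K27ac peaks are still one mark. A region passes the screen iff it
carries at least `min_marks = 3` distinct activation-associated marks
(H3K27ac, H3K4me2, p300, RNAP2, Med12 — RNAP2 and Med12 are treated as
two evidence sources, configurable), no repressive mark (H3K27me3), and at
least one binding-site hit.

Passing candidates are labelled relative to the promoter: negative
integers upstream (by gene strand), positive downstream, numbered 1..k per
side by increasing midpoint distance, ties broken by start coordinate. A
candidate overlapping the promoter has no defined side and is an error.
The promoter is supplied as an interval (TSS ± 500 bp is a reasonable
default when only a TSS is known).

# TAD calling

The caller is an insulation-square method in the spirit of the
hicFindTADs tool, not a bit-identical reimplementation. For bin $i$ and
window $w$ bins, the insulation score is the mean of the contact submatrix
$M[i-w..i-1,\; i+1..i+w]$ — the contacts crossing bin $i$ up to depth
$w \cdot \text{bin\_bp}$. Depths span `min_depth_bp` to `max_depth_bp`
(defaults 3000 and 31500 bp) at `n_scales = 3` evenly spaced bin
multiples.

Boundary acceptance has three ingredients, all fixed a priori:

* **Candidate minima.** The scale-averaged profile is smoothed with a
  centred 3-bin running mean (removes single-bin noise wiggles without
  moving minima) and candidate boundaries are bins that are the minimum
  within ± the smallest window size.
* **Prominence (`delta`, default 0.01).** On the min–max normalized
  profile, the smaller of the rises to the highest profile value between
  the candidate and its neighbouring candidate (or profile edge) on each
  side must reach `delta`.
* **Rank-sum test (`threshold`, default 0.05).** One-sided Wilcoxon
  rank-sum of intra-domain contacts (off-diagonal cells of the two
  flanking squares) against cross-boundary contacts (the cross
  rectangle), required at *every* scale, Bonferroni-corrected over
  candidates — the same semantics the reference tool attaches to its
  threshold. Test windows are clipped at neighbouring candidate
  boundaries; without clipping, a mid-domain bin whose large-scale window
  spans a real boundary inherits that contrast and tests significant for
  the wrong reason. Significance is required at every scale rather than
  on a pooled sample because a candidate is *selected* as an insulation
  minimum, which biases a single pooled comparison toward acceptance at
  pure-noise minima.

Domains tile the matrix span between consecutive accepted boundaries. All
domain queries are midpoint-based and domains are half-open, so a midpoint
exactly on a boundary belongs to the downstream domain. The matrix is
assumed already balanced/normalized: no ICE/KR correction is applied.
CTCF concordance is the fraction of boundary-bin midpoints within
`tol_bp` of a CTCF peak midpoint, and is `NA` (not 0) when there are no
boundaries.

# Disruption design

A disruption plan overwrites a core binding-site sequence (e.g. the Ets
core `GGAA`, the Tcf/Lef core `SCTTTGATS`, the homeodomain core `TAATTA`)
with a restriction-enzyme recognition site using substitutions only — no
indels, so coordinates are preserved and the edit is verifiable by digest.
Every placement of every catalog enzyme overlapping the core is scored by
substitution count (degenerate enzyme positions keep a compliant reference
base; otherwise the lexicographically smallest compatible base is used);
the fewest-substitution placement wins, ties going to the leftmost
placement and then catalog order. A plan is only *feasible* if the edited
sequence no longer matches the core at any offset overlapping the original
core, and only *accepted* if re-scanning wild type and mutant with the
discovery PWM set at the discovery cutoff (`1e-2`) creates no new hit.
Site spacings are reported edge-to-edge (overlap collapses to zero).

# Reporter statistics

Per-embryo GFP intensity is normalized by the RFP transfection-control
channel. Construct groups are compared to a control construct with a
one-way ANOVA followed by single-step Dunnett comparisons: the adjusted
p-value of comparison $i$ is $P(\max_j |T_j| \ge |t_i|)$ under the
multivariate-$t$ null with $N-k$ degrees of freedom and correlations
$\sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}$, evaluated with
`mvtnorm::pmvt()`. A Monte-Carlo evaluation of the same null is available
(`n_mc`) and is used as a cross-check. Adjusted p-values are clamped to be
at least the unadjusted two-sided $t$ p-value. Identical constant groups
return a zero difference with p = 1; zero within-group variance with
differing means is a degenerate-input error, as is any group with fewer
than two embryos. The wild-type-versus-mutant contrast uses the pooled
two-sample Student's $t$ (two-tailed).

# Co-expression

Cells are classified by a normalized-expression threshold of 0.5 for the
marker gene; *lower than* 0.5 defines the negative class, so a cell at
exactly 0.5 is positive. Candidate transcripts use the same threshold
(configurable; nothing in the data argues for a different one). Summaries
report, per candidate, expressing-cell counts, co-expressing counts, and
both conditional fractions. Batch correction, differential expression and
embeddings are deliberately out of scope — they are upstream workflow
steps, not part of the quantity recorded here.

# Synthetic fixtures and what passing tests mean

The generators are first-class, tested code. `synth_locus()` plants 49
conserved blocks (12 passing the screen, 10 upstream / 2 downstream of the
promoter — the fixture's locus-scan convention), writes every input file
the screen consumes, and returns the full truth record. Block identity is
0.9 against 0.45 spacers, giving a ~5 σ margin at the 0.7 threshold for a
100 bp window; planted block lengths are sampled from [300, 2000] bp so
edge erosion (above) cannot push a planted block below the 150 bp filter
floor or above the 2100 bp ceiling. Negatives fail through mark evidence
(0–2 active marks, or ≥3 active marks vetoed by a repressive peak) rather
than through the binding-site requirement, because at `p < 1e-2` per
window any few-hundred-bp sequence contains chance hits.

`synth_contact_matrix()` defaults to 200 bins of 500 bp with boundaries at
bins 81 and 131, a 5-fold intra/inter contrast and multiplicative
lognormal noise of CV 0.3. `synth_expression()` draws the marker bimodally
around the 0.5 threshold and candidates as Bernoulli on-states with
probabilities $p_1$ (marker-positive cells) and $p_2$ (marker-negative).
`synth_fluorescence()` plants group effects in units of the control SD.
One master seed fans out to per-stream sub-seeds, so every generator is
byte-deterministic given `(config, seed)`.

What the fixtures do **not** emulate: alignment gaps and indel drift,
distance-dependent Hi-C decay within domains, peak-calling noise at mark
boundaries, doublets and dropout in expression data, or non-normal
fluorescence error. Passing tests therefore demonstrate correctness of the
procedures under their stated models, not performance on real tracks; on
real data the conservation window, mark catalogue and TAD depths should be
revisited against the tissue and assay at hand.

Problem sizes used by the test-suite and the acceptance script — an
~87 kb locus, 200-bin matrices, 1500-cell expression matrices, 2000-rep
null calibrations — were chosen so each stage's statistical margins are
meaningful (binomial SEs of a percent or two) while a full run stays in
the minutes range.

# Known limitations

* Cross-species coordinate mapping (liftover) is not implemented: one run
  works in one reference coordinate system, and multi-species support is a
  composition of pairwise runs.
* The TAD caller does not reproduce the reference tool bit-for-bit, and no
  loop or compartment analysis is attempted.
* The per-window p-value semantics of motif hits ignores multiple testing
  across windows; it is an evidence flag, not a discovery claim.
* The screen's headline counts on any real locus depend on inputs
  (alignment source, peak calls) that this package deliberately treats as
  given.
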