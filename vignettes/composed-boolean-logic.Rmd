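---
title: "Composed Boolean logic in bipartite models of gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composed Boolean logic in bipartite models of gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfcompose)
```

## The model

In a unipartite Boolean network a gene with $k$ regulators updates through an
arbitrary Boolean function (BF) $f\colon\{0,1\}^k \to \{0,1\}$, one of
$2^{2^k}$ possibilities. Bipartite models distinguish genes from the
*transcriptional regulators* (TRs) that act on them — a single transcription
factor (TF), a heteromeric TF complex, or a *cis*-regulatory element bound by
several TFs. A gene regulated by $r$ TRs, the $i$-th driven by $t_i$ genes,
carries the **composition structure** $\{t_1,\dots,t_r\}$ with
$k=\sum_i t_i$, and its effective update rule is the **composed function**

$$h(x_1,\dots,x_k) = g\big(p_1(x_1,\dots,x_{t_1}),\ \dots,\
p_r(x_{k-t_r+1},\dots,x_k)\big),$$

where $g$ (the gene's response to its TRs) and the $p_i$ (each TR's response
to its input genes) are arbitrary Boolean functions of the stated arities.
The structures $\{k\}$ and $\{1,\dots,1\}$ are *trivial* — they realize every
$k$-input function — while every other structure restricts the reachable
logic, often severely. Because gene labels are biologically meaningful, the
package additionally closes composed sets under all $k!$ relabelings of the
inputs (which also closes them under input negation); both the closed and the
base ("blocks in sorted order") sets are exposed, since their sizes are not
related by $k!$ due to symmetries.

Four classes of update rules are widely taken as biologically meaningful:

* **unate** (UF): monotone increasing or decreasing in every input;
* **canalyzing** (CF): some input value forces the output;
* **nested canalyzing** (NCF): canalyzing recursively, down to a last input
  whose two values yield complementary outputs;
* **read-once** (RoF): expressible with AND/OR/NOT using each variable
  exactly once.

`bfcompose` enumerates composed sets and class sets exhaustively for
$k \le 5$, measures their overlaps, and tests whether a catalog of
empirically observed update rules is enriched for either kind of restriction.

## Representation and conventions

A function is stored as the integer bitmask of its $2^k$-row truth table,
held in a double (exact well beyond the $2^{32}$ masks needed at $k=5$). The
row index encodes the input assignment with $x_1$ as the **most significant
bit**, so row 0 is the all-zero assignment; the text serialization
(`k` + bitstring, row 0 first) fixes the same convention. The convention is a
genuinely free choice — permutation-closed counts are invariant under it —
but it is held fixed package-wide because base sets and single functions are
not invariant.

Degenerate functions (constants, inessential inputs) are legal values.
They count as unate and canalyzing (the definitions hold vacuously) and are
excluded from the nested canalyzing and read-once classes, whose definitions
force every input to matter. This choice is validated by the enumeration
results themselves: with it, the canalyzing counts at $k=2,3,4$ are 14, 120
and 3514, matching the published overlap tables the test suite asserts.

## Enumeration algorithms

**Composed sets.** A naive enumeration evaluates
$2^{2^{t_1}}\cdots 2^{2^{t_r}}\,2^{2^r}$ compositions — about $6.7\times 10^7$
for $\{1,1,1,2\}$. The package instead observes that a choice of inner
functions $(p_1,\dots,p_r)$ only matters through the *coloring* it induces on
the $2^k$ truth-table rows (which cell of $\{0,1\}^r$ each row maps to), and
that, because $g$ ranges over *all* $r$-input functions, colorings that
differ by a relabeling of cells generate identical sets. Colorings are
therefore canonicalized and deduplicated, after which all outer functions are
applied at once as a single integer matrix product. Permutation closure then
follows the direct route: apply all $k!$ row remaps to the base set and
deduplicate. The full $k=5$ tier (including $\{1,4\}$ and $\{1,1,1,2\}$)
completes in about two minutes on one CPU; everything is deterministic and
memoized in memory per session. A disk cache was considered and rejected:
regeneration is fast enough that content invalidation would be the only thing
a cache could get wrong. An independent brute-force oracle (the direct
product enumeration for $\{1,2\}$) pins the algorithm in the test suite.

**Class sets.** Each class has a structural enumerator and an independent
definition-driven checker, compared against each other on the full function
space for $k \le 4$:

* NCF: iterate every input permutation and every pair of canalyzing-value /
  canalyzed-output vectors in the nested cascade, deduplicate
  ($k!\,4^k$ constructions at most);
* RoF: recursive formula construction over all set partitions of the
  variables with AND/OR connectives and signed literals, deduplicated by
  truth table (formula-level symmetries are deliberately ignored — the
  bitmask is the identity);
* CF: union of the $4k$ half-space-constant families;
* UF: monotone functions via the pairing recursion
  ($f$ monotone on $k$ inputs iff $f=(f_0,f_1)$ with both halves monotone
  and $f_0 \le f_1$ pointwise), closed under input negations.

The read-once *checker* is a genuine recognition algorithm, not a set lookup:
a function with all inputs essential is read-once iff it is a literal, or it
(or its complement, by De Morgan) factorizes across some bipartition of its
variables into the product of its two OR-projections, each recursively
read-once. Since every read-once function is unate, the cheap vectorized
unateness test prunes the recursion.

## Enrichment statistics

For a catalog of observed update rules (one regulatory instance per row,
duplicates legitimate), all statistics are stratified by $k$; the null
ensemble draws uniformly from all $2^{2^k}$ functions. For a target set $T$,
$f_0 = |T|/2^{2^k}$, $f_1$ is the observed fraction of the $M$ records at
that $k$ falling in $T$, the enrichment factor is $E=f_1/f_0$, and the
one-sided p-value is the exact upper binomial tail
$\sum_{m \ge M f_1} \binom{M}{m} f_0^m (1-f_0)^{M-m}$, computed through the
survival function. The sum starts at the observed integer count, with no
continuity correction; depletion is reported through $E<1$ without a second
test, and no multiple-testing correction is applied by default (the CLI can
append Bonferroni-adjusted columns). Relative enrichment $E_R$ conditions on
membership in $T$: with $T_s \subseteq T$, $f_{s,0}=|T_s|/|T|$ and $f_{s,1}$
the fraction of in-$T$ records in $T_s$, on $M_T$ conditional draws. The
disjoint-region analysis applies the plain enrichment factor to
$T_C \cap T_s$, $T_C \setminus T_s$ and $T_s \setminus T_C$, flagging the
third region not-applicable when the class is contained in the composed set.

Published enrichment values for the curated collection of 2687 update rules
from 88 reconstructed models depend on that external dataset and are not
recomputed here; the statistics are instead validated on synthetic mixture
catalogs with known ground truth (below). Any catalog in the simple TSV
layout (`source_id`, `node_id`, `k`, `output_bits`) can be analyzed directly.

## The enhancer co-binding rule

The *cis*-regulatory module quantifies how often enhancers are bound by two
or more TFs — the situation that makes an enhancer a multi-input TR and hence
a source of non-trivial composition structures. A TF **binds** an active
enhancer iff both the **midpoint** and the **summit** of one of its ChIP-seq
peaks fall within the enhancer interval. Coordinates are 0-based half-open
(BED); the midpoint of an even-length peak is the floor of the average
(left-biased) and "within" excludes the right boundary. These two rounding /
boundary choices are documented conventions, not inferred from any published
analysis, and the summary statistics are insensitive to them away from exact
boundary ties. Summit offsets of $-1$ (absent) are rejected by default; an
explicit fallback substitutes the midpoint with a warning. Replicate peak
files merge under one TF name through a manifest TSV, and a TF counts once
per enhancer no matter how many of its peaks bind.

## Synthetic data: what it emulates and what it does not

`simulate_catalog()` draws each record from a weighted mixture — a uniform
background plus spikes of a class or composed set — emulating the one robust
statistical feature of curated model collections: an excess of biologically
meaningful logic over the uniform ensemble. It deliberately does *not*
reproduce the in-degree distribution, per-model record correlation, or
curation biases of real collections, so passing recovery tests demonstrates
correctness of the statistics, not realism of the null. Default test
settings (k = 3, n = 2000 records, NCF weight 0.3, 20 seeds) give closed-form
expected fractions (e.g. $0.3 + 0.7\cdot 64/256 = 0.475$) that the measured
values must match within three binomial standard deviations.

`simulate_cobind_fixture()` plants a known TF-enhancer binding matrix:
enhancers of 600 bp separated by four widths on a synthetic chromosome, bound
peaks of 240 bp placed wholly inside the enhancer, and — for a controllable
fraction of unbound pairs — near-miss peaks straddling the enhancer's left
edge so that exactly one of midpoint/summit falls outside. Widths are
ENCODE-typical scales; the geometry is validated (an enhancer narrower than a
peak is rejected). Recovery of the planted per-enhancer counts must be exact.

## Numerical and design notes

* All masks, set operations and matrix products stay within exact double
  integer range ($< 2^{53}$); no randomness exists anywhere in the
  enumeration path, so results are bit-identical across runs.
* Exhaustive operations are capped at $k=5$ ($2^{32}$ truth tables is the
  practical limit of enumeration); single-function operations accept any
  $k$ that fits memory. Trivial structures at $k=5$ are counted analytically
  rather than materialized.
* The binomial tail is exact (survival function), checked against direct
  summation to 12 significant digits for $M \le 50$.
* Inner-function blocks attach to consecutive variables in sorted-part
  order; this matters only for base (non-closed) sets, where it reproduces
  the published base counts (e.g. 88 for $\{1,2\}$ versus 152 closed).
* The shared-input generalization (the same gene feeding two TRs) has no
  defined semantics here and is out of scope.

## Known limitations

* No closed-form counting: everything is enumeration, hence the $k \le 5$
  cap.
* The read-once recognizer is exponential in $k$ in the worst case —
  irrelevant at $k \le 5$ but not a general-purpose algorithm.
* Enrichment p-values assume independent draws within a stratum; records
  from the same model are correlated in real catalogs, so p-values there are
  anti-conservative and should be read as rankings.
* The co-binding analysis takes enhancer calls as given and does not assign
  enhancers to target genes, so it bounds the prevalence of multi-TF TRs
  rather than reconstructing composition structures.

## Problem sizes used by the test suite

Tests enumerate every non-trivial structure at $k\le5$ (the largest,
$\{1,1,1,2\}$, has 3,446,488 closed members), the four class sets at
$k\le5$, full-space checker/enumerator agreement at $k\le4$ (65,536
functions), mixture recovery on 20 catalogs of 2000 records, and co-binding
fixtures of 5-8 enhancers with planted truth.
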