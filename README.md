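# bfcompose

Logic rules available to genes in **bipartite Boolean models of gene
regulation**, for systems biologists who work with Boolean network models
and want to know how strongly biology constrains an update rule.

In a bipartite model a gene is driven by *transcriptional regulators* (TRs)
— single transcription factors, heteromeric TF complexes, or *cis*-regulatory
elements bound by TFs. A gene with `r` TRs, the i-th fed by `t_i` genes,
carries the *composition structure* `{t_1,...,t_r}` (with `k = Σ t_i`
inputs), and its effective update rule is the *composed function*

    h(x_1..x_k) = g(p_1(x_1..x_{t_1}), ..., p_r(..., x_k))

over all choices of the inner functions `p_i` and outer function `g`.
`bfcompose` answers, by exhaustive enumeration for `k ≤ 5`:

* how many of the `2^(2^k)` Boolean functions each structure allows, with
  and without closure under input relabeling (`enumerate_composed()`,
  `composed_fraction()`);
* how those sets overlap each other (`intersection_counts()`) and the four
  biologically meaningful classes — unate, canalyzing, nested canalyzing,
  read-once (`enumerate_class()`, `is_unate()`, `is_canalyzing()`,
  `is_ncf()`, `is_rof()`, `class_overlap()`);
* whether a catalog of empirically observed update rules is enriched for a
  set, with exact one-sided binomial p-values (`enrichment_factor()`,
  `relative_enrichment()`, `disjoint_enrichments()`);
* how often enhancers are co-bound by several TFs — the empirical signature
  of multi-input TRs — under the rule that a TF binds an enhancer iff both
  the midpoint and the summit of a ChIP-seq peak fall inside it
  (`read_narrowpeak()`, `cobinding_summary()`);
* synthetic catalogs and co-binding fixtures with planted ground truth for
  testing all of the above (`simulate_catalog()`,
  `simulate_cobind_fixture()`).

## Worked example

```r
library(bfcompose)

# the {1,2} structure: one single-TF regulator and one two-input TR
s <- enumerate_composed("1,2")                       # permutation-closed
length(s)                                            # 152
length(enumerate_composed("1,2", permutation_closed = FALSE))  # 88
composed_fraction("1,2")$fraction                    # 0.59375

# nested canalyzing functions are exactly the most restricted core
length(enumerate_class("NCF", 3))                    # 64
class_overlap("1,2", "NCF")                          # 64  (all of them)

# is x1 OR (x2 AND x3) a composed / nested canalyzing / read-once rule?
h <- bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)
is_ncf(h); is_rof(h)                                 # TRUE TRUE

# enrichment of the composed set in a catalog with a 30% NCF spike
cat3 <- simulate_catalog(3, 2000, c(NCF = 0.3, uniform = 0.7), seed = 1)
enrichment_factor(cat3, s, "{1,2}")
#>   k target_label    M m_obs      f0     f1   factor      p_value
#> 1 3        {1,2} 2000  1441 0.59375 0.7205 1.213474 2.290361e-32
```

So 72.1% of the simulated records are compatible with `{1,2}` against 59.4%
expected under uniform random rules (the closed-form mixture expectation is
`0.3 + 0.7 * 0.59375 = 0.716`): enrichment factor 1.21, and the exact
binomial tail says chance cannot plausibly explain it — the planted
nested-canalyzing spike drives composed-set enrichment, the package's core
statistical observation.

A command-line interface wraps the same functions:

```sh
BFC=$(Rscript -e 'cat(system.file("cli", "bfcompose.R", package = "bfcompose"))')
Rscript $BFC compose --structure 1,2 --out out/        # 152-row catalog TSV
Rscript $BFC classify --k 3 --class NCF --out out/     # 64-row catalog TSV
Rscript $BFC cobind --manifest manifest.tsv --enhancers enhancers.bed --out out/
```

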