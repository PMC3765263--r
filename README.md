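# mircycle

Small-RNA sequencing analysis of hair-follicle cycling microRNAs, as a
tested R package.

Hair follicles cycle through growth (anagen), regression (catagen) and
quiescence (telogen), and microRNAs shift markedly between these stages
— in fibre-producing goats this underlies cashmere growth. The standard
way to profile them is a three-library small-RNA sequencing study: clean
the reads, collapse them into unique tags, map and annotate them,
quantify known miRNAs, discover novel ones from hairpin structure, and
compare stages. mircycle implements that whole pipeline with tidyverse
semantics (tibbles in and out, `tidy()`/`glance()`/`autoplot()`
methods), plus a synthetic-data generator that plants known miRNAs,
contamination and fold changes so every stage can be validated against
ground truth.

## What it computes

* **Read cleaning** — each high-quality read is classified once, in
  precedence order: no 3' adapter, empty insert, 5'-adapter
  contamination, polyA, shorter than 18 nt, clean; the categories
  partition the high-quality reads, reproducing the accounting tables of
  small-RNA sequencing reports (`filter_reads()`,
  `filter_accounting()`).
* **Mapping and annotation** — exact full-length matching on both
  strands; one class per tag by priority ncRNA (GenBank > Rfam) >
  miRNA > repeat > exon > intron; rRNA fraction < 40% as the
  animal-sample quality rule (`map_tags()`, `annotate_tags()`).
* **Conserved miRNAs** — tags credited to reference matures within
  ±4 nt / ≤2 mismatches; TPM = count/clean total × 10⁶; stage Venn
  membership and top-10 tables (`match_known_mirnas()`,
  `stage_membership()`, `top_expressed()`).
* **Folding** — minimum-free-energy secondary structure under a per-pair
  model (GC −3, AU −2, GU −1 kcal/mol), exact dynamic programming in
  C++, optional ViennaRNA backend (`fold_mfe()`).
* **Novel miRNAs** — hairpin candidates from unannotated tag clusters,
  scored against the twelve Mireap-style criteria (mature 18–26 nt, MFE
  ≤ −18 kcal/mol, ≥ 14 miRNA/miRNA\* pairs, bulge ≤ 4, asymmetry ≤ 5,
  space ≤ 35 nt, cut-site depth ≥ 3, ≤ 20 loci, …)
  (`predict_novel_mirnas()`).
* **Targets** — ungapped antiparallel scan of 3'UTRs under positional
  mismatch rules (≤ 4 weighted mismatches with G:U = 0.5, none at
  positions 10–11, ≤ 2.5 in 1–12, no adjacent mismatches in 2–12, ≤ 2
  consecutive anywhere) and a duplex energy ≥ 75% of the perfect
  complement (`predict_targets()`).
* **Differential expression** — the exact two-library test
  p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)), r = N2/N1, two-sided as
  twice the smaller tail; 0.01 revision of zero TPM; log2 fold changes;
  the printed significance and ratio classes; average-linkage profile
  clustering (`ac_pvalue()`, `diff_expression()`, `cluster_profiles()`).
* **Enrichment** — hypergeometric upper tail
  P = 1 − Σᵢ₌₀^{m−1} C(M,i)C(N−M,n−i)/C(N,n), Bonferroni for GO, BH-FDR
  for pathways, both at 0.05 (`hypergeom_p()`, `run_enrichment()`).

## Worked example

Simulate a full study (three libraries × 50,000 reads, 30 conserved + 8
novel planted precursors) and run the pipeline:

```r
library(mircycle)

cfg <- sim_config(seed = 42)
sim <- simulate_srna_study(cfg)
dir <- file.path(tempdir(), "demo")
write_simulation(sim, dir)              # FASTQ + FASTA + BED + TSV + JSON
res <- run_pipeline(simulation_paths(dir))

filter_stats_of(res$libraries$anagen)
#> # A tibble: 8 × 3
#>   category              count percent
#> 1 total_reads           50000  NA
#> 2 high_quality          49700 100
#> 3 adapter3_null           150   0.302
#> 4 insert_null             200   0.402
#> 5 adapter5_contaminants   100   0.201
#> 6 smaller_than_18nt      1000   2.01
#> 7 polyA                    50   0.101
#> 8 clean_reads           48200  97.0
```

The 49,700 high-quality reads split into the five contamination
categories plus 48,200 clean reads — exactly the counts the generator
injected. Sample quality and stage membership:

```r
res$rrna
#>   verdict rrna_fraction threshold
#> 1 PASS             34.8        40
res$venn
#>   region      n
#> 1 all        21
#> 2 anagen      3
#> 3 catagen     3
#> 4 telogen     3
nrow(res$novel)
#> [1] 8
```

The rRNA share (34.8%) is under the 40% animal-sample rule; 21 conserved
miRNAs are expressed in all three stages and 3 are specific to each
stage, matching the planted profiles; all 8 planted novel precursors are
recovered. Differential expression between stages:

```r
glance(res$diffexp)
#> # A tibble: 3 × 7
#>   control treatment     n n_excluded frac_p_lt_0.01 frac_p_0.01_0.05 frac_ns
#> 1 anagen  catagen      30          3          0.370           0.0370   0.593
#> 2 anagen  telogen      30          3          0.370           0        0.630
#> 3 catagen telogen      30          3          0.370           0        0.630

ac_pvalue(x = 2000, y = 500, n1 = 48200, n2 = 48200)
#> [1] 1.783955e-211
```

A planted 4-fold change at depth 2000 vs 500 is unambiguous under the
exact test. The planted enriched GO term tops the target-gene
enrichment:

```r
head(tidy(res$enrichment_go), 1)
#> term           N     n     M     m        p_raw p_adjusted significant
#> GO:0000001    40    10    12    10 0.0000000779 0.00000101 TRUE
```

Folding is exact under the simplified energy model:

```r
fold_mfe("GGGGAAAACCCC")
#> GGGGAAAACCCC
#> ((((....)))) (-12.00 kcal/mol, internal backend)
```

`autoplot(res$diffexp)` draws the classic two-library expression
scatter coloured by ratio class; `plot_length_distribution(res$lengths)`
shows the 22-nt insert peak.

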