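---
title: "Models and methods behind mircycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mircycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mircycle)
```

mircycle re-implements, as a tested and reusable pipeline, the small-RNA
sequencing analysis used to profile microRNAs across the three stages of
the hair-follicle cycle (anagen — growth, catagen — regression, telogen —
quiescence) in fibre-producing goats. This vignette explains each model
and procedure, the parameters that matter, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

## Read cleaning and the contamination accounting

Raw reads are classified into exactly one category, in a fixed precedence
order: low quality, missing 3' adapter, empty insert, 5'-adapter
contamination, polyA insert, too-short insert, clean. The precedence
mirrors the order such categories appear in sequencing reports, and a
read failing several rules is counted once, at the first failing rule, so
the categories always partition the high-quality reads. `filter_stats()`
enforces that partition; `filter_accounting()` applies the same
arithmetic to any per-library count table, which lets published
accounting tables be recomputed and audited.

Several rules are operational choices because no formal definition
exists in the source material:

* **Low quality** — more than 2 N bases, or more than 20% of bases below
  Phred 10. The synthetic generator creates low-quality reads by
  injecting N bases, which makes the definition testable.
* **3' adapter detection** — leftmost exact match of the adapter's first
  6 bases, allowing the adapter to be truncated at the read end.
  Deterministic and fast; no mismatch budget by default.
* **5' adapter detection** — the last 6 bases of the 5' adapter (the part
  adjacent to the insert) found anywhere in the trimmed insert.
* **polyA** — at least 90% adenine in the trimmed insert.
* **Length bounds** — inserts shorter than 18 nt are discarded. No upper
  filter is applied by default (`max_len = Inf`): the gel selection that
  produced such libraries is 18–30 nt and the read geometry already
  bounds the insert, but a finite cap can be configured.

Clean inserts are collapsed to unique tags (lexicographic order,
counts summed), the unit of all downstream analysis.

## Mapping and priority annotation

`map_tags()` performs exact, full-length matching of every tag against
both genome strands (Biostrings `PDict`/`matchPDict` grouped by tag
width). Exact matching is a deliberate choice — the original aligner
tolerated mismatches but its settings are unrecorded, and exactness
makes the mapper verifiable against a naive substring oracle. Tags
hitting more than 20 loci are flagged, matching the copy-number cap of
the novel-miRNA criteria.

`annotate_tags()` assigns each tag one class by priority:
housekeeping ncRNA (rRNA, then scRNA, snRNA, snoRNA, srpRNA, tRNA;
GenBank-sourced records outrank Rfam-sourced ones inside a class) >
known miRNA > repeat > exon > intron. Only the head of that order
(rRNA first, GenBank before Rfam, then miRNA > repeat > exon > intron)
is dictated by the published priority rule; the ordering among the
remaining ncRNA classes is alphabetical by our choice and configurable,
and it is immaterial in practice because a tag almost never overlaps two
different ncRNA classes. One base of overlap suffices; exon and intron
calls are split sense/antisense by strand agreement; tags that map
nowhere or overlap nothing become `unan` (unannotated), the input to
novel-miRNA discovery. The abundance-weighted rRNA fraction is a sample
quality indicator: below 40% passes (the animal-sample rule; plants use
60%).

## Conserved miRNA quantification

A tag is credited to a reference mature miRNA when it aligns inside the
precursor with at most 2 mismatches and its 5' end lies within ±4 nt of
the mature 5' end — tolerances that follow common small-RNA
quantification practice, since none are stated in the source. Each tag
is credited once, to its best match, ties broken lexicographically by
miRNA id. Expression is normalised as TPM = count / clean total × 10^6.
Stage membership uses a presence rule of raw count ≥ 1 (configurable);
the three-way Venn regions partition the detected set.

## Secondary-structure folding

`fold_mfe()` minimises total pair energy over all pseudoknot-free
structures with hairpin loops of at least 3 nt, by an interval dynamic
program in C++. The energy model is deliberately simple: GC −3, AU −2,
GU −1 kcal/mol per pair, loops free, no stacking or dangles. This
replaces the full nearest-neighbour tables of thermodynamic folding
engines with a model whose optimum can be verified exactly by exhaustive
enumeration — the package's folding tests do exactly that on short
random RNAs. The −18 kcal/mol precursor threshold and the 75% duplex
ratio are applied *within* whichever backend is active. The escape hatch
`energy_model(backend = "vienna")` delegates folding to ViennaRNA's
`RNAfold` (true nearest-neighbour energies) when it is installed; its
energies live on a different scale, so backends are each validated
against their own reference rather than against each other.

Ties are broken deterministically: among equal-energy structures the one
with more pairs wins, then 5'-most pairing in the traceback.

## Novel miRNA prediction

Unannotated mapped tags are clustered per contig and strand when loci
overlap or fall within 35 nt. The deepest tag of a cluster (ties:
5'-most) is the putative mature; two windows are excised per cluster —
star upstream and star downstream — each extending 10 nt (the flank
parameter) beyond the putative miRNA/miRNA\* duplex. Each folded window
is scored against the twelve criteria: mature length 18–26 nt, genomic
match span 20–24 nt, cut-site depth ≥ 3 reads, ≤ 20 genomic loci,
precursor MFE ≤ −18 kcal/mol, miRNA/miRNA\* space ≤ 35 nt, ≥ 14 arm
pairs, bulge ≤ 4 nt, asymmetry ≤ 5 nt. All verdicts are recorded;
acceptance requires all to pass, and rejections are data, not errors.

Interpretation choices: "cut-site depth" counts reads whose 5' end
coincides exactly with the mature 5' end (the cut-site homogeneity
notion); the "reference sequence length" bounds are applied to the
mature's genomic match span; the star strand need not be observed in
reads, and no 3'-overhang check is applied (overhangs are never
mentioned in the source criteria, and with unobserved stars the check
would be vacuous). Because a hairpin's reverse complement is itself a
hairpin, the same planted precursor can be recovered once per strand;
overlapping accepted windows are collapsed, keeping the deepest-supported
(then lowest-energy) one.

## Target prediction

Target sites are ungapped antiparallel duplexes: miRNA position *i*
(1-based from the 5' end) faces the UTR window's base *L − i + 1*. Gaps
are excluded because every rule is positional over the miRNA and would
be ill-defined under indels. The rules: weighted mismatches ≤ 4 with G:U
wobbles counting 0.5; no run of more than 2 consecutive mismatch
positions; no two adjacent mismatch positions within miRNA positions
2–12; no mismatch at positions 10–11; weighted mismatches over positions
1–12 ≤ 2.5; and duplex energy at least 75% of the energy of the miRNA
bound to its perfect complement (absolute values, since both energies
are negative). Wobbles count 0.5 toward the weighted totals but as full
mismatch *positions* for adjacency and positional exclusions. The
production scanner is a vectorised matrix evaluation; the scalar
`align_site()` + `check_target_rules()` path is an independent
implementation used to cross-check it window by window.

A consequence of the simplified energy model worth knowing: with at most
4 full mismatches the 75% rule cannot fail on its own (4 mismatches
remove at most 12 kcal/mol and a 22-mer's perfect duplex is at least 44);
violating only the energy rule requires G:U wobbles, which cost little
mismatch weight but two thirds of a GC pair's energy. The test decoys
are built accordingly.

## Differential expression

For each stage pair, counts are normalised to TPM; zero TPMs are revised
to 0.01 and miRNAs below 1 TPM in both libraries are excluded (the
source's revision sentence is ambiguous — "both samples is zero" yet
"revise to 0.01" singular — so the default revises any zero, and
`revise_when_both_zero = TRUE` gives the stricter alternative). The fold
change is log2(treatment/control) on revised TPM. The p-value uses the
exact two-library test on the *raw* counts: with library totals N1, N2
and r = N2/N1,

p(y | x) = r^y (x + y)! / ( x! y! (1 + r)^(x + y + 1) ),

which is the negative binomial NB(x + 1, 1/(1+r)) over y. Both tails are
summed directly in log space (log-gamma factorials; the infinite upper
tail is summed far enough past the conditional mean that the discarded
remainder is below 10^−18 of the leading term), and the two-sided
p-value is twice the smaller tail, capped at 1 — the tail-combination
rule is ours, as the source prints only the tail definitions. Equal
counts give p = 1 exactly; the type-I error under same-mean Poisson
counts is slightly conservative (≈ 0.044 at λ = 50) because of
discreteness.

One property worth flagging: the conditional formulation fixes one count
and sums tails over the other, so swapping the roles of control and
treatment is *not* an exact identity (even for equal totals, unless
x = y). The two orientations agree in order of magnitude, and the tests
assert exactly that.

Significance classes follow the printed bands (p < 0.01;
0.01 ≤ p < 0.05; NS) and ratio classes the scatter-plot convention
(ratio > 2; 1/2 < ratio ≤ 2; ratio ≤ 1/2), both with inclusive
boundaries as printed. Fold-change profiles over the three stage pairs
are clustered by average-linkage hierarchical clustering on Euclidean
distance, cut at k = 5 — "five rounds of clustering" is ambiguous
(iterations vs groups), and five matches the five expression patterns
described, so k defaults to 5 and is exposed.

No multiple-testing correction is applied to the DE p-values, matching
the source procedure.

## Enrichment

For a candidate gene set, every term with at least one overlap is tested
by the hypergeometric upper tail P(overlap ≥ m) computed in log space;
for numerical stability the complement sum is evaluated directly and
normalised (the two tails sum to one analytically, so this is exactly
the printed 1 − Σ formula without the cancellation of subtracting a
near-1 partial sum). GO mode corrects by Bonferroni, pathway mode by
Benjamini–Hochberg FDR (the FDR method is unnamed in the source; BH is
the standard default), both at 0.05 on the corrected value. The universe
N is the number of genes carrying any annotation in the supplied
mapping, so it is mode-specific. Terms with zero overlap are not tested;
under Bonferroni over tested terms this cannot change any candidate
term's significance adversely relative to testing them, but it is a
documented deviation risk. Candidates missing from the universe are
dropped from n with a warning.

## The synthetic study generator

`sim_config()` fixes the study conditions; `simulate_srna_study()`
produces a genome, truth manifest and three FASTQ libraries that are a
byte-deterministic function of the configuration.

* **Genome** (default 100 kb, one contig): 30 conserved and 8 novel
  precursors, 4 loci per ncRNA class, 6 repeats, 8 exons, 8 introns and
  6 unannotated intergenic pools, shuffled and placed with ≥ 80 nt gaps;
  a capacity error is raised if they cannot fit.
* **Precursors** are perfect stem-loops: mature arm (lengths 20–24 nt
  with a sharp mode at 22, mirroring real miRNomes), loop of 8–20 nt
  (within the 35-nt miRNA/miRNA* space), reverse-complement star arm;
  70% of matures start with U, the hallmark 5'-uridine bias. After
  embedding, each precursor is re-excised exactly as the candidate
  builder would excise it and verified to pass every criterion under the
  default model; failing draws are redrawn, so noise-free recall of 1.0
  is a construction guarantee, not luck.
* **Counts** are Poisson around stage profiles — the simplest count
  process consistent with the exact test's assumptions. Defaults plant
  four miRNAs with a 4-fold anagen/telogen difference at deep
  (≥ 500 expected) counts, three stage-specific miRNAs per stage, and a
  lognormal abundance spread for the rest; novel precursors get two
  anagen-only members.
* **Reads** are insert + 3' adapter truncated to 36 cycles, constant
  high quality. Contaminants of each category are injected at fixed
  per-library rates (defaults between 0.1% and 2%, echoing the
  magnitudes of published accounting tables) and are constructed to be
  unambiguous under the classifier — including across the
  insert/adapter boundary — so the recovered accounting equals the
  manifest exactly. Low-quality reads carry N bases. rRNA pools are
  oversampled so the mapped rRNA share lands near 30–35%, the regime the
  animal-sample quality rule is designed around.
* **UTRs and terms**: 40 genes of 300 nt; perfect-complement sites of
  five conserved matures planted in ten genes; GO and pathway mappings
  in which every gene carries a root term and one term is concentrated
  on the planted target genes.

What passing on this generator shows — and does not. It validates the
accounting arithmetic, the priority logic, the folding and criteria
implementations, and the statistics, against planted truth at zero
sequencing noise. It does not demonstrate robustness to sequencing
error, isomiR heterogeneity, adapter variants, or a repetitive
mammalian-scale genome; and the simplified energy model will accept
hairpins a nearest-neighbour model would score differently. Background
intergenic reads can occasionally assemble a passing hairpin at small
library sizes — a genuine property of rule-based discovery on shallow
data, visible in the candidate verdict tables.

## Problem sizes used in the validation suite

The bundled tests run a reduced study (3 × 6,000 reads, 12 + 4
precursors, 60 kb genome) for the module-level checks and the full
default conditions (3 × 50,000 reads, 30 + 8 precursors, 100 kb) for the
end-to-end recovery check; the exact-test oracle grid covers all counts
up to 50 at three library-size ratios, and the folding oracle covers 200
random RNAs up to 18 nt. These sizes were chosen so the planted effects
are unambiguous (e.g. the exact test's power at the planted depths is
essentially 1) while the whole suite stays quick to run.

## Known limitations

* Exact matching only; no mismatch-tolerant mapping or spliced
  alignment.
* The internal energy model ignores loop penalties and stacking; its
  MFEs are not comparable to thermodynamic engines (use the ViennaRNA
  backend for that, with the same thresholds).
* Ungapped target duplexes only; no conservation filtering or site-type
  classification.
* The exact test has no replicate or dispersion model: it tests sampling
  variation between two libraries, not biological variability.
* GO terms are used as given — no propagation to ancestors.
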