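---
title: "Methods: pangenome structure, biogeography and selection in MAG collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome structure, biogeography and selection in MAG collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangevo)
```

# Scope and data model

`pangevo` analyses a collection of metagenome-assembled genomes (MAGs) of
one bacterial clade sampled from two environments ("sites"). The unit of
analysis is the *gene cluster*: a family of ORFs grouped by similarity
upstream of this package. The pipeline consumes tabular exports — bins,
contigs, gene calls with cluster assignments, cluster annotations (COG
letters), SNV records and single-codon-variant (SCV) records — and never
touches reads, assemblies or clustering itself. Gene-call coordinates are
0-based half-open; SNV positions are 0-based. The canonical on-disk dialect
is header-bearing UTF-8 TSV with `NA` for missing values, so every stage
output can be audited with standard tools.

# The statistics, stage by stage

## Presence/absence structure

Occupancy of cluster $g$ in MAG $m$ is binary; paralogs collapse to one
presence. The *frequency* of a cluster is the number of MAGs carrying it,
and the frequency spectrum of a natural mixed-clade pangenome is U-shaped:
many singletons, many (near-)core clusters, few in between.

Gene-content similarity is summarized by the asymmetric *containment*
$C[A,B] = |A \cap B| / |A|$, the fraction of A's clusters also found in B.
Asymmetry is informative (a small genome can be fully contained in a larger
one), but a dendrogram needs a metric, so genomes are clustered on
$d(A,B) = 1 - (C[A,B] + C[B,A])/2$ with average linkage. Whether to
symmetrize this way or feed the raw asymmetric proportions into a
clustering heuristic was genuinely open; the arithmetic-mean symmetrization
was chosen because it keeps $d$ a proper dissimilarity and reduces to
$1 - $ Jaccard-style overlap for equal-sized genomes. Bins are sorted
lexicographically before agglomeration so ties break deterministically.

Rarefaction tracks the cumulative union (pangenome size) and intersection
(core size) over random orderings of the MAGs; when $M! \le$ the requested
number of orderings the package enumerates all orderings and the curves
are exact. An accumulation curve that keeps rising is the operational
signature of an open pangenome; no Heaps-law exponent is fitted.

## Completeness-aware core posterior

MAG incompleteness censors presence: a truly-core cluster observed in only
$n$ of $M$ MAGs may simply have been missed by the others. `core_posterior()`
treats each MAG's completeness $c_m$ as its detection probability and
estimates, by Monte Carlo, $P(\text{present in all } M \mid \text{observed
in } n)$: draw the true presence count $t$ from a prior, a uniform subset
of that size, then Bernoulli($c_m$) detection per member, and condition on
the observed count. The default prior is flat on $t \in \{1..M\}$ — the
least-informative choice on the quantity of interest; the object records a
prior tag so results are never detached from this choice, and an
`"all_core"` prior is provided for calibration tests (under it the observed
count is exactly Binomial when completeness is constant). Two consequences
worth knowing: the posterior is monotone non-decreasing in $n$ (property-
tested), and at $n = M$ it is exactly 1 because the model has no
false-presence channel — redundancy-driven spurious presences are outside
this model. Cells with no qualifying simulations are reported as undefined
(`NA` with `n_matching = 0`), never as 0.

## COG composition and permutation enrichment

Category profiles count, per (category, frequency) cell, the clusters at
that frequency carrying the category; clusters with several annotations
count once in each (so proportions can sum above 1 — the convention is
stated on the output), and unannotated clusters travel as `"N/A"` rather
than silently disappearing.

The enrichment null permutes category label-sets across clusters while
every cluster keeps its frequency. This is one concrete reading of a
"nonparametric simulation" null: it preserves both marginals (category
abundance and the frequency spectrum) and destroys only their association,
which is exactly the hypothesis at stake. The one-sided empirical P value
$(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$ makes small values
over-representation and values near 1 under-representation; users wanting
two-sided statements can fold. The add-one correction keeps P in $(0,1]$
and valid; when the cluster count is small enough that all $n!$
permutations fit in the budget the package switches to exhaustive
enumeration and reports the exact permutation probability instead (the
identity permutation is then part of the null, so no correction applies).
Band comparisons (e.g., frequencies below vs at-or-above 15 MAGs) use a
Welch t-test on per-frequency proportions; the band boundary is a
configurable parameter, default 15.

## Biogeographic enrichment

For a cluster found in $N$ MAGs, $k$ of them from site 1, the score is the
inclusive lower tail $P(X \le k)$, $X \sim \mathrm{Binomial}(N, p)$, with
$p$ the site-1 share of the MAG collection (13/22 on the reference design;
recomputed from the input by default, overridable). Inclusivity of $k$ is
pinned by numeric inversion of reference scores (e.g., $q^7 = 0.00191752$
at $k=0, n=7$) and by the summation oracle in the test suite. Clusters are
scored only when found in at least 7 site-2 or at least 12 site-1 MAGs —
without such a filter every low-frequency cluster of a site-skewed
collection would score extreme. Calls use the raw CDF cutoffs 0.05/0.95;
no multiplicity correction is applied by default because the score is used
as a ranked screen, but `biogeo_bh()` adds a folded two-sided P with a
Benjamini–Hochberg column for users who want error-rate control. The
category-level test compares CDF values of a category against all other
scored clusters with a Welch t-test (two-sample form; whether the original
comparison was two-sample or against the fixed value 0.5 is not
documented, so the one-sample form is exposed as `against = "half"`).

## pN/pS from single-codon variants

Per ORF, observed synonymous/nonsynonymous variant counts are normalized
by potential site counts under Nei–Gojobori equal-weight enumeration: for
each reference codon, each of the 9 single-nucleotide mutants contributes
1/3 of a site to the class (synonymous/nonsynonymous) of its effect, so
potential sites sum to exactly 3 per sense codon. The conventions, chosen
for self-consistency and recorded here and in the output metadata:

* mutational paths to stop codons count as nonsynonymous sites, and
  stop-introducing variants classify as nonsynonymous — the same event is
  treated the same way on both sides of the ratio;
* variants departing from the reference codon at more than one nucleotide
  are excluded (not decomposed into mutational paths) and tallied in a
  diagnostics column;
* reference stop codons (mid-ORF) are excluded from site totals with a
  warning;
* only variants flagged as covering the full codon are admitted;
* ratios are reported only when finite: ORFs with no admitted variants are
  `nonpolymorphic`, ORFs with nonsynonymous but no synonymous variants are
  `undefined_no_syn` (never $\infty$), and pN $= 0$ with pS $> 0$ is the
  `zero` class. Group summaries use only finite ratios.

Site counting is done in integer thirds, so the implementation is exactly
comparable to a rational-arithmetic enumeration oracle (the test suite
holds agreement below $10^{-12}$ on random ORFs). Group tests are
two-sided rank-sum tests of a group against all others pooled; for small
groups the package enumerates all assignments on midranks, which stays
exact under ties, and falls back to the tie-corrected normal approximation
otherwise.

## SNV density and sweep detection

A bin's $N$ SNVs scattered neutrally over its $L$ bp give a contig of
length $l_c$ a $\mathrm{Poisson}(n_c)$ count, $n_c = N l_c / L$; the
inclusive lower-tail CDF at the observed count is the sweep P value, and
genes inherit the value of their contig. The inclusive convention keeps
$P \in (0,1]$ and makes $N = 0$ give the uninformative $P = 1$.
$L$ is the summed length of the bin's contigs passing the length filter
(default 1,000 bp), the same set over which $N$ is counted, so expected
counts conserve exactly: $\sum_c n_c = N$ per bin. The flag threshold
$10^{-10}$ is deliberately extreme — with thousands of genes per genome it
keeps genome-wide false flags at essentially zero, so any flagged gene is
worth manual inspection; it is configurable. The statistic cannot
distinguish a gene-specific sweep from recent acquisition or a clonal
expansion; it is a deficit detector, nothing more. The coverage-by-
frequency diagnostic guards the other flank: if apparent accessory genes
sat systematically on low-coverage contigs, "gene frequency" would partly
measure assembly depth, not biology.

# The synthetic world

The generator states one world and the defaults are not tuned: 22 MAGs
(13 "Axial", 9 "MCR"); per-MAG completeness Uniform(0.70, 0.97) acting as
Bernoulli dropout on true presence; 10,000 gene clusters in a U-shaped
mixture — 10% true-core, 35% singletons, the rest accessory with a
truncated-geometric frequency law (decay 0.20, mean frequency about 6) so
per-MAG gene counts land near 2,000, matching genomes of roughly 2 Mbp at
about 900 bp per gene with 100 bp spacing on 40 kb contigs. Where the
emulated quantities were stated (MAG counts, completeness range, SNV
density range 0.1–10 per kbp, site-biased design "all MCR, at most one
Axial"), the defaults are those statements; where only a figure's shape
was available (the spectrum), the mixture parameters are exposed in
`sim_config()` and the chosen defaults reproduce the U shape at a
realistic per-genome gene count. Specific choices a reader should know:

* **Biased clusters** (default 50) are truly present in all 9 MCR MAGs and
  at most 1 Axial MAG; dropout then decides what is observed. Sensitivity
  of the biogeographic caller is therefore defined *among scored clusters*:
  a biased cluster dropped below the inclusion filter by incompleteness
  was never presented to the caller, and folding recovery of censored
  input into the caller's sensitivity would conflate two different
  failures. The inclusion rate itself is visible in the outputs
  (`n_excluded`).
* **Singleton islands.** Within each simulated genome, singleton clusters
  are placed contiguously, emulating genomic islands of recently acquired
  genes; swept contigs (default 20, density multiplier 0) are drawn among
  singleton-dominated contigs. This is what makes contig-level sweep
  signals attributable to low-frequency genes, as a gene-specific sweep
  model requires.
* **pN/pS targets** are per-class (core 0.15, accessory 0.25, singleton
  0.35, reflecting relaxed purifying pressure on rarer genes). For each
  ORF the generator computes its actual potential-site ratio with the same
  site counting the analysis uses and draws each variant synonymous with
  probability $q = 1/(1 + r\,N_{pot}/S_{pot})$, which makes the expected
  ratio equal the target $r$. The mean of per-ORF ratios carries a small
  upward Jensen bias of order $1/E[S_{obs}]$; at the default 30 variants
  per ORF this is a few percent, and recovery tests at 200+ variants sit
  within a few percent of target.
* **SNV densities** are drawn log-uniformly per MAG over 0.1–10 per kbp
  (the stated range spans two orders of magnitude, and log-uniform is the
  scale-neutral way to cover it); positions are uniform without
  duplication; a fixed-density degenerate range (including 0) is allowed.

What the generator does **not** emulate — and hence what a green test does
not establish: sequence divergence along a phylogeny (all ORFs of a
cluster share one reference sequence, and variants are independent draws,
not inherited polymorphism); read-level error and coverage fluctuation
(coverage is a lognormal decoration, independent of everything);
redundancy-driven false presences (so the core posterior's no-false-
presence assumption is true by construction here and only approximately
true on real bins); linkage between SNVs and SCVs (the two variant layers
are generated independently); and any geochemical or functional reality
behind the COG labels. Tests against this world validate the statistical
machinery, not upstream assembly, binning or clustering.

# Numerical and reproducibility choices

Binomial and Poisson tails use R's exact `pbinom`/`ppois` (cross-checked
against term-by-term summation oracles to $10^{-12}$ over the relevant
domain); potential-site arithmetic is integer until the final division;
permutation and rarefaction engines switch to exhaustive enumeration when
the budget covers the full space. One global seed drives everything: each
stage derives a named substream (`stage_seed`), so adding a stage never
perturbs another stage's draws, and rerunning a pipeline with the same
inputs and seed is byte-identical (outputs carry the seed and a config
hash, and no timestamps are written). Degenerate inputs have defined
behaviour rather than accidents: empty gene-call tables give empty
matrices, bins with zero clusters make containment fail loudly, zero
Monte Carlo mass gives `NA` posteriors, and all integrity violations raise
classed errors carrying the offending identifiers.

# Known limitations

The core posterior's prior over the true presence count is a modelling
choice the data cannot identify at $n = M$; results there (posterior
exactly 1) follow from the no-false-presence assumption, not from
evidence. The permutation null conditions on the observed frequency
spectrum, so it cannot detect biases that act through the spectrum itself.
The sweep statistic pools SNVs per bin; with several samples mapping to
one MAG a per-sample analysis may be preferable (the record layout keeps
an optional sample column for this). Welch t-tests on per-frequency
proportions treat frequencies as exchangeable replicates, which is a
pragmatic approximation, not a sampling model.
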