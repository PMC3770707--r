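---
title: "Genotype superset networks: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype superset networks: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snpsupernet)
```

## The model

An individual genotyped at M biallelic SNPs is summarized by their *genotype
superset*: the ordered, space-separated concatenation of the M genotype calls,
e.g. `"12 22 11 22 11"`. Calls are written over the alphabet `{11, 12, 22}`
(wild homozygote, heterozygote, mutant homozygote); `"21"` is the same
unordered allele pair as `"12"` and is canonicalized on input. With M markers
there are exactly 3^M possible supersets, but a cohort of P individuals can
realize at most min(P, 3^M) of them — for even moderate M the realized
supersets are a vanishing fraction of the possible ones, which is what makes
them informative group labels.

The cohort is displayed as a bipartite *super-node network*: one super-node
per study group (case, control, ...) plus one node per observed superset. A
superset node is connected to a group's super-node iff at least one individual
of that group carries it, and the edge weight w is the number of such
individuals (1 &le; w &le; P). The nodes partition into 2^k &minus; 1
membership classes by which of the k groups they touch; *group-specific*
nodes (exactly one group) are the classification signal, shared nodes the
background.

```{r}
cohort <- generate_cohort(synth_preset("acs-like", seed = 1))
net <- build_network(superset_table(cohort))
glance(net)
partition_counts(partition_nodes(net))
```

## Knockout ranking

To score individual markers, each SNP is omitted in turn: every superset loses
that call, supersets that differed only there collapse, and the group-specific
counts are recomputed. A marker whose removal *destroys* much of the
focal-group specificity carried most of it; accordingly rank 1 goes to the
marker with the **smallest** remaining focal-specific count (or smallest
focal/reference ratio) after its own omission. Ties fall back to marker input
order, deterministically. When the reference-specific count is zero under the
ratio criterion, 0.5 is added to both counts (a continuity rule, the same
device as the Haldane correction for odds ratios) so the ranking stays total.
The restructuring of [focal-specific, reference-specific] counts between the
full and the reduced network is testable with a Yates-corrected chi-square.

```{r}
scan <- knockout_scan(cohort, focal = "case", reference = "control")
rank_markers(scan, "case_specific_nodes")
```

## Shuffle nulls and rank conservation

Two permutation nulls probe the stability of the ranking:

* **Type 1** permutes the genotype calls of each SNP across individuals,
  preserving the per-SNP genotype counts.
* **Type 2** pools each SNP's alleles, permutes them, and re-pairs them into
  genotypes, preserving allele counts but not genotype counts
  (Hardy–Weinberg re-randomization).

A design decision worth spelling out: by default both shuffles permute
**within each group** (`within = "group"`), not across the pooled cohort.
Within-group permutation is the null that leaves every per-SNP group-level
genotype (Type 1) or allele (Type 1 and 2) spectrum intact, so single-marker
association statistics are unchanged and only the *joint*, multi-marker
arrangement is destroyed. That is precisely the question rank conservation
asks: does the marker's rank depend on the joint arrangement or only on the
marginal spectra? Pooled permutation (`within = "population"`) additionally
destroys the group/marker association itself; under it, rank conservation
collapses toward the uniform baseline and measures nothing beyond the
single-marker signal. Both variants are available; the within-group default is
the one under which a genuinely strong marker holds rank 1 in nearly all
replicates.

*Rank conservation* is the percentage of shuffled replicates in which a marker
occupies exactly its original rank. Every replicate derives its seed
deterministically from the base seed, so tables are exactly reproducible.

```{r}
rank_conservation(cohort, method = "type1", n_reps = 100, seed = 1,
                  focal = "case", reference = "control")
```

## Segregation with panel size

On a large marker panel, the number of supersets shared by all groups decays
as the SNP subset grows: with enough markers every individual's superset is
unique to its group. `segregation_curve()` estimates the mean and sd of the
shared count over random subsets of each size; past a threshold (a few dozen
SNPs on a panel of hundreds of individuals) the curve reaches and holds zero.
This is the regime in which group-specific supersets become a usable
classification device.

## Association statistics

The classical single-marker and haplotype machinery is included because the
network results are read side by side with it:

* `yates_chi_square()`: df = 1 chi-square with the continuity correction
  capped at |O &minus; E| (the `stats::chisq.test(correct = TRUE)`
  convention, which that function cross-checks in the tests).
* `odds_ratio_woolf()`: OR with Woolf's log-based 95% CI; if any cell is
  zero, 0.5 is added to all four cells (Haldane–Anscombe).
* `haplotype_case_control_or()`: one-vs-rest OR per haplotype, keeping
  haplotypes above 3% frequency in either group.
* `em_two_locus()`: two-locus haplotype frequencies from unphased genotypes.
  Only the double heterozygote is phase-ambiguous; the E-step splits it
  between cis and trans in the ratio p11·p22 : p12·p21. The M-step is a
  closed-form count update, so the log-likelihood is monotone (asserted at
  run time); convergence is declared at a 1e-8 change. Because any maximizer
  must keep the allele-frequency margins at their observed values, the MLE is
  one-dimensional in p11 — the tests exploit this with an independent
  grid-search oracle.
* `ld_stats()`: D, D&prime; (conventional Dmax) and r&sup2; from the EM
  frequencies.

## Synthetic presets

The package ships three frozen generator presets, chosen a priori to mirror
the study designs the method targets, and used as-is by the test suite and
the acceptance script:

* `"acs-like"`: 91 cases / 86 controls over 5 SNPs. SNP4 is the planted risk
  marker (mutant-allele frequency 0.40 vs 0.03), SNP2–SNP3 are a linked pair
  with haplotype frequencies chosen so r&sup2; = 0.7 at equal allele
  frequency 0.15, and SNP1/SNP5 are background markers. The linked pair sits
  on two *background* markers deliberately: at the frequencies printed for a
  risk marker, r&sup2; = 0.7 is arithmetically impossible (r&sup2; is bounded
  by the allele-frequency imbalance), so the preset plants the linkage where
  the target r&sup2; is attainable and keeps the risk signal on SNP4.
* `"oral-like"`: three groups (369/219/298) over 5 independent SNPs with
  moderate frequency gradients.
* `"panel-like"`: a 1804-SNP × 635-individual two-group null panel for
  segregation curves.

Generation is Hardy–Weinberg within group (two Bernoulli allele draws per
genotype), haplotype-pair draws for linked pairs, and fully deterministic
given the seed.

## Limitations

* Synthetic cohorts demonstrate the *mechanics* — that a strong planted
  marker earns rank 1 and survives shuffling — not clinical performance on
  any real cohort.
* Supersets treat markers symmetrically and unphased; the network carries no
  linkage information beyond what the superset identity encodes.
* Group-specific counts are in-sample quantities; with P &#8810; 3^M most
  supersets are singletons and specificity partly reflects sampling, which is
  exactly what the shuffle nulls are for.
* A PLINK PED reader is intentionally out of scope; the TSV reader plus the
  per-marker allele map covers letter-coded input, and established tools
  already convert PED to tabular genotypes.
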