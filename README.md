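# pansort

Population-genetic and phylogenetic analysis of incomplete lineage sorting
between closely related populations, built around multilocus amplicon
resequencing designs of the kind used to compare bonobos (*Pan paniscus*)
and chimpanzees (*Pan troglodytes*): many ~10 kb non-coding autosomal
regions plus mtDNA, sequenced on a 454 platform, with a human outgroup.

It is aimed at researchers who need the complete computational chain from
aligned reads to lineage-sorting summaries, with every stage testable on
synthetic data with known truth:

* **Coalescent simulation** — Hudson-style neutral coalescent with
  recombination (ancestral recombination graph), optional exponential
  growth, and a two-population split model that records the realized gene
  tree (`simulate_locus()`, `simulate_split()`).
* **454-style read simulation** — emulsion-PCR duplicates, allelic
  imbalance and dropout, quality-calibrated miscalls and homopolymer
  indels (`simulate_reads()`).
* **SNP calling** — the conservative five-filter cascade for pyrosequencing
  amplicons: duplicate removal, gap proximity, mismatch screen, homopolymer
  mask, Neighbor Quality Score (site ≥ 20, flanks ≥ 15), with a
  heterozygote called only when the minor-allele read fraction exceeds 0.15
  at depth ≥ 8 and both alleles have quality support; plus the regional
  allele-imbalance (skew) and all-homozygous screens for allelic dropout
  (`call_region()`).
* **Diversity statistics** — S, π, Watterson's
  θ<sub>w</sub> = S / (a<sub>n</sub> L), Tajima's D, Fu & Li's D*,
  pooled multilocus tables, and effective population size
  N<sub>e</sub> = θ<sub>w</sub> / 4µ with µ = (d / 2t) · g
  (`diversity_table()`, `effective_size()`).
* **Differentiation and allele sharing** — Hudson F<sub>st</sub> as a
  ratio of averages, and per-site derived-allele sharing classification
  against the outgroup (`pairwise_fst()`, `classify_shared_sites()`).
* **Neutrality testing** — a composite goodness-of-fit test against a
  simulated null with Gamma-distributed θ and log-normal ρ across loci:
  five summary statistics, two-sided empirical p-values, composite
  statistic C = Σ ln p, and a fit p-value from leave-one-out scoring of
  the simulations (`composite_fit()`).
* **Posterior monophyly** — monophyly and reciprocal-monophyly
  probabilities over Bayesian tree samples (10% burn-in per run, rooted on
  the outgroup, >95% / <5% support classification) and strict-majority
  consensus trees (`posterior_monophyly()`, `majority_consensus()`).

## Worked example

Simulate one 10 kb locus for 10 + 10 chromosomes under a two-population
split, summarize diversity, and call SNPs on a simulated read set:

```r
library(pansort)

aln <- simulate_split(
  split_model_params(c(10, 10), split_time = 1.2,
                     pop_names = c("bonobo", "chimp")),
  theta = 12, seed = 42, locus_length = 10000, sequences = TRUE)

diversity_table(list(aln), rates = evolutionary_rates())
#>   population  n  S pi_pct theta_w_pct ne_rounded   tajima_d
#> 1     bonobo 10 45   0.15        0.16      17700 -0.3867165
#> 2      chimp 10 36   0.13        0.13      14100  0.0621077

pairwise_fst(list(aln), "bonobo", "chimp")
#> [1] 0.771

ts <- tree_sample(list(attr(aln, "genealogy")), aln$pop_map, "ancestor")
posterior_monophyly(ts, "bonobo", burnin = 0)
#> Monophyly of {bonobo}: p = 1.0000 over 1 trees -> monophyly_supported

## a heterozygous PCR product, sequenced at 30x and run through the cascade
pl <- simulate_reads(unname(aln$sequences[c("bonobo_1", "bonobo_7")]),
                     read_sim_config(mean_coverage = 30), seed = 7)
call_region(pl)
#> Region call report
#>   sites 10000 | covered 9984 | callable 9748 | heterozygous 35
#>   skew flag: FALSE | all-homozygous flag: FALSE
```

The diversity table reads like a resequencing-study summary: per-site π and
θ<sub>w</sub> as percentages, N<sub>e</sub> from θ<sub>w</sub> with the
default rates (d = 1.35%, t = 6 My, g = 20 y), and Tajima's D on the
pooled data. The F<sub>st</sub> of 0.77 and the supported bonobo clade
reflect the fairly deep split time chosen (1.2 × 4N generations). Of the
36 sites distinguishing the two sampled haplotypes, 35 are recovered as
heterozygous; the remainder sits in filtered context. Two haplotypes that
coalesce recently instead produce `heterozygous 0 | all-homozygous flag
TRUE` — the signature that triggers re-amplification with a second primer
pair in the laboratory workflow.

An end-to-end demonstration (simulate → call → stats → neutrality →
monophyly, with TSV outputs and a reproducibility manifest) is one call:
`run_pipeline(list(seed = 1, out_dir = "demo_run"))`.

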