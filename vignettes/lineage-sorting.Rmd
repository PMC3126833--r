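---
title: "Quantifying incomplete lineage sorting from multilocus resequencing data"
author: "pansort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying incomplete lineage sorting from multilocus resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two species separate, their gene genealogies do not sort instantly.
Every locus passes through polyphyly, then paraphyly, and only after roughly
4Ne generations of isolation does it typically reach reciprocal monophyly.
Bonobos and chimpanzees are a textbook case: bonobos form a clade at almost
every locus, while chimpanzees — with their larger effective population size
— retain ancestral polymorphism that predates the species split, so that for
several loci some chimpanzee haplotypes are closer to bonobo haplotypes than
to other chimpanzees.

`pansort` implements the full computational chain used to measure this from
multilocus amplicon resequencing: SNP calling from pyrosequencing reads
through a conservative filter cascade, per-population diversity statistics
and effective-size estimation, a simulation-based composite test of the
standard neutral model, Hudson Fst and derived-allele sharing counts, and
posterior monophyly probabilities over Bayesian tree samples. Because raw
reads and alignments from such studies are rarely re-distributable, the
package carries its own coalescent and read simulators; every downstream
stage is exercised and validated on synthetic data with known truth.

## The coalescent simulator

`simulate_locus()` is a Hudson-style back-in-time simulator. Conventions:

* Time is measured in units of 4N generations; the pairwise coalescence
  rate is 2 (so E[T2] = 1/2).
* `theta` and `rho` are per-locus population-scaled rates, `4*N*mu*L` and
  `4*N*r*L`; mutation and recombination rates per lineage are `theta` and
  `rho` times the fraction of the locus the lineage spans.
* With `rho = 0` the sample genealogy is built directly and mutations are
  Poisson-distributed on branches. With `rho > 0` a full ancestral
  recombination graph is simulated: each lineage carries segments of
  ancestral material, recombination splits a lineage at a uniform point of
  its span, coalescence merges segment lists (unions of descendant sets),
  and segments that reach the sample-wide MRCA are retired. Mutations
  accrue between events at rate `theta` times the live ancestral length and
  hit a segment proportionally to its length.
* Mutations follow the infinite-sites model; continuous positions are
  mapped to discrete sites with a collision re-draw. At the ~1% divergence
  scale of the target system, finite-site double hits are negligible.
* Optional exponential growth (`N(t) = N0 exp(-alpha t)` looking back)
  enters through a closed-form time transformation of the coalescence
  hazard.
* The known ancestral state is returned as an all-ancestral outgroup row
  (`"ancestor"`), which downstream code uses for polarization and rooting.

`simulate_split()` adds a clean two-population isolation model (structured
coalescent until `split_time`, panmixia before) and records the realized
gene tree, so the lineage-sorting state of every simulated locus is known
truth rather than something re-inferred.

Checks worth trusting: E[S] = theta * a_n and E[pi] = theta hold to within
3 Monte-Carlo standard errors at 10,000 replicates; for n = 2 the number of
segregating sites is geometric with success probability 1/(1+theta)
(chi-square goodness of fit at alpha = 0.001); marginal single-site
statistics are unchanged by recombination; and the mean of Tajima's D
matches an independent simulator (msprime/tskit) run at identical
parameters. The same seed always reproduces byte-identical output;
multi-locus runs derive per-locus substreams from one master seed.

## The read simulator

`simulate_reads()` emulates the error modes of 454 amplicon sequencing that
the SNP-calling cascade exists to absorb, for one diploid PCR product:

* **Emulsion-PCR duplicates** — a configurable fraction of reads is
  re-emitted with identical start and strand (fresh error realizations).
* **Allelic imbalance** — reads are drawn from the first allele with
  probability `allele_balance` (0.5 = unbiased); `dropout = TRUE` silences
  that allele entirely. The consensus is the major allele, as an iterative
  mapping assembler would call it.
* **Quality-calibrated miscalls** — per-base qualities are drawn from a
  truncated normal (default mean 30, sd 5, clamped to [5, 40]) and each
  base miscalls with probability `10^(-q/10)`, keeping quality scores
  honest about error rates.
* **Homopolymer over- and under-calls** — a run of k identical bases
  suffers an indel with probability `min(0.5, rate * (k - 1))`. An
  undercall appears as a single-base gap in consensus coordinates; an
  overcall bleeds the run base across the boundary and carries a low
  quality score (5–12), mirroring the collapse of flowgram confidence at
  run boundaries. The pileup dialect has no insertion channel, so both
  modes are realized in consensus coordinates.

Not emulated: PCR chimeras, context-dependent substitution bias, read-length
variation, and real assembler (MIA) behaviour. Passing the synthetic checks
therefore shows that the filter cascade handles duplicate, imbalance,
miscall and homopolymer noise as designed — not that it is robust to every
artifact of real 454 assemblies.

## The SNP-calling cascade

`call_region()` applies, per candidate site:

1. **Duplicate removal** — one read per (strand, start) group, keeping the
   highest read quality (first in input on ties).
2. **Gap proximity** — a read is ignored at a site if it aligns with a gap
   within 5 bp of it.
3. **Mismatch screen** — a read is not allele support at a site if it shows
   more than one mismatch to the consensus within 5 bp around the site (the
   site itself excluded).
4. **Homopolymer mask** — no SNP is called where a run of >= 6 identical
   bases intersects the 20 bp window centred on the site (site +/- 10 bp;
   a run "counts" if it intersects the window at all).
5. **Neighbour Quality Score** — support reads need quality >= 20 at the
   site and >= 15 at the five flanking bases on each side (flanks clipped
   at read ends).

A site is **no call** if fewer than 8 reads survive steps 1–2, if the
homopolymer mask covers it, if no read passes steps 3 and 5, or if three
alleles remain (an infinite-sites artifact flag). Otherwise it is
**heterozygous** iff the minor-allele fraction — computed over all reads
surviving steps 1–2 — strictly exceeds 0.15 *and* each allele has at least
one read passing steps 3 and 5; otherwise homozygous. Computing the allele
frequency over the step-1/2 survivors (with the mismatch/NQS filters acting
as per-allele support) keeps the cascade monotone: switching on any
additional filter can only remove heterozygote calls, a property the test
suite asserts. Regional screens reproduce the laboratory workflow: the
**skew flag** (every SNP's minor fraction below 0.30) and the
**all-homozygous flag** mark products that would be re-amplified with a
second primer pair to exclude allelic dropout.

All thresholds live in `call_params()` and default to the values above;
coordinates are 1-based inside R, 0-based in the on-disk pileup dialect,
1-based in the VCF-like output.

### Validation experiments

Two properties replace data-dependent checks on the original reads:

* **False positives**: 22 homozygous 5 kb products (~1.05e5 callable sites)
  simulated at 40x with the full error model yield zero heterozygote
  calls. Deep amplicon coverage matters here: at 20x a non-trivial number
  of sites sits at depth 8–13, where two same-base miscalls with quality
  >= 20 can exceed the 0.15 fraction; at amplicon-typical depth the
  threshold geometry makes that impossible.
* **False negatives**: every planted heterozygote with realized minor-read
  fraction >= 0.35, filtered depth >= 20 and no homopolymer context is
  recovered (100% of ~300 clean sites at 30x).

## Diversity statistics and effective size

Per locus and pooled across loci, the package computes the number of
segregating sites S, nucleotide diversity (mean pairwise difference per
site, missing bases excluded site-wise), Watterson's estimator
`theta_w = S / (a_n L)`, Tajima's D and Fu & Li's D* (the corrected
variance constants; singletons are alleles observed exactly once, no
outgroup needed). Multi-locus tables pool the way resequencing studies
report: summed S and lengths, length-pooled per-site rates, and D
statistics computed on the concatenated data (per-locus values remain
available — the neutrality test needs their across-locus variance).
Percentages are rounded to two decimals and Ne to the nearest hundred in
the formatted columns.

Effective size uses `Ne = theta_w / (4 mu)` with `mu = (d / 2t) g` — default
divergence d = 1.35%, divergence time t = 6 My, generation time g = 20 y,
giving mu = 2.25e-8 per site per generation — and the mean coalescent time
of sequences is `4 Ne g` years.

Fst is Hudson-type, `1 - mean(Hw)/mean(Hb)` as a ratio of averages over all
usable biallelic sites, with Hw the *plain* average within-population
heterozygosity `2p(1-p)`. The plain (uncorrected) form is deliberate: it
makes equal allele frequencies give exactly 0 and alternatively fixed sites
exactly 1; small-sample-corrected variants trade those identities for
unbiasedness. Derived-allele sharing is classified per site against the
outgroup into the five standard categories (each species polymorphic or
fixed derived/ancestral); sites where the outgroup carries a third allele
are skipped and counted.

## The composite neutrality test

The fit of each population to a constant-size, random-mating neutral model
is scored against its own simulated null. A null configuration records the
observed loci layout (chromosomes and length per locus) plus locus-to-locus
rate heterogeneity: per-locus theta drawn from a Gamma distribution and rho
from a log-normal, each moment-matched to per-locus estimates
(`sample_null_hyperparams()`). Each of `reps` simulated datasets yields five
summaries: the across-locus variance of Tajima's D and the across-locus
means of S, pi, Fu & Li's D* and Tajima's D. rho is drawn (it shapes the
variance of the D statistics) but is never itself a summary statistic.
Loci without segregating sites contribute zero to the S and pi means and
are excluded from D-statistic means and variances, with their count
recorded.

Each observed summary gets a two-sided empirical p-value
`2 * min(P(<=), P(>=))` with add-one smoothing `(1 + count)/(1 + reps)`, so
p is never zero and `log p` stays finite. The composite statistic is
`C = sum(log p)` over the five summaries; the reported fit p-value is the
smoothed proportion of simulated datasets whose own C — computed
leave-one-out against the remaining simulations — is at least as small.
Two-sided tails and leave-one-out scoring are deliberate choices where the
procedure's description leaves room; both are switchable (`tail=`) or
differ from the alternative only at O(1/reps). Simulation uses fixed-theta
draws (matching the stated Gamma model) rather than conditioning on the
observed S; the fixed-S alternative changes the null subtly and is not
offered.

Calibration is checked by construction: with 15 loci of 2 kb at n = 20,
per-site theta 0.001 (Gamma, shape 4) and rho ~ log-normal with mean 2, 200
null datasets scored against a shared pool of 500 null simulations reject
at alpha = 0.05 at a rate inside the 99% binomial band around 0.05, and
strong exponential growth (alpha = 15) collapses the median fit p-value by
two orders of magnitude. These problem sizes are the package's validation
conditions and are stated here so the numbers in the acceptance output are
interpretable.

## Posterior monophyly and consensus

`tree_sample()` pools rooted (or rootable) trees across runs with a
tip-to-population map; all posterior summaries first discard a burn-in
fraction (default 10%) per run, then root every tree on the outgroup. A
group is monophyletic iff some clade equals exactly its tip set — a
polytomy containing extra tips fails. Posterior support is the fraction of
retained trees containing the clade; the conventional thresholds classify
support for monophyly above 0.95 and for paraphyly below 0.05, everything
between as ambiguous (so a posterior of 0.913 is ambiguous and 0.003
supports paraphyly). Reciprocal monophyly counts trees where both groups
are simultaneously monophyletic and can never exceed either marginal
probability — asserted on every run. Counting is over all retained
samples, not unique topologies. The majority consensus keeps exactly the
clades present in strictly more than half of the sample (ties at exactly
50% are excluded, keeping the retained set compatible by construction) and
annotates each with its frequency.

## Numerical choices and degenerate inputs

* Statistics on zero-variation input return `NA` with a flag, never 0:
  Tajima's D and D* are undefined at S = 0.
* D* requires n >= 3; the harmonic constants are computed stably for
  n up to 1e4.
* Zero-variance rate estimates degenerate to point-mass distributions with
  a warning.
* Dedup tie-break: first read in input order; homozygous major-allele
  tie-break: alphabetical.
* Read-end handling: NQS flanks are clipped at read boundaries; the gap
  filter looks only within the read's aligned span.
* All simulators accept a single integer seed; multi-unit runs derive
  per-unit substreams (`derive_seed`) so per-locus results are individually
  reproducible.

## Limitations

No migration, admixture, selection or gene conversion in the simulators; a
single fixed read length; no genotype-likelihood model in the caller (it is
a faithful re-implementation of a threshold cascade, not a probabilistic
caller); unphased-genotype input is not supported for pi (inputs are
haplotype/consensus alignments); and Bayesian tree inference itself is out
of scope — the tree module consumes posterior samples produced elsewhere.
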