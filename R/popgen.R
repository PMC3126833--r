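## Per-site allele counts over the selected rows; gaps and N are missing.
site_allele_counts <- function(m) {
  lapply(seq_len(ncol(m)), function(j) {
    b <- m[, j]
    table(factor(b[b %in% DNA_BASES], levels = DNA_BASES))
  })
}

#' Harmonic numbers used by theta estimators
#'
#' `a_n = sum(1/i, i = 1..n-1)` and `b_n = sum(1/i^2, i = 1..n-1)`.
#'
#' @param n number of chromosomes.
#' @return Numeric value.
#' @export
harmonic_a <- function(n) {
  stop_if(!is_count(n, 2), "n must be an integer >= 2")
  sum(1 / seq_len(n - 1))
}

#' @rdname harmonic_a
#' @export
harmonic_b <- function(n) {
  stop_if(!is_count(n, 2), "n must be an integer >= 2")
  sum(1 / seq_len(n - 1)^2)
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_w = S / (a_n * L)` per site, with `a_n` the harmonic number
#' `sum(1/i, i < n)`.
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes.
#' @param length aligned length in bp (excluding alignment gaps).
#' @return Per-site Watterson estimate (a proportion, not a percentage).
#' @export
#' @examples
#' 100 * watterson_theta(611, 40, 144055) # theta_w as a percentage
watterson_theta <- function(S, n, length) {
  stop_if(!is.numeric(S) || any(S < 0), "S must be >= 0")
  stop_if(length <= 0, "length must be positive")
  S / (harmonic_a(n) * length)
}

## Sum over sites of unbiased per-site heterozygosity; equals the mean
## number of pairwise differences when no data are missing.
pi_total <- function(m) {
  if (ncol(m) == 0) return(0)
  sum(vapply(site_allele_counts(m), function(cnt) {
    tot <- sum(cnt)
    if (tot < 2) return(0)
    (1 - sum((cnt / tot)^2)) * tot / (tot - 1)
  }, 0))
}

#' Nucleotide diversity
#'
#' Mean pairwise sequence difference per site, computed site-by-site with
#' missing bases (gaps, N) excluded pairwise, divided by the effective
#' alignment length.
#'
#' @param aln a [haplo_alignment].
#' @param pop optional population restriction.
#' @param per_site divide by effective length (default) or return the mean
#'   number of pairwise differences for the whole locus?
#' @return Numeric diversity estimate.
#' @export
nucleotide_diversity <- function(aln, pop = NULL, per_site = TRUE) {
  m <- allele_matrix(aln, pop)
  stop_if(nrow(m) < 2, "need at least 2 sequences")
  tot <- pi_total(m)
  if (per_site) tot / aln$n_sites else tot
}

## Tajima (1989) normalizing constants.
tajima_constants <- function(n) {
  a1 <- harmonic_a(n); a2 <- harmonic_b(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-difference and
#' segregating-sites estimators of theta. Negative values indicate an excess
#' of rare variants. Returns `NA` (flagged undefined) when there are no
#' segregating sites.
#'
#' @inheritParams nucleotide_diversity
#' @return Scalar D, or `NA_real_` when S = 0.
#' @export
tajimas_d <- function(aln, pop = NULL) {
  m <- allele_matrix(aln, pop)
  n <- nrow(m)
  stop_if(n < 3, "Tajima's D needs at least 3 chromosomes")
  S <- n_segregating(aln, pop)
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total(m) - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fu and Li's D* (no outgroup)
#'
#' Contrasts the number of singletons (alleles observed in exactly one
#' sequence) with the total number of segregating sites, using the corrected
#' published variance constants. Returns `NA` when there are no segregating
#' sites.
#'
#' @inheritParams nucleotide_diversity
#' @return Scalar D*, or `NA_real_` when S = 0.
#' @export
fu_li_dstar <- function(aln, pop = NULL) {
  m <- allele_matrix(aln, pop)
  n <- nrow(m)
  stop_if(n < 3, "Fu and Li's D* needs at least 3 chromosomes")
  S <- n_segregating(aln, pop)
  if (S == 0) return(NA_real_)
  eta_s <- sum(vapply(site_allele_counts(m), function(cnt) sum(cnt == 1), 0))
  a <- harmonic_a(n); b <- harmonic_b(n)
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * (a + 1 / n) - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  ((n / (n - 1)) * S - a * eta_s) / sqrt(uD * S + vD * S^2)
}

#' Per-locus summary statistics
#'
#' One row of per-locus diversity statistics: sample size, effective length,
#' segregating sites, per-site pi and Watterson's theta, Tajima's D and
#' Fu & Li's D*.
#'
#' @inheritParams nucleotide_diversity
#' @return A one-row `data.frame`.
#' @export
locus_summary <- function(aln, pop = NULL) {
  m <- allele_matrix(aln, pop)
  n <- nrow(m)
  S <- n_segregating(aln, pop)
  data.frame(
    n = n, length = aln$n_sites, S = S,
    pi = pi_total(m) / aln$n_sites,
    theta_w = watterson_theta(S, n, aln$n_sites),
    tajima_d = if (n >= 3 && S > 0) tajimas_d(aln, pop) else NA_real_,
    fu_li_dstar = if (n >= 3 && S > 0) fu_li_dstar(aln, pop) else NA_real_
  )
}

#' Evolutionary rate parameters for Ne estimation
#'
#' The per-generation, per-site mutation rate is derived from interspecies
#' divergence as `mu = (d / 2t) * g`: divergence accumulated along two
#' lineages over `t` years, converted to a per-generation rate with
#' generation time `g`.
#'
#' @param d sequence divergence to the outgroup species (proportion).
#' @param t divergence time in years.
#' @param g generation time in years.
#' @return A list of class `evolutionary_rates` with the derived `mu`.
#' @export
#' @examples
#' evolutionary_rates(d = 0.0135, t = 6e6, g = 20)$mu
evolutionary_rates <- function(d = 0.0135, t = 6e6, g = 20) {
  stop_if(d <= 0 || t <= 0 || g <= 0, "d, t and g must be positive")
  structure(list(d = d, t = t, g = g, mu = (d / (2 * t)) * g),
            class = "evolutionary_rates")
}

#' Effective population size from Watterson's theta
#'
#' `Ne = theta_w / (4 mu)` with `mu = (d / 2t) * g`.
#'
#' @param theta_w per-site Watterson estimate (proportion).
#' @param rates an [evolutionary_rates] object.
#' @return Estimated effective population size.
#' @export
#' @examples
#' tw <- watterson_theta(611, 40, 144055)
#' effective_size(tw, evolutionary_rates())
effective_size <- function(theta_w, rates = evolutionary_rates()) {
  stopifnot(inherits(rates, "evolutionary_rates"))
  stop_if(theta_w < 0, "theta_w must be >= 0")
  theta_w / (4 * rates$mu)
}

#' Mean coalescent time in years
#'
#' The expected coalescent time of DNA sequences, ~4 Ne generations.
#'
#' @param ne effective population size.
#' @param g generation time in years.
#' @return Time in years.
#' @export
#' @examples
#' mean_coalescent_time(35000, 20) # 2.8 million years
mean_coalescent_time <- function(ne, g = 20) {
  stop_if(ne < 0 || g <= 0, "ne must be >= 0 and g > 0")
  4 * ne * g
}

#' Pooled multi-locus diversity table
#'
#' Pools loci per population the way multilocus resequencing studies report
#' them: summed segregating sites and lengths, length-pooled per-site pi and
#' theta_w, Tajima's D and Fu & Li's D* computed on the pooled data, and Ne
#' from the pooled theta_w. Percentages are rounded to two decimals and Ne
#' to the nearest hundred in the formatted columns.
#'
#' @param loci list of [haplo_alignment] objects sharing populations.
#' @param pops population names to report; default: all present.
#' @param rates an [evolutionary_rates] object, or `NULL` to skip Ne.
#' @return A `data.frame` with one row per population, carrying both raw
#'   (`pi`, `theta_w`, `ne`) and Table-style rounded (`pi_pct`,
#'   `theta_w_pct`, `ne_rounded`) columns.
#' @export
diversity_table <- function(loci, pops = NULL,
                            rates = evolutionary_rates()) {
  if (inherits(loci, "haplo_alignment")) loci <- list(loci)
  if (is.null(pops)) pops <- unique(unlist(lapply(loci, function(a) a$pop_map)))
  rows <- lapply(pops, function(p) {
    per <- lapply(loci, function(a) if (p %in% a$pop_map) a else NULL)
    per <- Filter(Negate(is.null), per)
    stop_if(length(per) == 0, "population not present in any locus: ", p)
    n <- max(vapply(per, function(a) length(ingroup_labels(a, p)), 0L))
    L <- sum(vapply(per, function(a) a$n_sites, 0L))
    S <- sum(vapply(per, function(a) n_segregating(a, p), 0L))
    pit <- sum(vapply(per, function(a) pi_total(allele_matrix(a, p)), 0))
    tw <- watterson_theta(S, n, L)
    ## pooled D statistics: computed on the concatenated data
    k <- tajima_constants(n)
    td <- if (S > 0) (pit - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
          else NA_real_
    eta_s <- sum(vapply(per, function(a) {
      m <- allele_matrix(a, p)
      sum(vapply(site_allele_counts(m), function(cnt) sum(cnt == 1), 0))
    }, 0))
    ds <- if (S > 0) {
      a1 <- k$a1; b <- harmonic_b(n)
      cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
      dn <- cn + (n - 2) / (n - 1)^2 +
        (2 / (n - 1)) * (1.5 - (2 * (a1 + 1 / n) - 3) / (n - 2) - 1 / n)
      vD <- ((n / (n - 1))^2 * b + a1^2 * dn -
               2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + b)
      uD <- (n / (n - 1)) * (a1 - n / (n - 1)) - vD
      ((n / (n - 1)) * S - a1 * eta_s) / sqrt(uD * S + vD * S^2)
    } else NA_real_
    ne <- if (is.null(rates)) NA_real_ else effective_size(tw, rates)
    data.frame(population = p, n = n, length = L, S = S,
               pi = pit / L, theta_w = tw, ne = ne,
               tajima_d = td, fu_li_dstar = ds,
               pi_pct = round(100 * pit / L, 2),
               theta_w_pct = round(100 * tw, 2),
               ne_rounded = if (is.na(ne)) NA_real_ else round(ne / 100) * 100)
  })
  do.call(rbind, rows)
}
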