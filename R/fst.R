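#' Per-site allele frequencies for a pair of populations
#'
#' Extracts, across one or more loci, every biallelic site usable for Fst:
#' sites where exactly two bases segregate across the pooled pair and both
#' populations have at least one called chromosome.
#'
#' @param loci a [haplo_alignment] or list of them.
#' @param pop_a,pop_b population names.
#' @return A `data.frame` with columns `p1`, `p2` (frequency of an arbitrary
#'   reference allele in each population) and `n1`, `n2` (called
#'   chromosomes).
#' @export
pair_site_frequencies <- function(loci, pop_a, pop_b) {
  if (inherits(loci, "haplo_alignment")) loci <- list(loci)
  rows <- lapply(loci, function(aln) {
    ma <- allele_matrix(aln, pop_a)
    mb <- allele_matrix(aln, pop_b)
    if (ncol(ma) == 0) return(NULL)
    out <- lapply(seq_len(ncol(ma)), function(j) {
      a <- ma[, j]; b <- mb[, j]
      a <- a[a %in% DNA_BASES]; b <- b[b %in% DNA_BASES]
      alle <- unique(c(a, b))
      if (length(alle) != 2 || !length(a) || !length(b)) return(NULL)
      ref <- alle[1]
      data.frame(p1 = mean(a == ref), p2 = mean(b == ref),
                 n1 = length(a), n2 = length(b))
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(p1 = numeric(0), p2 = numeric(0),
                                      n1 = integer(0), n2 = integer(0))
  out
}

#' Hudson-type pairwise Fst
#'
#' `Fst = 1 - mean(Hw) / mean(Hb)` combined across sites as a ratio of
#' averages, where per site `Hw` is the average within-population
#' heterozygosity `2 p (1 - p)` of the two populations and
#' `Hb = p1 (1 - p2) + p2 (1 - p1)` is the between-population
#' heterozygosity. Identical allele frequencies give 0 and alternatively
#' fixed alleles give 1 by construction.
#'
#' @param x either a `data.frame` from [pair_site_frequencies] or a
#'   [haplo_alignment] (or list of them), in which case `pop_a`/`pop_b`
#'   must be given.
#' @param pop_a,pop_b population names (when `x` holds alignments).
#' @return Scalar Fst estimate.
#' @export
pairwise_fst <- function(x, pop_a = NULL, pop_b = NULL) {
  freqs <- if (is.data.frame(x)) x else {
    stop_if(is.null(pop_a) || is.null(pop_b),
            "pop_a and pop_b are required with alignment input")
    pair_site_frequencies(x, pop_a, pop_b)
  }
  stop_if(nrow(freqs) == 0, "no usable biallelic sites for this pair")
  hw <- (2 * freqs$p1 * (1 - freqs$p1) + 2 * freqs$p2 * (1 - freqs$p2)) / 2
  hb <- freqs$p1 * (1 - freqs$p2) + freqs$p2 * (1 - freqs$p1)
  stop_if(sum(hb) == 0, "no between-population heterozygosity at usable sites")
  min(1, 1 - sum(hw) / sum(hb))
}

#' Pairwise Fst matrix over all populations
#'
#' @param loci a [haplo_alignment] or list of them.
#' @param pops population names; default: all present.
#' @return A symmetric matrix of pairwise Fst values (diagonal 0).
#' @export
fst_matrix <- function(loci, pops = NULL) {
  if (inherits(loci, "haplo_alignment")) loci <- list(loci)
  if (is.null(pops)) pops <- unique(unlist(lapply(loci, function(a) a$pop_map)))
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      f <- pairwise_fst(loci, pops[i], pops[j])
      m[i, j] <- m[j, i] <- f
    }
  }
  m
}

#' Classify shared polymorphic and fixed sites between two populations
#'
#' Every biallelic site with a called outgroup base matching one of the two
#' segregating alleles is polarized and assigned to exactly one of five
#' mutually exclusive categories: (1) population B polymorphic / population A
#' fixed derived; (2) population A polymorphic / population B fixed derived;
#' (3) both polymorphic; (4) population B fixed derived / population A fixed
#' ancestral; (5) population A fixed derived / population B fixed ancestral.
#' Sites whose outgroup carries a third allele are skipped.
#'
#' @param loci a [haplo_alignment] or list of them; each needs an outgroup.
#' @param pop_a,pop_b population names (A plays the role bonobos play in the
#'   original design, B the chimpanzees).
#' @return A named integer vector of class `site_class_counts` with the five
#'   category counts and attributes `n_polarized` (sites classified) and
#'   `n_skipped` (outgroup carried a third allele).
#' @export
classify_shared_sites <- function(loci, pop_a, pop_b) {
  if (inherits(loci, "haplo_alignment")) loci <- list(loci)
  cats <- c(b_poly_a_fixed_derived = 0L, a_poly_b_fixed_derived = 0L,
            both_polymorphic = 0L, b_fixed_derived_a_ancestral = 0L,
            a_fixed_derived_b_ancestral = 0L)
  skipped <- 0L; polarized <- 0L; other <- 0L
  for (aln in loci) {
    stop_if(is.null(aln$outgroup_label), "outgroup required to polarize sites")
    ma <- allele_matrix(aln, pop_a)
    mb <- allele_matrix(aln, pop_b)
    og <- aln$alleles[aln$outgroup_label, ]
    for (j in seq_along(aln$positions)) {
      a <- ma[, j]; b <- mb[, j]
      a <- a[a %in% DNA_BASES]; b <- b[b %in% DNA_BASES]
      alle <- unique(c(a, b))
      if (length(alle) != 2 || !length(a) || !length(b)) next
      if (!og[j] %in% alle) { skipped <- skipped + 1L; next }
      anc <- og[j]; der <- setdiff(alle, anc)
      fa <- length(unique(a)) == 1; fb <- length(unique(b)) == 1
      polarized <- polarized + 1L
      if (!fa && !fb) cats["both_polymorphic"] <- cats["both_polymorphic"] + 1L
      else if (!fb && fa && a[1] == der)
        cats["b_poly_a_fixed_derived"] <- cats["b_poly_a_fixed_derived"] + 1L
      else if (!fa && fb && b[1] == der)
        cats["a_poly_b_fixed_derived"] <- cats["a_poly_b_fixed_derived"] + 1L
      else if (fa && fb && b[1] == der && a[1] == anc)
        cats["b_fixed_derived_a_ancestral"] <- cats["b_fixed_derived_a_ancestral"] + 1L
      else if (fa && fb && a[1] == der && b[1] == anc)
        cats["a_fixed_derived_b_ancestral"] <- cats["a_fixed_derived_b_ancestral"] + 1L
      else { # one population polymorphic, the other fixed ancestral
        polarized <- polarized - 1L
        other <- other + 1L
      }
    }
  }
  structure(cats, n_polarized = polarized, n_skipped = skipped,
            n_other = other, class = "site_class_counts")
}

#' @export
print.site_class_counts <- function(x, ...) {
  cat("Derived-allele sharing site classification\n")
  for (i in seq_along(x)) cat(sprintf("  %-28s %d\n", names(x)[i], x[i]))
  cat("  polarized:", attr(x, "n_polarized"),
      " skipped (triallelic outgroup):", attr(x, "n_skipped"), "\n")
  invisible(x)
}
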