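## Shared fixture builders (everything generated in code; no data files).

## 5-haplotype toy alignment with hand-chosen variable sites; the frozen
## expected values for pi / D (dendropy) and D* (hand evaluation of the
## published formulas) refer to exactly this matrix.
toy_alignment <- function() {
  alle <- rbind(
    h1 = c("A", "C", "G", "T", "A", "C"),
    h2 = c("A", "C", "G", "T", "A", "C"),
    h3 = c("G", "C", "T", "T", "A", "C"),
    h4 = c("G", "T", "T", "A", "A", "C"),
    h5 = c("G", "T", "T", "A", "C", "T"))
  haplo_alignment(alle, positions = c(5, 17, 30, 44, 60, 78),
                  locus_length = 100,
                  pop_map = stats::setNames(rep("p", 5), rownames(alle)))
}

## Singleton-heavy variant: every mutation private to h5 (eta_s = S = 6).
toy_singletons <- function() {
  alle <- rbind(h1 = rep("A", 6), h2 = rep("A", 6), h3 = rep("A", 6),
                h4 = rep("A", 6), h5 = rep("G", 6))
  haplo_alignment(alle, positions = (1:6) * 10, locus_length = 100,
                  pop_map = stats::setNames(rep("p", 5), rownames(alle)))
}

## A pileup built read-by-read: `alleles` gives the base shown at `site` by
## each read; all other bases match the consensus. Qualities default to a
## clean profile that passes every filter.
build_pileup <- function(consensus, site, alleles,
                         starts = NULL, strands = NULL,
                         read_len = 21, site_quals = NULL,
                         flank_quals = 30, read_quality = NULL) {
  n <- length(alleles)
  L <- nchar(consensus)
  starts <- starts %||% rep(max(1L, site - (read_len %/% 2)), n)
  strands <- strands %||% rep(c("+", "-"), length.out = n)
  site_quals <- site_quals %||% rep(30L, n)
  read_quality <- read_quality %||% seq(30, 30 + n - 1)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  reads <- lapply(seq_len(n), function(i) {
    s <- starts[i]
    e <- min(L, s + read_len - 1L)
    b <- cons[s:e]
    b[site - s + 1L] <- alleles[i]
    q <- rep(as.integer(flank_quals), length(b))
    q[site - s + 1L] <- as.integer(site_quals[i])
    list(start = s, strand = strands[i], bases = paste(b, collapse = ""),
         read_quality = read_quality[i], qual = q)
  })
  df <- data.frame(start = vapply(reads, `[[`, 0, "start"),
                   strand = vapply(reads, `[[`, "", "strand"),
                   bases = vapply(reads, `[[`, "", "bases"),
                   read_quality = vapply(reads, `[[`, 0, "read_quality"),
                   stringsAsFactors = FALSE)
  df$qual <- lapply(reads, `[[`, "qual")
  read_pileup(consensus, df)
}

## Consensus free of homopolymer runs >= `max_run` (alternating pattern).
clean_consensus <- function(L, max_run = 2) {
  paste(rep_len(c("A", "C", "G", "T"), L), collapse = "")
}

## Independent per-site Fst oracle: plain loops over sites, no shared code
## with pairwise_fst().
fst_oracle <- function(freqs) {
  num <- 0; den <- 0
  for (k in seq_len(nrow(freqs))) {
    p1 <- freqs$p1[k]; p2 <- freqs$p2[k]
    hw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    num <- num + hw; den <- den + hb
  }
  1 - num / den
}

## Exhaustive pairwise nucleotide-diversity oracle.
pi_oracle <- function(aln, pop = NULL) {
  m <- aln$alleles[names(aln$pop_map), , drop = FALSE]
  if (!is.null(pop)) m <- m[aln$pop_map[rownames(m)] %in% pop, , drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}
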