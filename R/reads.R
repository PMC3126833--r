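#' Read-simulator configuration
#'
#' Emulates the error modes of 454 pyrosequencing amplicon data that the SNP
#' caller's filter cascade is designed to absorb: emulsion-PCR duplicates
#' (identical start and strand), unequal amplification of the two alleles of
#' a PCR product (allelic imbalance, in the extreme allelic dropout), base
#' miscalls at a rate implied by the per-base quality score, and
#' homopolymer over-/under-calls whose probability grows with run length.
#'
#' @param mean_coverage expected reads per site.
#' @param read_length read length in bp.
#' @param duplicate_rate fraction of reads duplicated with the same start and
#'   strand (in `[0, 1)`).
#' @param allele_balance expected fraction of reads drawn from the first
#'   allele at heterozygous sites (`0.5` = unbiased; must be in `(0, 0.5]`).
#' @param dropout if `TRUE`, the first allele is silenced entirely.
#' @param homopolymer_error_rate per-run indel probability scale; a run of
#'   length `k` suffers an indel with probability
#'   `min(0.5, rate * (k - 1))`.
#' @param quality_mean,quality_sd normal parameters for per-base quality
#'   scores (truncated to `[5, 40]`); the implied miscall probability per
#'   base is `10^(-q/10)`.
#' @param seed optional RNG seed stored with the configuration.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_coverage = 20, read_length = 250,
                            duplicate_rate = 0.05, allele_balance = 0.5,
                            dropout = FALSE, homopolymer_error_rate = 0.002,
                            quality_mean = 30, quality_sd = 5, seed = NULL) {
  stop_if(mean_coverage <= 0, "coverage must be positive")
  stop_if(duplicate_rate < 0 || duplicate_rate >= 1,
          "duplicate_rate must be in [0, 1)")
  stop_if(allele_balance <= 0 || allele_balance > 0.5,
          "allele_balance must be in (0, 0.5]")
  structure(list(mean_coverage = mean_coverage, read_length = read_length,
                 duplicate_rate = duplicate_rate,
                 allele_balance = allele_balance, dropout = dropout,
                 homopolymer_error_rate = homopolymer_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = seed),
            class = "read_sim_config")
}

#' Aligned-read pileup container
#'
#' Reads aligned to a consensus sequence. Internally coordinates are
#' 1-based (R convention); the on-disk TSV dialect and SAM use their own
#' conventions. Each read records its start, strand, aligned bases (with
#' `-` marking deletions relative to the consensus), per-base qualities for
#' the non-gap bases, and a scalar read quality.
#'
#' @param consensus consensus/reference sequence (single string).
#' @param reads `data.frame` with columns `start` (1-based), `strand`
#'   (`"+"`/`"-"`), `bases` (aligned string), `read_quality`, and a list
#'   column `qual` of integer vectors (one per non-gap base).
#' @return An object of class `read_pileup`.
#' @export
read_pileup <- function(consensus, reads) {
  stop_if(nchar(consensus) == 0, "empty consensus")
  L <- nchar(consensus)
  if (nrow(reads) > 0) {
    ends <- reads$start + nchar(reads$bases) - 1L
    stop_if(any(reads$start < 1) || any(ends > L),
            "read alignment outside consensus bounds")
    ngap <- vapply(strsplit(reads$bases, "", fixed = TRUE),
                   function(b) sum(b != "-"), 0L)
    qlen <- vapply(reads$qual, length, 0L)
    stop_if(any(ngap != qlen), "quality vectors must match non-gap base counts")
  }
  structure(list(consensus = consensus, reads = reads), class = "read_pileup")
}

#' @export
print.read_pileup <- function(x, ...) {
  cat("Read pileup:", nrow(x$reads), "reads over",
      nchar(x$consensus), "bp consensus\n")
  invisible(x)
}

## Homopolymer runs (length >= min_len) in a character vector of bases.
homopolymer_runs <- function(chars, min_len = 2) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values %in% DNA_BASES
  data.frame(start = starts[keep], end = ends[keep],
             len = r$lengths[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Simulate a 454-style read set for one diploid PCR product
#'
#' Draws reads alternately from the two haplotypes (biased by
#' `allele_balance`, or from only one under dropout), adds quality-dependent
#' miscalls and homopolymer indels, and duplicates a fraction of reads with
#' identical start and strand. The consensus is the second (major) allele,
#' as an iterative mapping assembler would call it under allelic imbalance.
#'
#' @param haplotypes character vector of the two haplotype sequences (equal
#'   length).
#' @param config a [read_sim_config].
#' @param seed integer RNG seed (overrides the one in `config`).
#' @return A [read_pileup] with attributes `truth_het_sites` (planted
#'   heterozygous positions), `read_hap` (source haplotype per read) and
#'   `config`.
#' @export
simulate_reads <- function(haplotypes, config = read_sim_config(),
                           seed = NULL) {
  stopifnot(inherits(config, "read_sim_config"))
  stop_if(length(haplotypes) != 2, "need exactly two haplotypes")
  stop_if(any(nchar(haplotypes) == 0), "zero-length haplotypes")
  stop_if(nchar(haplotypes[1]) != nchar(haplotypes[2]),
          "haplotypes must have equal length")
  seed <- seed %||% config$seed
  with_seed(seed, {
    L <- nchar(haplotypes[1])
    hap_chars <- strsplit(haplotypes, "", fixed = TRUE)
    het_sites <- which(hap_chars[[1]] != hap_chars[[2]])
    runs <- lapply(hap_chars, homopolymer_runs)
    len <- min(config$read_length, L)
    n_reads <- max(1L, round(config$mean_coverage * L / len))
    p_hap1 <- if (config$dropout) 0 else config$allele_balance
    make_read <- function(hap_i, start, strand) {
      tmpl <- hap_chars[[hap_i]][start:(start + len - 1L)]
      q <- pmin(40L, pmax(5L, as.integer(round(
        stats::rnorm(len, config$quality_mean, config$quality_sd)))))
      err <- stats::runif(len) < 10^(-q / 10)
      if (any(err)) {
        tmpl[err] <- vapply(tmpl[err], function(b)
          sample(setdiff(DNA_BASES, b), 1), "")
      }
      rr <- runs[[hap_i]]
      ov <- rr[rr$end >= start & rr$start <= start + len - 1L, , drop = FALSE]
      for (k in seq_len(nrow(ov))) {
        p_ind <- min(0.5, config$homopolymer_error_rate * (ov$len[k] - 1))
        if (stats::runif(1) >= p_ind) next
        if (stats::runif(1) < 0.5) { # undercall: one run base dropped
          lo <- max(ov$start[k], start); hi <- min(ov$end[k], start + len - 1L)
          pos <- if (lo == hi) lo else sample(lo:hi, 1)
          tmpl[pos - start + 1L] <- "-"
        } else {                     # overcall: run base bleeds past the run
          pos <- ov$end[k] + 1L
          if (pos >= start && pos <= start + len - 1L) {
            tmpl[pos - start + 1L] <- ov$base[k]
            ## flowgram confidence collapses at the run boundary; the
            ## miscalled base carries a low quality score
            q[pos - start + 1L] <- sample(5:12, 1)
          }
        }
      }
      bases <- paste(tmpl, collapse = "")
      qv <- q[tmpl != "-"]
      list(start = start, strand = strand, bases = bases,
           read_quality = round(mean(q), 1), qual = list(qv))
    }
    hap_i <- ifelse(stats::runif(n_reads) < p_hap1, 1L, 2L)
    starts <- sample.int(L - len + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads))
      reads[[i]] <- make_read(hap_i[i], starts[i], strands[i])
    dup <- which(stats::runif(n_reads) < config$duplicate_rate)
    for (i in dup) {
      reads[[length(reads) + 1L]] <- make_read(hap_i[i], starts[i], strands[i])
      hap_i <- c(hap_i, hap_i[i])
    }
    df <- data.frame(start = vapply(reads, `[[`, 0, "start"),
                     strand = vapply(reads, `[[`, "", "strand"),
                     bases = vapply(reads, `[[`, "", "bases"),
                     read_quality = vapply(reads, `[[`, 0, "read_quality"),
                     stringsAsFactors = FALSE)
    df$qual <- lapply(reads, function(r) r$qual[[1]])
    pl <- read_pileup(haplotypes[2], df)
    attr(pl, "truth_het_sites") <- het_sites
    attr(pl, "read_hap") <- hap_i
    attr(pl, "config") <- config
    pl
  })
}

#' Write / read the TSV pileup dialect
#'
#' One read per line with columns `start` (0-based offset into the
#' consensus), `strand`, `bases` (aligned string, `-` = deletion), `quals`
#' (comma-separated integers, one per non-gap base) and `read_quality`. The
#' consensus is carried in a `## consensus=` header line.
#'
#' @param pileup a [read_pileup].
#' @param file path.
#' @return `write_pileup_tsv` returns the path invisibly;
#'   `read_pileup_tsv` returns a [read_pileup].
#' @export
write_pileup_tsv <- function(pileup, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("## consensus=", pileup$consensus), con)
  writeLines("start\tstrand\tbases\tquals\tread_quality", con)
  r <- pileup$reads
  if (nrow(r) > 0) {
    writeLines(paste(r$start - 1L, r$strand, r$bases,
                     vapply(r$qual, paste, "", collapse = ","),
                     r$read_quality, sep = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^## consensus=", lines, value = TRUE)
  stop_if(length(hdr) != 1, "pileup TSV must carry one '## consensus=' header")
  consensus <- sub("^## consensus=", "", hdr)
  body <- lines[!startsWith(lines, "#")]
  stop_if(length(body) < 1, "missing column header line")
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  reads <- data.frame(start = df$start + 1L, strand = df$strand,
                      bases = df$bases, read_quality = df$read_quality,
                      stringsAsFactors = FALSE)
  reads$qual <- lapply(strsplit(as.character(df$quals), ",", fixed = TRUE),
                       as.integer)
  read_pileup(consensus, reads)
}

#' Read a SAM-subset file into a pileup
#'
#' Parses the minimal column subset needed here: `POS`, the strand bit of
#' `FLAG`, `SEQ`, `QUAL` (Phred+33) and `CIGAR` restricted to M/I/D (and
#' S, whose clipped bases are dropped). Inserted bases have no place in
#' consensus coordinates and are dropped; deletions become `-`.
#'
#' @param file path to a SAM file.
#' @param consensus consensus sequence the reads are aligned to; if `NULL`,
#'   taken from the `@SQ` `LN` field as an `N`-run (positions only).
#' @return A [read_pileup].
#' @export
read_sam <- function(file, consensus = NULL) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (is.null(consensus)) {
    sq <- grep("^@SQ", hdr, value = TRUE)
    stop_if(length(sq) == 0, "no @SQ header and no consensus supplied")
    ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq[1]))
    consensus <- strrep("N", ln)
  }
  reads <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); pos <- as.integer(f[4])
    cigar <- f[6]; seqc <- strsplit(f[10], "", fixed = TRUE)[[1]]
    qualc <- utf8ToInt(f[11]) - 33L
    ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
    stop_if(length(ops) != length(ops_len), "unsupported CIGAR: ", cigar)
    bases <- character(0); qual <- integer(0); qi <- 1L
    for (k in seq_along(ops)) {
      n <- ops_len[k]
      if (ops[k] == "M") {
        bases <- c(bases, seqc[qi:(qi + n - 1L)])
        qual <- c(qual, qualc[qi:(qi + n - 1L)])
        qi <- qi + n
      } else if (ops[k] == "D") {
        bases <- c(bases, rep("-", n))
      } else { # I or S: consumes query only
        qi <- qi + n
      }
    }
    list(start = pos, strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
         bases = paste(bases, collapse = ""),
         read_quality = round(mean(qualc), 1), qual = qual)
  })
  df <- data.frame(start = vapply(reads, `[[`, 0L, "start"),
                   strand = vapply(reads, `[[`, "", "strand"),
                   bases = vapply(reads, `[[`, "", "bases"),
                   read_quality = vapply(reads, `[[`, 0, "read_quality"),
                   stringsAsFactors = FALSE)
  df$qual <- lapply(reads, `[[`, "qual")
  read_pileup(consensus, df)
}
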