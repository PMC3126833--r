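#' SNP-calling parameters
#'
#' Thresholds of the filter cascade. Defaults are the values tuned for 454
#' amplicon data: minimum post-dedup/post-gap-filter depth 8, heterozygote
#' minor-allele read fraction strictly above 0.15, neighbour-quality-score
#' cutoffs 20 (site) / 15 (five flanking bases per side), gap-proximity
#' window 5 bp, at most one mismatch within 5 bp around the site,
#' homopolymers of length >= 6 blocking a 20 bp window, and a region skew
#' threshold of 0.30.
#'
#' @param min_depth minimum read depth after duplicate and gap-proximity
#'   filtering.
#' @param maf minor-allele read fraction that must be exceeded (strictly)
#'   for a heterozygous call.
#' @param nqs length-2 vector: quality cutoff at the site and at flanking
#'   bases.
#' @param gap_window reads with an alignment gap within this many bp of the
#'   site are excluded there.
#' @param mismatch_window,max_mismatches a read is excluded at a site if it
#'   shows more than `max_mismatches` mismatches to the consensus within
#'   `mismatch_window` bp around the site (the site itself excluded).
#' @param homopolymer_len,homopolymer_window no SNP is called where a
#'   homopolymer of at least `homopolymer_len` bases intersects the
#'   `homopolymer_window`-bp window centred on the site.
#' @param skew_maf regional skew threshold: a region is flagged when every
#'   SNP's minor-allele fraction is below this value.
#' @return An object of class `call_params`.
#' @export
call_params <- function(min_depth = 8, maf = 0.15, nqs = c(20, 15),
                        gap_window = 5, mismatch_window = 5,
                        max_mismatches = 1, homopolymer_len = 6,
                        homopolymer_window = 20, skew_maf = 0.30) {
  stop_if(length(nqs) != 2, "nqs must be length 2: c(site, flank)")
  structure(list(min_depth = min_depth, maf = maf, nqs = nqs,
                 gap_window = gap_window, mismatch_window = mismatch_window,
                 max_mismatches = max_mismatches,
                 homopolymer_len = homopolymer_len,
                 homopolymer_window = homopolymer_window,
                 skew_maf = skew_maf),
            class = "call_params")
}

#' Remove emulsion-PCR duplicate reads
#'
#' For each group of reads with identical strand and start position, only
#' the read with the highest read quality is retained (first in input order
#' on ties). Idempotent and never increases depth.
#'
#' @param pileup a [read_pileup].
#' @return A deduplicated [read_pileup].
#' @export
dedup_reads <- function(pileup) {
  r <- pileup$reads
  if (nrow(r) <= 1) return(pileup)
  key <- paste(r$strand, r$start)
  ## stable: order by quality (desc) with input order as tiebreak
  ord <- order(-r$read_quality, seq_len(nrow(r)))
  keep <- sort(ord[!duplicated(key[ord])])
  out <- pileup
  out$reads <- r[keep, , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

## Precompute per-read structures used by the site filters.
explode_pileup <- function(pileup) {
  r <- pileup$reads
  chars <- strsplit(r$bases, "", fixed = TRUE)
  quals <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    q <- rep(NA_integer_, length(chars[[i]]))
    q[chars[[i]] != "-"] <- r$qual[[i]]
    quals[[i]] <- q
  }
  list(consensus = strsplit(pileup$consensus, "", fixed = TRUE)[[1]],
       start = r$start, end = r$start + lengths(chars) - 1L,
       chars = chars, quals = quals, n = nrow(r))
}

#' Is a site blocked by a nearby homopolymer?
#'
#' `TRUE` iff a run of at least `homopolymer_len` identical bases intersects
#' the `homopolymer_window`-bp window centred on the site (site +/- half the
#' window).
#'
#' @param consensus consensus sequence (string).
#' @param position 1-based site.
#' @param params a [call_params].
#' @return Logical.
#' @export
site_homopolymer_blocked <- function(consensus, position,
                                     params = call_params()) {
  stop_if(position < 1 || position > nchar(consensus),
          "position outside consensus")
  homopolymer_mask(consensus, params)[position]
}

## Logical mask over all consensus positions blocked by homopolymers.
homopolymer_mask <- function(consensus, params = call_params()) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(chars)
  mask <- rep(FALSE, L)
  runs <- homopolymer_runs(chars, min_len = params$homopolymer_len)
  half <- floor(params$homopolymer_window / 2)
  for (k in seq_len(nrow(runs))) {
    lo <- max(1L, runs$start[k] - half)
    hi <- min(L, runs$end[k] + half)
    mask[lo:hi] <- TRUE
  }
  mask
}

## Core per-read filter evaluation against precomputed context.
read_filters_impl <- function(ctx, i, position, params) {
  stop_if(position < ctx$start[i] || position > ctx$end[i],
          "position not covered by read")
  off <- position - ctx$start[i] + 1L
  ch <- ctx$chars[[i]]; qv <- ctx$quals[[i]]
  w <- params$gap_window
  lo <- max(1L, off - w); hi <- min(length(ch), off + w)
  gap5 <- any(ch[lo:hi] == "-")
  mw <- params$mismatch_window
  lo2 <- max(1L, off - mw); hi2 <- min(length(ch), off + mw)
  nb <- setdiff(lo2:hi2, off)
  cons_nb <- ctx$consensus[ctx$start[i] + nb - 1L]
  mism <- sum(ch[nb] != "-" & ch[nb] != cons_nb) > params$max_mismatches
  nqs_fail <- is.na(qv[off]) || qv[off] < params$nqs[1]
  if (!nqs_fail) {
    fl <- setdiff(max(1L, off - 5L):min(length(ch), off + 5L), off)
    fq <- qv[fl]
    nqs_fail <- any(!is.na(fq) & fq < params$nqs[2])
  }
  list(pass = !gap5 && !mism && !nqs_fail,
       gap5 = gap5, mismatch = mism, nqs = nqs_fail)
}

#' Per-read site filters
#'
#' Evaluates, for one read at one site, the gap-proximity filter (any
#' alignment gap within `gap_window` bp of the site), the mismatch filter
#' (more than `max_mismatches` mismatches to the consensus within
#' `mismatch_window` bp, site excluded) and the neighbour-quality-score
#' filter (site quality >= 20 and the five flanking bases on each side
#' >= 15, clipped at read ends).
#'
#' @param pileup a [read_pileup].
#' @param read index of the read in `pileup$reads`.
#' @param position 1-based site, which must be covered by the read.
#' @param params a [call_params].
#' @return A list with `pass` and the individual fail flags `gap5`,
#'   `mismatch`, `nqs`.
#' @export
read_passes_site_filters <- function(pileup, read, position,
                                     params = call_params()) {
  ctx <- explode_pileup(pileup)
  read_filters_impl(ctx, read, position, params)
}

## Full decision rule at one site, against precomputed context.
call_site_impl <- function(ctx, position, params, hp_blocked) {
  no_call <- function(flags, depth = 0L)
    list(position = position, status = "no_call", major = NA_character_,
         minor = NA_character_, maf = NA_real_, depth = depth, flags = flags)
  cov <- which(ctx$start <= position & ctx$end >= position)
  cov <- cov[vapply(cov, function(i)
    ctx$chars[[i]][position - ctx$start[i] + 1L] != "-", TRUE)]
  if (length(cov) == 0) return(no_call("uncovered"))
  filt <- lapply(cov, read_filters_impl, ctx = ctx, position = position,
                 params = params)
  gap_ok <- !vapply(filt, `[[`, TRUE, "gap5")
  depth12 <- sum(gap_ok)
  if (depth12 < params$min_depth) return(no_call("low_coverage", depth12))
  if (hp_blocked) return(no_call("homopolymer", depth12))
  kept <- cov[gap_ok]
  support <- kept[vapply(filt[gap_ok], `[[`, TRUE, "pass")]
  if (length(support) == 0) {
    flags <- unique(c("mismatch", "nqs")[c(
      any(vapply(filt, `[[`, TRUE, "mismatch")),
      any(vapply(filt, `[[`, TRUE, "nqs")))])
    return(no_call(flags, depth12))
  }
  ## allele counts come from all reads surviving filters 1-2; the mismatch
  ## and quality filters gate per-allele support, not the frequency itself
  base_at <- function(i) ctx$chars[[i]][position - ctx$start[i] + 1L]
  bases <- vapply(kept, base_at, "")
  cnt <- sort(table(bases), decreasing = TRUE)
  if (length(cnt) > 2) return(no_call("triallelic", depth12))
  supp_bases <- vapply(support, base_at, "")
  major <- names(cnt)[1]
  minor <- if (length(cnt) == 2) names(cnt)[2] else NA_character_
  maf <- if (length(cnt) == 2) cnt[[2]] / sum(cnt) else 0
  het <- length(cnt) == 2 && maf > params$maf &&
    major %in% supp_bases && minor %in% supp_bases
  list(position = position,
       status = if (het) "heterozygous" else "homozygous",
       major = major, minor = if (het) minor else NA_character_,
       maf = maf, depth = depth12, flags = character(0))
}

#' Call one site
#'
#' Applies the full decision rule at one position of an already
#' deduplicated pileup: no call if depth after the duplicate and
#' gap-proximity filters is below `min_depth`, or if the site sits in a
#' homopolymer context, or if no read survives the mismatch and
#' neighbour-quality filters; heterozygous if the minor-allele fraction
#' (computed over the reads surviving the duplicate and gap filters)
#' strictly exceeds `maf` and each allele is supported by at least one read
#' passing the mismatch and neighbour-quality filters; homozygous
#' otherwise.
#'
#' @param pileup a deduplicated [read_pileup] (see [dedup_reads]).
#' @param position 1-based site.
#' @param params a [call_params].
#' @return A list of class `site_call` with `position`, `status`
#'   (`"heterozygous"`, `"homozygous"`, `"no_call"`), `major`, `minor`,
#'   `maf`, `depth` (after filters 1-2) and `flags`.
#' @export
call_site <- function(pileup, position, params = call_params()) {
  stop_if(position < 1 || position > nchar(pileup$consensus),
          "position outside consensus")
  ctx <- explode_pileup(pileup)
  hp <- site_homopolymer_blocked(pileup$consensus, position, params)
  structure(call_site_impl(ctx, position, params, hp), class = "site_call")
}

#' Call all sites of a region
#'
#' Deduplicates the pileup, screens every position, runs the full filter
#' cascade at candidate sites (positions where more than one base is
#' observed), and summarizes the region: per-site status, SNP table, the
#' allele-imbalance skew flag (every SNP's minor-allele fraction below
#' `skew_maf`) and the all-homozygous flag (no heterozygous call in the
#' whole region) used to trigger re-amplification with a second primer
#' pair.
#'
#' @param pileup a [read_pileup] (deduplication is applied internally).
#' @param params a [call_params].
#' @return An object of class `region_call_report`: list with `site_status`
#'   (character vector over all positions: `"uncovered"`, `"no_call"`,
#'   `"homozygous"`, `"heterozygous"`), `calls` (`data.frame` for candidate
#'   sites), `skew_flag`, `all_homozygous_flag` and summary `counts`.
#' @export
call_region <- function(pileup, params = call_params()) {
  stop_if(nrow(pileup$reads) == 0, "empty pileup")
  pileup <- dedup_reads(pileup)
  ctx <- explode_pileup(pileup)
  L <- length(ctx$consensus)
  hp_mask <- homopolymer_mask(pileup$consensus, params)

  ## vectorized coverage and base tallies
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  cov_tab <- integer(L)
  code_tab <- integer(4L * L)
  for (i in seq_len(ctx$n)) {
    pos <- ctx$start[i]:ctx$end[i]
    nz <- ctx$chars[[i]] %in% DNA_BASES
    p <- pos[nz]
    cov_tab[p] <- cov_tab[p] + 1L
    bc <- base_code[ctx$chars[[i]][nz]]
    idx <- (p - 1L) * 4L + bc
    code_tab[idx] <- code_tab[idx] + 1L
  }
  ## depth after the gap-proximity filter
  depth12 <- cov_tab
  w <- params$gap_window
  for (i in seq_len(ctx$n)) {
    gaps <- which(ctx$chars[[i]] == "-")
    if (length(gaps) == 0) next
    excl <- unique(unlist(lapply(gaps, function(g)
      max(1L, g - w):min(length(ctx$chars[[i]]), g + w))))
    excl <- excl[ctx$chars[[i]][excl] != "-"]
    p <- ctx$start[i] + excl - 1L
    depth12[p] <- depth12[p] - 1L
  }
  nbase <- colSums(matrix(code_tab > 0L, nrow = 4L))
  candidates <- which(nbase >= 2L)

  status <- rep("uncovered", L)
  covered <- cov_tab > 0L
  status[covered] <- ifelse(depth12[covered] >= params$min_depth,
                            "homozygous", "no_call")
  calls <- lapply(candidates, function(p) {
    sc <- call_site_impl(ctx, p, params, hp_mask[p])
    status[p] <<- sc$status
    data.frame(position = p, status = sc$status,
               major = sc$major %||% NA_character_,
               minor = sc$minor %||% NA_character_,
               maf = sc$maf, depth = sc$depth,
               flags = paste(sc$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(position = integer(0), status = character(0),
                           major = character(0), minor = character(0),
                           maf = numeric(0), depth = integer(0),
                           flags = character(0), stringsAsFactors = FALSE)
  het <- calls[calls$status == "heterozygous", , drop = FALSE]
  skew <- nrow(het) >= 1 && all(het$maf < params$skew_maf)
  counts <- c(n_sites = L, n_covered = sum(covered),
              n_callable = sum(depth12 >= params$min_depth & !hp_mask),
              n_het = nrow(het),
              n_no_call = sum(status == "no_call"))
  structure(list(site_status = status, calls = calls, skew_flag = skew,
                 all_homozygous_flag = nrow(het) == 0, counts = counts,
                 params = params),
            class = "region_call_report")
}

#' @export
print.region_call_report <- function(x, ...) {
  cat("Region call report\n")
  cat(sprintf("  sites %d | covered %d | callable %d | heterozygous %d\n",
              x$counts["n_sites"], x$counts["n_covered"],
              x$counts["n_callable"], x$counts["n_het"]))
  cat("  skew flag:", x$skew_flag,
      "| all-homozygous flag:", x$all_homozygous_flag, "\n")
  invisible(x)
}

#' Write calls as a VCF-like TSV
#'
#' One line per candidate site with 1-based positions: CHROM (region id),
#' POS, REF (consensus base), ALT (minor allele for heterozygous calls),
#' MAF, DEPTH and FILTER flags.
#'
#' @param report a `region_call_report`.
#' @param file output path.
#' @param consensus consensus sequence used for the REF column.
#' @param chrom region identifier.
#' @return Invisibly, the path.
#' @export
write_calls <- function(report, file, consensus = NULL, chrom = "region") {
  calls <- report$calls
  ref <- if (!is.null(consensus))
    substring(consensus, calls$position, calls$position) else NA_character_
  df <- data.frame(CHROM = chrom, POS = calls$position, REF = ref,
                   ALT = ifelse(is.na(calls$minor), ".", calls$minor),
                   STATUS = calls$status,
                   MAF = round(calls$maf, 4), DEPTH = calls$depth,
                   FILTER = ifelse(nzchar(calls$flags), calls$flags, "PASS"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
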