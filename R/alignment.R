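#' Haplotype alignment container
#'
#' A compact container for a locus-wide haplotype alignment: bases are stored
#' only at variable (segregating) positions together with the total and
#' effective alignment length, sample labels, a label-to-population map and an
#' optional outgroup row used to polarize ancestral/derived states. Full
#' sequences (needed for FASTA export) can be attached but are optional, so
#' that large simulation studies never materialize invariant columns.
#'
#' @param alleles character matrix (samples x variable sites) of bases in
#'   `{A,C,G,T,N,-}`; row names are sample labels.
#' @param positions 1-based positions of the variable sites in the locus.
#' @param locus_length total aligned length in bp.
#' @param pop_map named character vector mapping ingroup sample labels to
#'   population names.
#' @param outgroup_label label of the outgroup row, or `NULL`.
#' @param n_sites effective number of aligned sites (excluding masked or
#'   gapped columns); defaults to `locus_length`.
#' @param sequences optional named character vector of full-length sequences.
#'
#' @return An object of class `haplo_alignment`.
#' @export
haplo_alignment <- function(alleles, positions, locus_length, pop_map,
                            outgroup_label = NULL, n_sites = locus_length,
                            sequences = NULL) {
  alleles <- as.matrix(alleles)
  stop_if(is.null(rownames(alleles)), "alleles matrix needs row names (sample labels)")
  stop_if(ncol(alleles) != length(positions),
          "positions length must match number of variable sites")
  stop_if(!is_count(locus_length, 1), "locus_length must be a positive integer")
  if (length(positions) && (any(positions < 1) || any(positions > locus_length)))
    stop("variable-site positions outside the locus", call. = FALSE)
  labels <- rownames(alleles)
  ingroup <- setdiff(labels, outgroup_label)
  missing_pop <- setdiff(ingroup, names(pop_map))
  stop_if(length(missing_pop) > 0,
          "labels missing from pop_map: ", paste(missing_pop, collapse = ", "))
  stop_if(!is.null(outgroup_label) && !outgroup_label %in% labels,
          "outgroup_label not present among sequence labels")
  structure(list(
    alleles = alleles,
    positions = as.integer(positions),
    locus_length = as.integer(locus_length),
    n_sites = as.integer(n_sites),
    pop_map = pop_map[ingroup],
    outgroup_label = outgroup_label,
    sequences = sequences
  ), class = "haplo_alignment")
}

#' @export
print.haplo_alignment <- function(x, ...) {
  pops <- table(x$pop_map)
  cat("Haplotype alignment:", length(x$pop_map), "haplotypes,",
      x$locus_length, "bp,", length(x$positions), "segregating sites\n")
  cat("  populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  if (!is.null(x$outgroup_label)) cat("  outgroup:", x$outgroup_label, "\n")
  invisible(x)
}

## Labels of the ingroup, optionally restricted to one population.
ingroup_labels <- function(aln, pop = NULL) {
  labs <- names(aln$pop_map)
  if (!is.null(pop)) {
    labs <- labs[aln$pop_map %in% pop]
    stop_if(length(labs) == 0, "no samples in population(s): ",
            paste(pop, collapse = ", "))
  }
  labs
}

## Allele matrix restricted to selected samples (no outgroup unless asked).
allele_matrix <- function(aln, pop = NULL) {
  aln$alleles[ingroup_labels(aln, pop), , drop = FALSE]
}

#' Number of segregating sites
#'
#' Counts alignment columns with at least two distinct called bases (gaps and
#' `N` are treated as missing) among the selected samples.
#'
#' @param aln a [haplo_alignment].
#' @param pop optional population name(s) to restrict to.
#' @return Integer count of segregating sites.
#' @export
n_segregating <- function(aln, pop = NULL) {
  m <- allele_matrix(aln, pop)
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) {
    b <- col[col %in% DNA_BASES]
    length(unique(b)) >= 2
  }))
}

#' Read a multi-FASTA haplotype alignment
#'
#' Population labels are taken either from a `pop=` tag in the FASTA
#' description line or from a two-column (sample, population) TSV.
#'
#' @param file path to an aligned multi-FASTA file.
#' @param pop_map named character vector or path to a TSV with columns
#'   `sample` and `population`; may be `NULL` if every description line
#'   carries a `pop=` tag.
#' @param outgroup_label label of the outgroup record, if present.
#' @return A [haplo_alignment] with full sequences attached.
#' @export
read_haplotypes <- function(file, pop_map = NULL, outgroup_label = NULL) {
  dna <- ape::read.FASTA(file)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  headers <- names(seqs)
  labels <- sub("\\s.*$", "", headers)
  names(seqs) <- labels
  if (is.null(pop_map)) {
    tag <- regmatches(headers, regexpr("pop=\\S+", headers))
    has <- grepl("pop=", headers)
    pop_map <- structure(sub("^pop=", "", tag), names = labels[has])
  } else if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pm <- utils::read.delim(pop_map, header = TRUE, stringsAsFactors = FALSE)
    pop_map <- structure(pm$population, names = pm$sample)
  }
  alignment_from_sequences(seqs, pop_map, outgroup_label)
}

#' Build a haplotype alignment from full sequences
#'
#' @param seqs named character vector of equal-length sequences.
#' @inheritParams haplo_alignment
#' @return A [haplo_alignment].
#' @export
alignment_from_sequences <- function(seqs, pop_map, outgroup_label = NULL) {
  lens <- nchar(seqs)
  stop_if(length(unique(lens)) != 1, "sequences differ in length")
  L <- lens[[1]]
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  ingroup <- setdiff(names(seqs), outgroup_label)
  sub <- mat[ingroup, , drop = FALSE]
  ok_col <- colSums(sub == "-" | sub == "N") == 0
  variable <- apply(sub, 2, function(col) length(unique(col[col %in% DNA_BASES])) >= 2)
  keep <- which(variable & ok_col)
  haplo_alignment(mat[, keep, drop = FALSE], keep, L, pop_map, outgroup_label,
                  n_sites = sum(ok_col), sequences = seqs)
}

#' Write an alignment as multi-FASTA
#'
#' The population of each haplotype is encoded as a `pop=` tag on the
#' description line. Requires full sequences; simulated alignments must have
#' been generated with `sequences = TRUE`.
#'
#' @param aln a [haplo_alignment] carrying full sequences.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
write_fasta <- function(aln, file) {
  stop_if(is.null(aln$sequences),
          "alignment has no full sequences; simulate with sequences = TRUE")
  labs <- names(aln$sequences)
  desc <- ifelse(labs %in% names(aln$pop_map),
                 paste0(labs, " pop=", aln$pop_map[labs]),
                 ifelse(labs == (aln$outgroup_label %||% ""),
                        paste0(labs, " outgroup"), labs))
  out <- character(2 * length(labs))
  out[c(TRUE, FALSE)] <- paste0(">", desc)
  out[c(FALSE, TRUE)] <- unname(aln$sequences)
  writeLines(out, file)
  invisible(file)
}

#' Write alignments in ms-style text format
#'
#' Emits the familiar `//` / `segsites:` / `positions:` blocks with a 0/1
#' haplotype matrix (0 = ancestral), one block per alignment, for
#' interoperability with coalescent-era tooling. Alignments lacking a known
#' ancestral state (no outgroup row) cannot be written.
#'
#' @param alns a [haplo_alignment] or list of them.
#' @param file output path.
#' @param cmd header line to write first.
#' @return Invisibly, the file path.
#' @export
write_ms <- function(alns, file, cmd = "pansort simulate") {
  if (inherits(alns, "haplo_alignment")) alns <- list(alns)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(cmd, ""), con)
  for (aln in alns) {
    stop_if(is.null(aln$outgroup_label), "ms output needs an outgroup/ancestral row")
    anc <- aln$alleles[aln$outgroup_label, ]
    m <- allele_matrix(aln)
    writeLines("//", con)
    writeLines(paste("segsites:", ncol(m)), con)
    if (ncol(m) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", (aln$positions - 0.5) / aln$locus_length),
                             collapse = " ")), con)
      digits <- matrix("1", nrow(m), ncol(m))
      digits[sweep(m, 2, anc, "==")] <- "0"
      writeLines(apply(digits, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(file)
}
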