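cons60 <- function() clean_consensus(61)

test_that("duplicate removal keeps the best read per strand/start group", {
  cons <- cons60()
  pl <- build_pileup(cons, site = 31, alleles = c("A", "C", "G"),
                     starts = c(21, 21, 21), strands = c("+", "+", "+"),
                     read_quality = c(20, 30, 25))
  dd <- dedup_reads(pl)
  expect_identical(nrow(dd$reads), 1L)
  expect_identical(dd$reads$read_quality, 30)
  ## unique (strand, start) groups are untouched
  pl2 <- build_pileup(cons, site = 31, alleles = c("A", "C"),
                      starts = c(21, 22), strands = c("+", "+"))
  expect_identical(dedup_reads(pl2)$reads, pl2$reads)
  ## quality tie: first in input order wins
  pl3 <- build_pileup(cons, site = 31, alleles = c("A", "C"),
                      starts = c(21, 21), strands = c("-", "-"),
                      read_quality = c(25, 25))
  dd3 <- dedup_reads(pl3)
  expect_identical(dd3$reads$bases, pl3$reads$bases[1])
  ## idempotent, never increases depth
  expect_identical(dedup_reads(dd), dd)
  expect_lte(nrow(dd$reads), nrow(pl$reads))
})

test_that("per-read site filters implement the gap, mismatch and NQS rules", {
  cons <- cons60()
  ## gap 3 bp left of the site -> gap-proximity fail
  pl <- build_pileup(cons, site = 31, alleles = "A", starts = 21)
  b <- strsplit(pl$reads$bases, "")[[1]]
  b[31 - 21 + 1 - 3] <- "-"
  pl$reads$bases <- paste(b, collapse = "")
  pl$reads$qual[[1]] <- pl$reads$qual[[1]][-1] # one fewer non-gap base
  f <- read_passes_site_filters(pl, 1, 31)
  expect_true(f$gap5); expect_false(f$pass)
  ## NQS boundary: middle exactly 20, flanks exactly 15 -> pass
  pl2 <- build_pileup(cons, site = 31, alleles = "A",
                      site_quals = 20, flank_quals = 15)
  f2 <- read_passes_site_filters(pl2, 1, 31)
  expect_false(f2$nqs); expect_true(f2$pass)
  ## middle 19 -> fail
  pl3 <- build_pileup(cons, site = 31, alleles = "A", site_quals = 19,
                      flank_quals = 15)
  expect_true(read_passes_site_filters(pl3, 1, 31)$nqs)
  ## flank 14 -> fail
  pl4 <- build_pileup(cons, site = 31, alleles = "A", site_quals = 20,
                      flank_quals = 14)
  expect_true(read_passes_site_filters(pl4, 1, 31)$nqs)
  ## two mismatches within 5 bp -> fail; one mismatch -> pass
  pl5 <- build_pileup(cons, site = 31, alleles = "A")
  b5 <- strsplit(pl5$reads$bases, "")[[1]]
  off <- 31 - pl5$reads$start[1] + 1
  swap <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]
  b5[off + 2] <- swap(b5[off + 2]); b5[off - 2] <- swap(b5[off - 2])
  pl5$reads$bases <- paste(b5, collapse = "")
  expect_true(read_passes_site_filters(pl5, 1, 31)$mismatch)
  b5[off - 2] <- swap(b5[off - 2]) # revert one (swap is an involution? no)
  ## rebuild with exactly one mismatch instead
  pl6 <- build_pileup(cons, site = 31, alleles = "A")
  b6 <- strsplit(pl6$reads$bases, "")[[1]]
  b6[off + 2] <- swap(b6[off + 2])
  pl6$reads$bases <- paste(b6, collapse = "")
  expect_false(read_passes_site_filters(pl6, 1, 31)$mismatch)
  ## site not covered by the read -> error
  expect_error(read_passes_site_filters(pl6, 1, 2), "not covered")
})

test_that("homopolymer blocking uses run length >= 6 intersecting the 20 bp window", {
  base <- strsplit(clean_consensus(101), "")[[1]]
  ## run of 6 starting 8 bp from the site: blocked
  c1 <- base; c1[59:64] <- "A"
  expect_true(site_homopolymer_blocked(paste(c1, collapse = ""), 51))
  ## longest run 5: not blocked
  c2 <- base; c2[59:63] <- "A"
  expect_false(site_homopolymer_blocked(paste(c2, collapse = ""), 51))
  ## run of 6 just intersecting the window edge: blocked
  c3 <- base; c3[61:66] <- "A"  # window of site 51 is [41, 61]
  expect_true(site_homopolymer_blocked(paste(c3, collapse = ""), 51))
  c4 <- base; c4[63:68] <- "A"  # fully outside (62 is C, breaking the run)
  expect_false(site_homopolymer_blocked(paste(c4, collapse = ""), 51))
  ## brute-force window-scan oracle on random consensi
  set.seed(5)
  for (r in 1:10) {
    cc <- paste(sample(c("A", "C", "G", "T"), 80, TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    chars <- strsplit(cc, "")[[1]]
    for (pos in c(5, 20, 40, 60, 76)) {
      win <- max(1, pos - 10):min(80, pos + 10)
      oracle <- any(vapply(win, function(w) {
        run <- 1; i <- w
        while (i > 1 && chars[i - 1] == chars[w]) { run <- run + 1; i <- i - 1 }
        i <- w
        while (i < 80 && chars[i + 1] == chars[w]) { run <- run + 1; i <- i + 1 }
        run >= 6
      }, TRUE))
      expect_identical(site_homopolymer_blocked(cc, pos), oracle)
    }
  }
})

test_that("the site decision rule applies depth and minor-allele thresholds", {
  cons <- cons60()
  ## 10 clean reads, 5 A / 5 G -> heterozygous with maf 0.5
  pl <- build_pileup(cons, site = 31, alleles = rep(c("A", "G"), 5),
                     starts = 16 + seq_len(10))
  sc <- call_site(pl, 31)
  expect_identical(sc$status, "heterozygous")
  expect_equal(sc$maf, 0.5)
  ## 7 reads -> no call (low coverage)
  pl7 <- build_pileup(cons, site = 31, alleles = rep(c("A", "G"), length.out = 7),
                      starts = 16 + seq_len(7))
  sc7 <- call_site(pl7, 31)
  expect_identical(sc7$status, "no_call")
  expect_true("low_coverage" %in% sc7$flags)
  ## 1 G / 9 A -> homozygous (maf 0.10 not above 0.15)
  pl9 <- build_pileup(cons, site = 31, alleles = c(rep("A", 9), "G"),
                      starts = 16 + seq_len(10))
  sc9 <- call_site(pl9, 31)
  expect_identical(sc9$status, "homozygous")
  expect_identical(sc9$major, "A")
  expect_equal(sc9$maf, 0.1)
  ## exactly 0.15 is not above 0.15: 3 of 20 -> homozygous
  pl20 <- build_pileup(cons, site = 31, alleles = c(rep("A", 17), rep("G", 3)),
                       starts = 11 + seq_len(20))
  expect_identical(call_site(pl20, 31)$status, "homozygous")
  ## 4 of 20 (0.20) -> heterozygous
  pl20b <- build_pileup(cons, site = 31, alleles = c(rep("A", 16), rep("G", 4)),
                        starts = 11 + seq_len(20))
  expect_identical(call_site(pl20b, 31)$status, "heterozygous")
  ## three alleles -> no call, flagged
  pl3a <- build_pileup(cons, site = 31, alleles = c(rep("A", 4), rep("G", 3),
                                                    rep("T", 3)),
                       starts = 16 + seq_len(10))
  sc3 <- call_site(pl3a, 31)
  expect_identical(sc3$status, "no_call")
  expect_true("triallelic" %in% sc3$flags)
})

test_that("heterozygous calls require a quality-passing read from each allele", {
  cons <- cons60()
  ## minor-allele reads all fail NQS -> their reads drop out -> homozygous
  pl <- build_pileup(cons, site = 31, alleles = c(rep("A", 8), "G", "G"),
                     starts = 16 + seq_len(10),
                     site_quals = c(rep(30, 8), 10, 10))
  sc <- call_site(pl, 31)
  expect_identical(sc$status, "homozygous")
  expect_identical(sc$major, "A")
})

test_that("region calling sets skew and all-homozygous flags per definition", {
  cons <- clean_consensus(161)
  ## three SNPs with minor-read fractions 0.20, 0.25, 0.28 -> skew
  mk <- function(site, n_minor, n_total = 20) {
    build_pileup(cons, site = site,
                 alleles = c(rep("A", n_total - n_minor), rep("G", n_minor)),
                 starts = site - 20 + seq_len(n_total))
  }
  merge_pileups <- function(...) {
    pls <- list(...)
    reads <- do.call(rbind, lapply(pls, function(p) p$reads))
    read_pileup(pls[[1]]$consensus, reads)
  }
  pl <- merge_pileups(mk(41, 4), mk(81, 5), mk(121, 6, 21))
  rep <- call_region(pl)
  mafs <- rep$calls$maf[rep$calls$status == "heterozygous"]
  expect_identical(length(mafs), 3L)
  expect_true(all(mafs < 0.30))
  expect_true(rep$skew_flag)
  expect_false(rep$all_homozygous_flag)
  ## one SNP at 0.45 releases the skew flag
  pl2 <- merge_pileups(mk(41, 4), mk(81, 9))
  rep2 <- call_region(pl2)
  expect_false(rep2$skew_flag)
  ## no heterozygous call at all -> all-homozygous, no skew
  pl3 <- merge_pileups(mk(41, 0), mk(81, 0))
  rep3 <- call_region(pl3)
  expect_true(rep3$all_homozygous_flag)
  expect_false(rep3$skew_flag)
  expect_error(call_region(read_pileup(cons, data.frame())), "empty")
})

test_that("adding filters never increases the number of heterozygous calls", {
  set.seed(91)
  cons_hap <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  hap2 <- strsplit(cons_hap, "")[[1]]
  snps <- seq(100, 2900, by = 150)
  for (s in snps) hap2[s] <- setdiff(c("A", "C", "G", "T"), hap2[s])[1]
  pl <- simulate_reads(c(paste(hap2, collapse = ""), cons_hap),
                       read_sim_config(mean_coverage = 15, quality_mean = 22,
                                       homopolymer_error_rate = 0.02,
                                       duplicate_rate = 0.2), seed = 14)
  relaxed <- call_params(min_depth = 1, maf = 0, nqs = c(0, 0),
                         gap_window = 0, max_mismatches = 100,
                         homopolymer_len = 1000)
  n_het <- function(p) sum(call_region(pl, p)$calls$status == "heterozygous")
  base <- n_het(relaxed)
  one_at_a_time <- c(
    depth = n_het(call_params(min_depth = 8, maf = 0, nqs = c(0, 0),
                              gap_window = 0, max_mismatches = 100,
                              homopolymer_len = 1000)),
    maf = n_het(call_params(min_depth = 1, maf = 0.15, nqs = c(0, 0),
                            gap_window = 0, max_mismatches = 100,
                            homopolymer_len = 1000)),
    nqs = n_het(call_params(min_depth = 1, maf = 0, nqs = c(20, 15),
                            gap_window = 0, max_mismatches = 100,
                            homopolymer_len = 1000)),
    gap = n_het(call_params(min_depth = 1, maf = 0, nqs = c(0, 0),
                            gap_window = 5, max_mismatches = 100,
                            homopolymer_len = 1000)),
    hp = n_het(call_params(min_depth = 1, maf = 0, nqs = c(0, 0),
                           gap_window = 0, max_mismatches = 100,
                           homopolymer_len = 6)),
    all = n_het(call_params()))
  expect_true(all(one_at_a_time <= base))
  expect_lte(one_at_a_time[["all"]], min(one_at_a_time))
})

test_that("site calls depend only on reads near the site", {
  cons <- clean_consensus(200)
  pl <- build_pileup(cons, site = 50, alleles = rep(c("A", "G"), 5),
                     starts = 35 + seq_len(10))
  far <- build_pileup(cons, site = 150, alleles = rep("T", 3),
                      starts = 135 + seq_len(3))
  both <- read_pileup(cons, rbind(pl$reads, far$reads))
  a <- call_site(pl, 50); b <- call_site(both, 50)
  expect_identical(a[c("status", "major", "minor", "maf", "depth")],
                   b[c("status", "major", "minor", "maf", "depth")])
})

test_that("pileup TSV and SAM-subset readers reproduce alignments", {
  cons <- cons60()
  pl <- build_pileup(cons, site = 31, alleles = c("A", "G", "C"),
                     starts = c(20, 25, 30))
  f <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pl, f)
  back <- read_pileup_tsv(f)
  expect_identical(back$reads$start, as.integer(pl$reads$start))
  expect_identical(back$reads$bases, pl$reads$bases)
  expect_identical(back$reads$qual, lapply(pl$reads$qual, as.integer))
  ## SAM: 2M1D3M with an insertion dropped
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:region\tLN:60",
           paste("r1", "0", "region", "5", "60", "2M1D2M1I3M", "*", "0", "0",
                 "ACGTAACG", "IIIIIIII", sep = "\t"),
           paste("r2", "16", "region", "10", "60", "4M", "*", "0", "0",
                 "TTTT", "5555", sep = "\t"))
  fs <- tempfile(fileext = ".sam")
  writeLines(sam, fs)
  sp <- read_sam(fs, cons)
  expect_identical(sp$reads$bases[1], "AC-GTACG")  # D -> gap, I dropped
  expect_identical(sp$reads$strand, c("+", "-"))
  expect_identical(sp$reads$qual[[2]], rep(20L, 4))
})
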