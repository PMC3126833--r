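balanced_sample <- function(n_mono, n_other, extra_runs = NULL) {
  mono <- ape::read.tree(text = "(((b1,b2),(c1,c2)),h);")
  mixed <- ape::read.tree(text = "(((b1,c1),(b2,c2)),h);")
  trees <- c(rep(list(mono), n_mono), rep(list(other <- mixed), n_other))
  pm <- c(b1 = "bonobo", b2 = "bonobo", c1 = "chimp", c2 = "chimp")
  tree_sample(trees, pm, "h", run = extra_runs)
}

test_that("clade membership tests match explicit cases and the ape oracle", {
  t1 <- ape::read.tree(text = "((b1,b2),(c1,c2));")
  expect_true(is_monophyletic(t1, c("b1", "b2")))
  t2 <- ape::read.tree(text = "((b1,c1),(b2,c2));")
  expect_false(is_monophyletic(t2, c("b1", "b2")))
  expect_true(is_monophyletic(t2, "b1"))
  expect_error(is_monophyletic(t1, c("b1", "zz")), "absent")
  set.seed(40)
  for (r in 1:200) {
    phy <- ape::rtree(20)
    grp <- sample(phy$tip.label, sample(2:8, 1))
    expect_identical(is_monophyletic(phy, grp),
                     unname(ape::is.monophyletic(phy, grp)))
  }
})

test_that("posterior monophyly applies the 95%/5% classification rule", {
  s913 <- balanced_sample(913, 87)
  r <- posterior_monophyly(s913, "bonobo", burnin = 0)
  expect_equal(r$posterior_probability, 0.913)
  expect_identical(r$classification, "ambiguous")
  s3 <- balanced_sample(3, 997)
  r3 <- posterior_monophyly(s3, "bonobo", burnin = 0)
  expect_equal(r3$posterior_probability, 0.003)
  expect_identical(r3$classification, "paraphyly_supported")
  s_all <- balanced_sample(50, 0)
  r_all <- posterior_monophyly(s_all, "bonobo", burnin = 0)
  expect_equal(r_all$posterior_probability, 1)
  expect_identical(r_all$classification, "monophyly_supported")
  ## boundary: exactly 0.95 is ambiguous (strict >)
  s95 <- balanced_sample(95, 5)
  expect_identical(posterior_monophyly(s95, "bonobo", burnin = 0)$classification,
                   "ambiguous")
})

test_that("burn-in discards the first fraction of each run before pooling", {
  ## two runs of 10; the first tree of each run is the only discordant one
  mono <- ape::read.tree(text = "(((b1,b2),(c1,c2)),h);")
  mixed <- ape::read.tree(text = "(((b1,c1),(b2,c2)),h);")
  trees <- c(list(mixed), rep(list(mono), 9), list(mixed), rep(list(mono), 9))
  pm <- c(b1 = "bonobo", b2 = "bonobo", c1 = "chimp", c2 = "chimp")
  ts <- tree_sample(trees, pm, "h", run = rep(1:2, each = 10))
  expect_equal(posterior_monophyly(ts, "bonobo", burnin = 0.10)$posterior_probability, 1)
  expect_lt(posterior_monophyly(ts, "bonobo", burnin = 0)$posterior_probability, 1)
})

test_that("reciprocal monophyly is bounded by each marginal probability", {
  set.seed(50)
  pm <- stats::setNames(rep(c("A", "B"), each = 4),
                        c(paste0("a", 1:4), paste0("b", 1:4)))
  trees <- lapply(1:60, function(i) ape::rtree(9,
    tip.label = sample(c(names(pm), "out"))))
  ts <- tree_sample(trees, pm, "out")
  rec <- reciprocal_monophyly(ts, "A", "B", burnin = 0)$posterior_probability
  pa <- posterior_monophyly(ts, "A", burnin = 0)$posterior_probability
  pb <- posterior_monophyly(ts, "B", burnin = 0)$posterior_probability
  expect_lte(rec, min(pa, pb))
  expect_error(reciprocal_monophyly(ts, c("a1", "a2"), c("a2", "b1")),
               "overlap")
  ## degenerate case: A always monophyletic, B never
  mono <- ape::read.tree(text = "(((a1,a2),(b1,(b2,a3))),out);")
  ts2 <- tree_sample(rep(list(mono), 5),
                     c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B"),
                     "out")
  expect_equal(reciprocal_monophyly(ts2, c("a1", "a2"), c("b1", "b2"),
                                    burnin = 0)$posterior_probability, 0)
})

test_that("tip order never changes posterior probabilities", {
  set.seed(60)
  pm <- stats::setNames(rep(c("A", "B"), each = 3),
                        c(paste0("a", 1:3), paste0("b", 1:3)))
  trees <- lapply(1:30, function(i) ape::rtree(7,
    tip.label = sample(c(names(pm), "out"))))
  ts <- tree_sample(trees, pm, "out")
  shuffled <- lapply(trees, function(t) {
    ## rotate internal nodes: write out and re-read reverses child order
    ape::read.tree(text = ape::write.tree(ape::rotateConstr(t,
      rev(t$tip.label))))
  })
  ts2 <- tree_sample(shuffled, pm, "out")
  expect_equal(posterior_monophyly(ts, "A", burnin = 0)$posterior_probability,
               posterior_monophyly(ts2, "A", burnin = 0)$posterior_probability)
})

test_that("majority consensus keeps exactly the strict-majority clades", {
  mono <- ape::read.tree(text = "(((b1,b2),(c1,c2)),h);")
  ## identical trees: consensus is that tree with all supports 1
  cons <- majority_consensus(rep(list(mono), 4))
  expect_true(ape::all.equal.phylo(cons, mono, use.edge.length = FALSE))
  expect_true(all(as.numeric(stats::na.omit(suppressWarnings(
    as.numeric(cons$node.label)))) == 1))
  ## clade in 2 of 3 trees retained with support 2/3
  t_alt <- ape::read.tree(text = "(((b1,c1),(b2,c2)),h);")
  cons2 <- majority_consensus(list(mono, mono, t_alt))
  sets <- pansort:::node_tip_sets(cons2)
  expect_true(any(vapply(sets, identical, TRUE, y = c("b1", "b2"))))
  labs <- suppressWarnings(as.numeric(cons2$node.label))
  expect_true(any(abs(labs - 2 / 3) < 1e-9, na.rm = TRUE))
  ## exact 50% ties are excluded (strict majority)
  cons3 <- majority_consensus(list(mono, t_alt))
  sets3 <- pansort:::node_tip_sets(cons3)
  expect_false(any(vapply(sets3, identical, TRUE, y = c("b1", "b2"))))
  expect_false(any(vapply(sets3, identical, TRUE, y = c("b1", "c1"))))
})

test_that("consensus bipartition frequencies match the ape tally", {
  set.seed(70)
  for (r in 1:5) {
    ## correlated sample: a backbone topology in 6 of 11 trees guarantees
    ## majority clades beyond the root
    backbone <- ape::rtree(8, tip.label = paste0("t", 1:8))
    trees <- c(rep(list(backbone), 6),
               lapply(1:5, function(i) ape::rtree(8,
                 tip.label = sample(paste0("t", 1:8)))))
    cons <- majority_consensus(trees)
    ## oracle tally via ape::prop.part on the same rooted trees
    pp <- ape::prop.part(trees)
    labs <- attr(pp, "labels")
    freq <- attr(pp, "number") / 11
    oracle_clades <- lapply(pp[freq > 0.5], function(i) sort(labs[i]))
    got <- pansort:::node_tip_sets(cons)
    in_cons <- vapply(oracle_clades, function(cl)
      any(vapply(got, identical, TRUE, y = cl)), TRUE)
    expect_true(all(in_cons))
    expect_gt(length(oracle_clades), 2) # the backbone clades are present
    ## no clade below the threshold sneaks in
    internal <- Filter(function(s) length(s) > 1 && length(s) < 8, got)
    ok <- vapply(internal, function(s) {
      idx <- which(vapply(pp, function(i) identical(sort(labs[i]), s), TRUE))
      length(idx) == 1 && freq[idx] > 0.5
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("lineage sorting increases monotonically with split time", {
  set.seed(80)
  taus <- c(0.1, 0.4, 0.8, 1.4, 2.2, 3.5)
  frac <- vapply(taus, function(tau) {
    mean(replicate(60, {
      aln <- simulate_split(split_model_params(c(4, 4), tau), theta = 0)
      g <- attr(aln, "genealogy")
      is_monophyletic(g, names(aln$pop_map)[aln$pop_map == "pop1"]) &&
        is_monophyletic(g, names(aln$pop_map)[aln$pop_map == "pop2"])
    }))
  }, 0)
  expect_gt(stats::cor(taus, frac, method = "spearman"), 0.99)
})

test_that("newick round trips through files preserve the sample", {
  mono <- ape::read.tree(text = "(((b1,b2),(c1,c2)),h);")
  t_alt <- ape::read.tree(text = "(((b1,c1),(b2,c2)),h);")
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".nwk")
  ape::write.tree(c(mono, mono), f1)
  ape::write.tree(c(t_alt), f2)
  pmf <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample = c("b1", "b2", "c1", "c2"),
                                population = c("bonobo", "bonobo",
                                               "chimp", "chimp")),
                     pmf, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- read_tree_sample(c(f1, f2), pmf, "h")
  expect_identical(length(ts$trees), 3L)
  expect_identical(ts$run, c(1L, 1L, 2L))
  expect_equal(posterior_monophyly(ts, "bonobo",
                                   burnin = 0)$posterior_probability, 2 / 3)
})
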