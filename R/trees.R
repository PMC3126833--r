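#' Posterior tree sample container
#'
#' A collection of (rooted or rootable) trees, a tip-to-population map, the
#' outgroup tip used for rooting, and per-tree run identifiers so that the
#' burn-in fraction can be discarded per run before pooling.
#'
#' @param trees an `ape::multiPhylo`, list of `phylo`, or single `phylo`.
#' @param pop_map named character vector mapping tip labels to populations
#'   (the outgroup tip need not appear).
#' @param outgroup_label tip label used for rooting; must be in every tree.
#' @param run optional vector of run identifiers (one per tree); defaults
#'   to a single run.
#' @return An object of class `tree_sample`.
#' @export
tree_sample <- function(trees, pop_map, outgroup_label, run = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) {
    tl <- attr(trees, "TipLabel")  # compressed multiPhylo shares tip labels
    trees <- unclass(trees)
    if (!is.null(tl))
      trees <- lapply(trees, function(t) { t$tip.label <- tl; t })
  } else trees <- unclass(trees)
  stop_if(length(trees) == 0, "empty tree sample")
  tips <- lapply(trees, `[[`, "tip.label")
  ref <- sort(tips[[1]])
  same <- all(vapply(tips, function(x) identical(sort(x), ref), TRUE))
  stop_if(!same, "all trees must share an identical tip set")
  stop_if(!outgroup_label %in% ref, "outgroup tip absent from trees")
  ingroup <- setdiff(ref, outgroup_label)
  missing <- setdiff(ingroup, names(pop_map))
  stop_if(length(missing) > 0,
          "tips missing from pop_map: ", paste(missing, collapse = ", "))
  run <- run %||% rep(1L, length(trees))
  stop_if(length(run) != length(trees), "run must have one entry per tree")
  structure(list(trees = trees, pop_map = pop_map[ingroup],
                 outgroup_label = outgroup_label, run = run),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "trees,",
      length(unique(x$run)), "run(s), outgroup", x$outgroup_label, "\n")
  invisible(x)
}

#' Read Newick tree files into a tree sample
#'
#' Each file (one tree per line, or a nexus trees block) is treated as one
#' run.
#'
#' @param files character vector of tree file paths.
#' @param pop_map named character vector or path to a TSV with columns
#'   `sample` and `population`.
#' @param outgroup_label outgroup tip label.
#' @return A [tree_sample].
#' @export
read_tree_sample <- function(files, pop_map, outgroup_label) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pm <- utils::read.delim(pop_map, stringsAsFactors = FALSE)
    pop_map <- structure(pm$population, names = pm$sample)
  }
  all_trees <- list(); run <- integer(0)
  for (i in seq_along(files)) {
    first <- readLines(files[i], n = 1)
    tr <- if (grepl("#NEXUS", first, ignore.case = TRUE))
      ape::read.nexus(files[i]) else ape::read.tree(files[i])
    if (inherits(tr, "phylo")) tr <- list(tr)
    all_trees <- c(all_trees, unclass(tr))
    run <- c(run, rep(i, length(tr)))
  }
  tree_sample(all_trees, pop_map, outgroup_label, run)
}

## Root a tree on the outgroup (no-op if already rooted there).
root_on_outgroup <- function(phy, outgroup) {
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

## Descendant tip-label sets of every internal node (own traversal; the
## independent check in the tests uses ape's implementation).
node_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  phy <- stats::reorder(phy, "postorder")
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  lapply(sets[(n + 1):(n + phy$Nnode)],
         function(s) sort(phy$tip.label[s]))
}

#' Is a tip group monophyletic on a rooted tree?
#'
#' `TRUE` iff some clade of the rooted tree contains exactly the group's
#' tips. Polytomies count only when the polytomy's full tip set equals the
#' group; singletons are trivially monophyletic.
#'
#' @param phy a `phylo` tree (rooted; root it on the outgroup first for
#'   posterior counting).
#' @param group character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(phy, group) {
  stop_if(!all(group %in% phy$tip.label),
          "group tips absent from tree: ",
          paste(setdiff(group, phy$tip.label), collapse = ", "))
  if (length(group) <= 1) return(TRUE)
  target <- sort(unique(group))
  any(vapply(node_tip_sets(phy), identical, TRUE, y = target))
}

## Trees retained after per-run burn-in removal, rooted on the outgroup.
retained_trees <- function(sample, burnin) {
  stop_if(burnin < 0 || burnin >= 1, "burnin must be in [0, 1)")
  keep <- unlist(lapply(unique(sample$run), function(r) {
    idx <- which(sample$run == r)
    drop <- floor(burnin * length(idx))
    idx[seq_along(idx) > drop]
  }))
  lapply(sample$trees[keep], root_on_outgroup,
         outgroup = sample$outgroup_label)
}

## Resolve a group argument (population name or explicit tip vector).
resolve_group <- function(sample, group) {
  if (length(group) == 1 && group %in% sample$pop_map)
    names(sample$pop_map)[sample$pop_map == group]
  else as.character(group)
}

classify_support <- function(p, support = c(0.95, 0.05)) {
  if (p > support[1]) "monophyly_supported"
  else if (p < support[2]) "paraphyly_supported"
  else "ambiguous"
}

#' Posterior probability of monophyly
#'
#' Fraction of post-burn-in, outgroup-rooted trees in which the group forms
#' a clade, pooled across runs. The classification applies the conventional
#' thresholds: support for monophyly above 0.95, support for paraphyly
#' below 0.05, otherwise ambiguous.
#'
#' @param sample a [tree_sample].
#' @param group a population name or vector of tip labels.
#' @param burnin fraction of each run discarded (default 0.10).
#' @param support length-2 vector of (monophyly, paraphyly) thresholds.
#' @return A list of class `monophyly_report` with `group`,
#'   `posterior_probability`, `classification`, `n_trees`.
#' @export
posterior_monophyly <- function(sample, group, burnin = 0.10,
                                support = c(0.95, 0.05)) {
  stopifnot(inherits(sample, "tree_sample"))
  tips <- resolve_group(sample, group)
  trees <- retained_trees(sample, burnin)
  stop_if(length(trees) == 0, "no trees left after burn-in")
  p <- mean(vapply(trees, is_monophyletic, TRUE, group = tips))
  structure(list(group = group, posterior_probability = p,
                 classification = classify_support(p, support),
                 n_trees = length(trees)),
            class = "monophyly_report")
}

#' Posterior probability of reciprocal monophyly
#'
#' Fraction of trees in which both groups are simultaneously monophyletic.
#' The groups must not overlap; together they normally cover the ingroup.
#'
#' @inheritParams posterior_monophyly
#' @param group_a,group_b population names or tip vectors.
#' @return A `monophyly_report`.
#' @export
reciprocal_monophyly <- function(sample, group_a, group_b, burnin = 0.10,
                                 support = c(0.95, 0.05)) {
  stopifnot(inherits(sample, "tree_sample"))
  ta <- resolve_group(sample, group_a)
  tb <- resolve_group(sample, group_b)
  stop_if(length(intersect(ta, tb)) > 0, "groups overlap")
  trees <- retained_trees(sample, burnin)
  stop_if(length(trees) == 0, "no trees left after burn-in")
  p <- mean(vapply(trees, function(t)
    is_monophyletic(t, ta) && is_monophyletic(t, tb), TRUE))
  structure(list(group = c(group_a, group_b), posterior_probability = p,
                 classification = classify_support(p, support),
                 n_trees = length(trees)),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("Monophyly of {%s}: p = %.4f over %d trees -> %s\n",
              paste(x$group, collapse = " + "),
              x$posterior_probability, x$n_trees, x$classification))
  invisible(x)
}

#' Strict-majority-rule consensus tree
#'
#' Builds the tree containing exactly the clades (on outgroup-rooted trees)
#' that appear in strictly more than half of the sample; clades at exactly
#' 50% are excluded, so the retained set is compatible by construction.
#' Node labels carry the clade frequencies.
#'
#' @param sample a [tree_sample], or a list of rooted `phylo` trees.
#' @param burnin burn-in fraction (only for `tree_sample` input).
#' @return A `phylo` tree with `node.label` giving each clade's frequency.
#' @export
majority_consensus <- function(sample, burnin = 0) {
  trees <- if (inherits(sample, "tree_sample"))
    retained_trees(sample, burnin)
  else if (inherits(sample, "phylo")) list(sample)
  else lapply(sample, identity)
  stop_if(length(trees) == 0, "empty tree sample")
  m <- length(trees)
  tally <- new.env(parent = emptyenv())
  for (t in trees) {
    for (s in node_tip_sets(t)) {
      key <- paste(s, collapse = "\r")
      assign(key, (get0(key, tally) %||% 0L) + 1L, tally)
    }
  }
  keys <- ls(tally)
  freq <- vapply(keys, get, 0L, envir = tally) / m
  keep <- freq > 0.5
  clades <- lapply(strsplit(keys[keep], "\r", fixed = TRUE), identity)
  freq <- freq[keep]
  all_tips <- sort(trees[[1]]$tip.label)
  ## ensure the root clade is present
  root_key <- paste(all_tips, collapse = "\r")
  if (!root_key %in% keys[keep]) {
    clades <- c(clades, list(all_tips))
    freq <- c(freq, 1)
  }
  ## nest clades: parent = smallest strictly containing clade
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]; freq <- freq[ord]
  build <- function(i) {
    tips <- clades[[i]]
    children <- integer(0)
    claimed <- character(0)
    for (j in seq_along(clades)) {
      if (j == i || length(clades[[j]]) >= length(tips)) next
      if (all(clades[[j]] %in% tips) && !any(clades[[j]] %in% claimed)) {
        children <- c(children, j)
        claimed <- c(claimed, clades[[j]])
      }
    }
    free <- setdiff(tips, claimed)
    parts <- c(vapply(children, build, ""), free)
    sprintf("(%s)%.10g", paste(parts, collapse = ","), freq[i])
  }
  ape::read.tree(text = paste0(build(1L), ";"))
}
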