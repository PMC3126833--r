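#' Coalescent model parameters
#'
#' Parameters of a single-population, constant-size (optionally exponentially
#' growing) neutral coalescent for one locus. Time is measured in units of
#' 4N generations, so `theta = 4*N*mu*L` and `rho = 4*N*r*L` are the usual
#' per-locus population mutation and recombination rates.
#'
#' @param n_samples number of sampled chromosomes (>= 2).
#' @param locus_length locus length in bp.
#' @param theta population mutation rate per locus (4Ne mu L).
#' @param rho population recombination rate per locus (4Ne r L).
#' @param growth_rate exponential growth parameter alpha, with
#'   `N(t) = N0 * exp(-alpha t)` looking back in time; 0 = constant size.
#' @return An object of class `coalescent_params`.
#' @export
coalescent_params <- function(n_samples, locus_length = 10000, theta = 10,
                              rho = 0, growth_rate = 0) {
  stop_if(!is_count(n_samples, 2), "n_samples must be an integer >= 2")
  stop_if(!is_count(locus_length, 1), "locus_length must be >= 1")
  stop_if(!is.numeric(theta) || theta < 0, "theta must be >= 0")
  stop_if(!is.numeric(rho) || rho < 0, "rho must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 locus_length = as.integer(locus_length),
                 theta = theta, rho = rho, growth_rate = growth_rate),
            class = "coalescent_params")
}

#' Two-population split model parameters
#'
#' A clean isolation model: one ancestral population splits into two
#' descendant populations at `split_time` (units of 4N generations, looking
#' back from the present). Varying `split_time` moves simulated gene trees
#' through the polyphyly -> paraphyly -> reciprocal monophyly gradient of
#' lineage sorting.
#'
#' @param n_per_pop chromosomes sampled per descendant population (length-2
#'   vector, or scalar used for both).
#' @param split_time population split time in units of 4N generations.
#' @param size_ratios relative sizes of the two descendant populations
#'   (descendant N / reference N).
#' @param anc_size_ratio relative size of the ancestral population.
#' @param pop_names names of the two descendant populations.
#' @return An object of class `split_model_params`.
#' @export
split_model_params <- function(n_per_pop, split_time, size_ratios = c(1, 1),
                               anc_size_ratio = 1,
                               pop_names = c("pop1", "pop2")) {
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, 2)
  stop_if(any(n_per_pop < 1), "both populations must be sampled")
  stop_if(!is.numeric(split_time) || split_time < 0, "split_time must be >= 0")
  stop_if(any(size_ratios <= 0) || anc_size_ratio <= 0, "size ratios must be > 0")
  structure(list(n_per_pop = as.integer(n_per_pop), split_time = split_time,
                 size_ratios = size_ratios, anc_size_ratio = anc_size_ratio,
                 pop_names = pop_names),
            class = "split_model_params")
}

## ---- genealogy simulation without recombination ----------------------------
##
## Active lineages carry their descendant tip set, birth time and a growing
## newick fragment; every coalescence closes two branches. Mutation placement
## uses the recorded (tip set, branch length) pairs. Coalescence rate for k
## lineages in a population of relative size s is k*(k-1)/s (pairwise rate 2
## at s = 1, i.e. E[T2] = 0.5 in units of 4N generations).

sim_genealogy <- function(n, growth = 0, tip_labels = paste0("hap", seq_len(n))) {
  act <- lapply(seq_len(n), function(i)
    list(tips = i, birth = 0, nwk = tip_labels[i]))
  branches_tips <- vector("list", 2 * n - 2)
  branches_len <- numeric(2 * n - 2)
  nb <- 0L
  t <- 0
  k <- n
  while (k > 1) {
    rate0 <- k * (k - 1)
    if (growth == 0) {
      dt <- stats::rexp(1, rate0)
    } else {
      e <- stats::rexp(1)
      dt <- log1p(growth * e / (rate0 * exp(growth * t))) / growth
    }
    t <- t + dt
    pair <- sample.int(k, 2)
    a <- act[[pair[1]]]; b <- act[[pair[2]]]
    for (x in list(a, b)) {
      nb <- nb + 1L
      branches_tips[[nb]] <- x$tips
      branches_len[nb] <- t - x$birth
    }
    merged <- list(tips = c(a$tips, b$tips), birth = t,
                   nwk = sprintf("(%s:%.8f,%s:%.8f)", a$nwk, t - a$birth,
                                 b$nwk, t - b$birth))
    act[[pair[1]]] <- merged
    act <- act[-pair[2]]
    k <- k - 1L
  }
  list(branch_tips = branches_tips[seq_len(nb)],
       branch_len = branches_len[seq_len(nb)],
       newick = paste0(act[[1]]$nwk, ";"), tmrca = t)
}

## Structured (two-population) version: within-population coalescence only
## until split_time, then all lineages join the ancestral population.
sim_genealogy_split <- function(params, tip_labels) {
  n1 <- params$n_per_pop[1]; n2 <- params$n_per_pop[2]
  n <- n1 + n2
  pop_of <- c(rep(1L, n1), rep(2L, n2))
  act <- lapply(seq_len(n), function(i)
    list(tips = i, birth = 0, nwk = tip_labels[i], pop = pop_of[i]))
  branches_tips <- list(); branches_len <- numeric(0)
  t <- 0
  sizes <- params$size_ratios
  merged_pops <- FALSE
  repeat {
    k <- length(act)
    if (k == 1) break
    if (!merged_pops) {
      kp <- tabulate(vapply(act, `[[`, 0L, "pop"), 2)
      rates <- kp * (kp - 1) / sizes
      total <- sum(rates)
      dt <- if (total > 0) stats::rexp(1, total) else Inf
      if (t + dt >= params$split_time) {
        t <- params$split_time
        act <- lapply(act, function(x) { x$pop <- 0L; x })
        merged_pops <- TRUE
        next
      }
      t <- t + dt
      pop <- sample.int(2, 1, prob = rates / total)
      idx <- which(vapply(act, `[[`, 0L, "pop") == pop)
    } else {
      total <- k * (k - 1) / params$anc_size_ratio
      t <- t + stats::rexp(1, total)
      idx <- seq_len(k)
    }
    pair <- sample(idx, 2)
    a <- act[[pair[1]]]; b <- act[[pair[2]]]
    for (x in list(a, b)) {
      branches_tips <- c(branches_tips, list(x$tips))
      branches_len <- c(branches_len, t - x$birth)
    }
    act[[pair[1]]] <- list(tips = c(a$tips, b$tips), birth = t,
                           nwk = sprintf("(%s:%.8f,%s:%.8f)", a$nwk,
                                         t - a$birth, b$nwk, t - b$birth),
                           pop = a$pop)
    act <- act[-pair[2]]
  }
  list(branch_tips = branches_tips, branch_len = branches_len,
       newick = paste0(act[[1]]$nwk, ";"), tmrca = t)
}

## ---- ancestral recombination graph (rho > 0) -------------------------------
##
## Hudson-style back-in-time simulation. Each lineage holds a list of
## segments of ancestral material on [0, 1]; a segment knows which sampled
## chromosomes it is ancestral to (logical mask). Recombination splits a
## lineage at a uniform breakpoint within its span; coalescence merges two
## lineages, taking set unions on overlaps and retiring segments whose set
## reaches the full sample (marginal MRCA). Mutations accrue between events
## at rate theta * (total ancestral length) and hit a segment proportional
## to its length; carriers are that segment's set.

sim_arg_mutations <- function(n, theta, rho, growth = 0) {
  lineages <- lapply(seq_len(n), function(i) {
    set <- rep(FALSE, n); set[i] <- TRUE
    list(segs = list(list(l = 0, r = 1, set = set)))
  })
  mut_pos <- numeric(0)
  mut_carriers <- list()
  t <- 0
  repeat {
    k <- length(lineages)
    if (k == 0) break
    seg_lens <- lapply(lineages, function(ln)
      vapply(ln$segs, function(s) s$r - s$l, 0))
    amat <- vapply(seg_lens, sum, 0)
    A <- sum(amat)
    if (A <= 0) break
    spans <- vapply(lineages, function(ln) {
      ls <- vapply(ln$segs, `[[`, 0, "l"); rs <- vapply(ln$segs, `[[`, 0, "r")
      max(rs) - min(ls)
    }, 0)
    r_rec <- rho * sum(spans)
    t_rec <- if (r_rec > 0) stats::rexp(1, r_rec) else Inf
    if (k >= 2) {
      rate0 <- k * (k - 1)
      if (growth == 0) t_coal <- stats::rexp(1, rate0)
      else {
        e <- stats::rexp(1)
        t_coal <- log1p(growth * e / (rate0 * exp(growth * t))) / growth
      }
    } else t_coal <- Inf
    dt <- min(t_rec, t_coal)
    if (!is.finite(dt)) stop("coalescent simulation stalled", call. = FALSE)
    ## mutations during the waiting interval
    if (theta > 0) {
      nm <- stats::rpois(1, theta * A * dt)
      if (nm > 0) {
        flat_len <- unlist(seg_lens)
        pick <- sample.int(length(flat_len), nm, replace = TRUE,
                           prob = flat_len)
        flat_segs <- unlist(lapply(lineages, `[[`, "segs"), recursive = FALSE)
        for (j in pick) {
          s <- flat_segs[[j]]
          mut_pos <- c(mut_pos, stats::runif(1, s$l, s$r))
          mut_carriers <- c(mut_carriers, list(s$set))
        }
      }
    }
    t <- t + dt
    if (t_rec < t_coal) {
      i <- sample.int(k, 1, prob = spans)
      segs <- lineages[[i]]$segs
      ls <- vapply(segs, `[[`, 0, "l"); rs <- vapply(segs, `[[`, 0, "r")
      u <- stats::runif(1, min(ls), max(rs))
      left <- list(); right <- list()
      for (s in segs) {
        if (s$r <= u) left <- c(left, list(s))
        else if (s$l >= u) right <- c(right, list(s))
        else {
          left <- c(left, list(list(l = s$l, r = u, set = s$set)))
          right <- c(right, list(list(l = u, r = s$r, set = s$set)))
        }
      }
      if (length(left) && length(right)) {
        lineages[[i]] <- list(segs = left)
        lineages[[length(lineages) + 1L]] <- list(segs = right)
      } ## breakpoint outside ancestral material on one side: no-op
    } else {
      pair <- sample.int(k, 2)
      sa <- lineages[[pair[1]]]$segs; sb <- lineages[[pair[2]]]$segs
      bps <- sort(unique(c(vapply(sa, `[[`, 0, "l"), vapply(sa, `[[`, 0, "r"),
                           vapply(sb, `[[`, 0, "l"), vapply(sb, `[[`, 0, "r"))))
      segs <- list()
      cover <- function(segset, mid)
        Find(function(s) s$l < mid && mid < s$r, segset)
      for (j in seq_len(length(bps) - 1L)) {
        a <- bps[j]; b <- bps[j + 1L]
        if (b - a <= 0) next
        mid <- (a + b) / 2
        ca <- cover(sa, mid); cb <- cover(sb, mid)
        if (is.null(ca) && is.null(cb)) next
        set <- if (is.null(ca)) cb$set else if (is.null(cb)) ca$set
               else ca$set | cb$set
        if (sum(set) < n) segs <- c(segs, list(list(l = a, r = b, set = set)))
      }
      lineages[[pair[1]]] <- list(segs = segs)
      lineages <- lineages[-pair[2]]
      lineages <- Filter(function(ln) length(ln$segs) > 0, lineages)
    }
  }
  list(pos = mut_pos, carriers = mut_carriers)
}

## Map continuous mutation positions to distinct discrete sites
## (infinite-sites model with collision re-draw) and build the alignment.
mutations_to_alignment <- function(pos, carriers, n, L, labels, pop_map,
                                   sequences = FALSE) {
  S <- length(pos)
  stop_if(S >= L, "locus saturated: more mutations than sites")
  sites <- integer(S)
  used <- integer(0)
  for (j in seq_len(S)) {
    s <- floor(pos[j] * L) + 1L
    while (s %in% used) s <- sample.int(L, 1)
    sites[j] <- s
    used <- c(used, s)
  }
  ord <- order(sites)
  sites <- sites[ord]; carriers <- carriers[ord]
  anc <- sample(DNA_BASES, S, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1), "")
  out_label <- "ancestor"
  alle <- matrix(rep(anc, each = n + 1L), nrow = n + 1L,
                 dimnames = list(c(labels, out_label), NULL))
  for (j in seq_len(S)) {
    idx <- if (is.logical(carriers[[j]])) which(carriers[[j]]) else carriers[[j]]
    alle[idx, j] <- der[j]
  }
  seqs <- NULL
  if (sequences) {
    ref <- sample(DNA_BASES, L, replace = TRUE)
    if (S > 0) ref[sites] <- anc
    seqs <- vapply(seq_len(n + 1L), function(i) {
      s <- ref
      if (S > 0) s[sites] <- alle[i, ]
      paste(s, collapse = "")
    }, "")
    names(seqs) <- c(labels, out_label)
  }
  haplo_alignment(alle, sites, L, pop_map, outgroup_label = out_label,
                  sequences = seqs)
}

#' Simulate one locus under the neutral coalescent
#'
#' Hudson-style coalescent with optional recombination (ancestral
#' recombination graph) and optional exponential growth. Mutations follow the
#' infinite-sites model, mapped to discrete positions with collision re-draw;
#' the known ancestral state is returned as an all-ancestral outgroup row
#' labelled `"ancestor"`.
#'
#' @param params a [coalescent_params] object.
#' @param seed integer RNG seed; `NULL` uses the current stream.
#' @param sequences materialize full-length sequences (needed for FASTA
#'   export)? Off by default so that large simulation studies stay cheap.
#' @param pop name of the (single) population in the returned alignment.
#' @return A [haplo_alignment] with `attr(, "tmrca")` set when `rho = 0`, and
#'   `attr(, "genealogy")` holding the newick genealogy when `rho = 0`.
#' @export
#' @examples
#' aln <- simulate_locus(coalescent_params(10, 1000, theta = 5), seed = 1)
#' n_segregating(aln)
simulate_locus <- function(params, seed = NULL, sequences = FALSE,
                           pop = "pop1") {
  stopifnot(inherits(params, "coalescent_params"))
  with_seed(seed, {
    n <- params$n_samples
    labels <- paste0("hap", seq_len(n))
    pop_map <- structure(rep(pop, n), names = labels)
    if (params$rho == 0) {
      g <- sim_genealogy(n, params$growth_rate, labels)
      nmut <- stats::rpois(length(g$branch_len), params$theta * g$branch_len)
      carriers <- rep(g$branch_tips, nmut)
      pos <- stats::runif(sum(nmut))
      aln <- mutations_to_alignment(pos, carriers, n, params$locus_length,
                                    labels, pop_map, sequences)
      attr(aln, "genealogy") <- g$newick
      attr(aln, "tmrca") <- g$tmrca
    } else {
      mut <- sim_arg_mutations(n, params$theta, params$rho,
                               params$growth_rate)
      aln <- mutations_to_alignment(mut$pos, mut$carriers, n,
                                    params$locus_length, labels, pop_map,
                                    sequences)
    }
    attr(aln, "params") <- params
    aln
  })
}

#' Simulate a locus under a two-population split model
#'
#' Structured coalescent without recombination: within-population
#' coalescence until `split_time`, then panmixia in the ancestral
#' population. The realized gene tree is recorded so the lineage-sorting
#' state (polyphyly / paraphyly / reciprocal monophyly) is known truth.
#'
#' @param params a [split_model_params] object.
#' @param theta per-locus population mutation rate.
#' @param seed integer RNG seed.
#' @param locus_length locus length in bp.
#' @param sequences materialize full sequences?
#' @return A [haplo_alignment]; `attr(, "genealogy")` holds the realized gene
#'   tree as an [ape::phylo] object.
#' @export
simulate_split <- function(params, theta, seed = NULL, locus_length = 10000,
                           sequences = FALSE) {
  stopifnot(inherits(params, "split_model_params"))
  with_seed(seed, {
    n1 <- params$n_per_pop[1]; n2 <- params$n_per_pop[2]
    n <- n1 + n2
    labels <- c(paste0(params$pop_names[1], "_", seq_len(n1)),
                paste0(params$pop_names[2], "_", seq_len(n2)))
    pop_map <- structure(rep(params$pop_names, c(n1, n2)), names = labels)
    g <- sim_genealogy_split(params, labels)
    nmut <- stats::rpois(length(g$branch_len), theta * g$branch_len)
    carriers <- rep(g$branch_tips, nmut)
    pos <- stats::runif(sum(nmut))
    aln <- mutations_to_alignment(pos, carriers, n, locus_length, labels,
                                  pop_map, sequences)
    ## the all-ancestral outgroup row joins the gene tree at the root
    nwk <- sprintf("(%s:0.0,ancestor:%.8f);",
                   sub(";$", "", g$newick), g$tmrca)
    attr(aln, "genealogy") <- ape::read.tree(text = nwk)
    attr(aln, "tmrca") <- g$tmrca
    attr(aln, "params") <- params
    aln
  })
}

#' Moment-match null-model hyperparameters from per-locus rate estimates
#'
#' Locus-to-locus variation in the mutation rate is modelled as a Gamma
#' distribution and in the recombination rate as a log-normal, each
#' moment-matched (on the natural scale) to the supplied per-locus
#' estimates. Zero-variance inputs degenerate to point masses with a
#' warning.
#'
#' @param theta_rates per-locus mutation-rate (or theta) estimates.
#' @param rho_rates per-locus recombination-rate (or rho) estimates.
#' @return A list of class `null_hyperparams` with components `theta`
#'   (`shape`, `scale`, `mean`) and `rho` (`meanlog`, `sdlog`, `mean`).
#' @export
sample_null_hyperparams <- function(theta_rates, rho_rates = NULL) {
  stop_if(length(theta_rates) < 2, "need at least 2 loci")
  stop_if(any(theta_rates < 0), "rates must be non-negative")
  m <- mean(theta_rates); v <- stats::var(theta_rates)
  if (v == 0) {
    warning("zero variance in mutation-rate estimates: theta is a point mass")
    theta <- list(shape = Inf, scale = 0, mean = m)
  } else {
    theta <- list(shape = m^2 / v, scale = v / m, mean = m)
  }
  rho <- NULL
  if (!is.null(rho_rates)) {
    stop_if(length(rho_rates) < 2, "need at least 2 loci for rho")
    stop_if(any(rho_rates <= 0), "recombination rates must be positive")
    mr <- mean(rho_rates); vr <- stats::var(rho_rates)
    if (vr == 0) {
      warning("zero variance in recombination-rate estimates: rho is a point mass")
      rho <- list(meanlog = log(mr), sdlog = 0, mean = mr)
    } else {
      s2 <- log1p(vr / mr^2)
      rho <- list(meanlog = log(mr) - s2 / 2, sdlog = sqrt(s2), mean = mr)
    }
  }
  structure(list(theta = theta, rho = rho), class = "null_hyperparams")
}

## Draw per-locus rates from moment-matched hyperparameters.
draw_gamma <- function(n, par) {
  if (!is.finite(par$shape)) rep(par$mean, n)
  else stats::rgamma(n, shape = par$shape, scale = par$scale)
}

draw_lognormal <- function(n, par) {
  if (par$sdlog == 0) rep(par$mean, n)
  else stats::rlnorm(n, par$meanlog, par$sdlog)
}
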