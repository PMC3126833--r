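#' Build or read a pipeline run configuration
#'
#' Central place for all stage parameters and their defaults: simulation
#' layout (two-population split model), SNP-calling thresholds (depth 8,
#' minor-allele fraction 0.15, NQS 20/15), diversity-table rate constants,
#' neutrality-test replication, and monophyly thresholds (95%/5% support,
#' 10% burn-in). Accepts a YAML file or a named list; anything not supplied
#' keeps its default.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    stop_if(!file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    stages = c("simulate", "callsnps", "stats", "neutrality", "monophyly"),
    seed = 1L,
    out_dir = "pansort_run",
    simulate = list(n_loci = 15, n_per_pop = c(10, 10), split_time = 1.0,
                    locus_length = 10000, theta = 10,
                    pop_names = c("popA", "popB")),
    callsnps = list(min_depth = 8, maf = 0.15, nqs = c(20, 15),
                    mean_coverage = 20),
    stats = list(divergence = 0.0135, t_div = 6e6, generation = 20),
    neutrality = list(reps = 200, rho_mean = 0, population = NULL),
    monophyly = list(burnin = 0.10, support = c(0.95, 0.05))
  )
  known <- names(defaults)
  unknown <- setdiff(names(config), known)
  stop_if(length(unknown) > 0,
          "unknown config entries: ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      stop_if(length(bad) > 0, "unknown ", nm, " option(s): ",
              paste(bad, collapse = ", "))
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else defaults[[nm]] <- config[[nm]]
  }
  valid_stages <- c("simulate", "callsnps", "stats", "neutrality", "monophyly")
  bad <- setdiff(defaults$stages, valid_stages)
  stop_if(length(bad) > 0, "unknown stage(s): ", paste(bad, collapse = ", "))
  structure(defaults, class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order on synthetic data:
#' simulate two-population loci (split model, gene trees recorded), write
#' FASTA + population map, simulate and call a 454-style read set for one
#' diploid individual per population, produce the pooled diversity table,
#' Fst matrix and allele-sharing classification, run the composite
#' neutrality test per population, and compute monophyly probabilities and
#' the majority consensus over the recorded gene trees. A manifest (seed,
#' parameters, output checksums) is written alongside the outputs; the same
#' config and seed reproduce identical outputs and manifest.
#'
#' @param config a [run_config], list of overrides, or YAML path.
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  seed <- config$seed
  stages <- config$stages

  ## simulate -----------------------------------------------------------
  sim <- config$simulate
  loci <- lapply(seq_len(sim$n_loci), function(i)
    simulate_split(split_model_params(sim$n_per_pop, sim$split_time,
                                      pop_names = sim$pop_names),
                   theta = sim$theta, seed = derive_seed(seed, i),
                   locus_length = sim$locus_length, sequences = TRUE))
  if ("simulate" %in% stages) {
    for (i in seq_along(loci))
      write_fasta(loci[[i]],
                  file.path(config$out_dir, sprintf("locus_%02d.fasta", i)))
    pm <- loci[[1]]$pop_map
    utils::write.table(data.frame(sample = names(pm), population = pm),
                       file.path(config$out_dir, "popmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$loci <- loci
  }

  ## callsnps ------------------------------------------------------------
  if ("callsnps" %in% stages) {
    cs <- config$callsnps
    params <- call_params(min_depth = cs$min_depth, maf = cs$maf,
                          nqs = cs$nqs)
    rc <- read_sim_config(mean_coverage = cs$mean_coverage)
    reports <- lapply(seq_along(sim$pop_names), function(k) {
      labs <- names(loci[[1]]$pop_map)[loci[[1]]$pop_map == sim$pop_names[k]]
      haps <- loci[[1]]$sequences[labs[1:2]]
      pl <- simulate_reads(unname(haps), rc,
                           seed = derive_seed(seed, 1000 + k))
      rep <- call_region(pl, params)
      write_calls(rep, file.path(config$out_dir,
                                 sprintf("calls_%s.tsv", sim$pop_names[k])),
                  consensus = pl$consensus, chrom = sim$pop_names[k])
      rep
    })
    names(reports) <- sim$pop_names
    out$call_reports <- reports
  }

  ## stats ---------------------------------------------------------------
  if ("stats" %in% stages) {
    st <- config$stats
    rates <- evolutionary_rates(st$divergence, st$t_div, st$generation)
    tab <- diversity_table(loci, rates = rates)
    utils::write.table(tab, file.path(config$out_dir, "diversity_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fm <- fst_matrix(loci)
    utils::write.table(round(fm, 4),
                       file.path(config$out_dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    cls <- classify_shared_sites(loci, sim$pop_names[1], sim$pop_names[2])
    utils::write.table(data.frame(category = names(cls),
                                  count = as.integer(cls)),
                       file.path(config$out_dir, "site_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$diversity <- tab; out$fst <- fm; out$site_classes <- cls
  }

  ## neutrality ----------------------------------------------------------
  if ("neutrality" %in% stages) {
    ne <- config$neutrality
    pops <- ne$population %||% sim$pop_names
    fits <- lapply(pops, function(p) {
      per_theta <- vapply(loci, function(a)
        n_segregating(a, p) / harmonic_a(length(ingroup_labels(a, p))), 0)
      per_theta[per_theta <= 0] <- min(per_theta[per_theta > 0]) / 2
      hyper <- sample_null_hyperparams(per_theta)
      cfg <- null_model_config(
        loci = data.frame(n = length(ingroup_labels(loci[[1]], p)),
                          length = sim$locus_length)[rep(1, sim$n_loci), ],
        reps = ne$reps, theta_gamma = hyper$theta,
        rho_lognormal = if (ne$rho_mean > 0)
          list(meanlog = log(ne$rho_mean), sdlog = 0.5) else NULL,
        seed = derive_seed(seed, 2000 + match(p, pops)))
      composite_fit(loci, simulate_null(cfg), pop = p)
    })
    names(fits) <- pops
    res <- data.frame(population = pops,
                      C = vapply(fits, `[[`, 0, "C"),
                      fit_pvalue = vapply(fits, `[[`, 0, "fit_pvalue"))
    utils::write.table(res, file.path(config$out_dir, "neutrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$neutrality <- fits
  }

  ## monophyly -----------------------------------------------------------
  if ("monophyly" %in% stages) {
    mo <- config$monophyly
    trees <- lapply(loci, attr, "genealogy")
    pm <- loci[[1]]$pop_map
    ts <- tree_sample(trees, pm, outgroup_label = "ancestor")
    rows <- lapply(seq_along(loci), function(i) {
      one <- tree_sample(trees[i], pm, "ancestor")
      data.frame(
        locus = i,
        reciprocal = reciprocal_monophyly(one, sim$pop_names[1],
                                          sim$pop_names[2], burnin = 0,
                                          support = mo$support)$posterior_probability,
        mono_a = posterior_monophyly(one, sim$pop_names[1], burnin = 0,
                                     support = mo$support)$posterior_probability,
        mono_b = posterior_monophyly(one, sim$pop_names[2], burnin = 0,
                                     support = mo$support)$posterior_probability)
    })
    tab2 <- do.call(rbind, rows)
    names(tab2)[3:4] <- paste0("mono_", sim$pop_names)
    utils::write.table(tab2, file.path(config$out_dir, "monophyly.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cons <- majority_consensus(ts, burnin = 0)
    ape::write.tree(cons, file.path(config$out_dir, "consensus.nwk"))
    out$monophyly <- tab2; out$consensus <- cons
  }

  ## manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.json")))
  manifest <- list(
    package = "pansort",
    version = as.character(utils::packageVersion("pansort")),
    seed = seed, stages = stages,
    parameters = unclass(config)[setdiff(names(config), "stages")],
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
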