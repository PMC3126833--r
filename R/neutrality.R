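#' Null-model configuration for the composite neutrality test
#'
#' Describes the simulated null: the per-locus sample sizes and lengths of
#' the observed data, the Gamma distribution of locus-wise theta, the
#' log-normal distribution of locus-wise rho, and the number of simulated
#' multilocus datasets.
#'
#' @param loci `data.frame` with columns `n` (chromosomes) and `length`
#'   (bp), one row per locus.
#' @param reps number of simulated multilocus datasets.
#' @param theta_gamma list or vector with `shape` and `scale` of the Gamma
#'   distribution of per-locus theta (use `shape = Inf` with a `mean` for a
#'   point mass).
#' @param rho_lognormal list or vector with `meanlog` and `sdlog` of the
#'   log-normal distribution of per-locus rho; `NULL` disables
#'   recombination.
#' @param growth_rate exponential growth parameter of the simulated model
#'   (0 = the standard constant-size null).
#' @param seed RNG seed.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(loci, reps = 1000, theta_gamma,
                              rho_lognormal = NULL, growth_rate = 0,
                              seed = NULL) {
  stop_if(!is.data.frame(loci) || nrow(loci) == 0,
          "loci must be a non-empty data.frame with n and length")
  stop_if(!all(c("n", "length") %in% names(loci)), "loci needs n and length")
  stop_if(!is_count(reps, 1), "reps must be >= 1")
  tg <- as.list(theta_gamma)
  stop_if(is.null(tg$shape) || is.null(tg$scale),
          "theta_gamma needs shape and scale")
  if (is.null(tg$mean)) tg$mean <- tg$shape * tg$scale
  rl <- if (!is.null(rho_lognormal)) {
    x <- as.list(rho_lognormal)
    stop_if(is.null(x$meanlog) || is.null(x$sdlog),
            "rho_lognormal needs meanlog and sdlog")
    if (is.null(x$mean)) x$mean <- exp(x$meanlog + x$sdlog^2 / 2)
    x
  } else NULL
  structure(list(loci = loci, reps = as.integer(reps), theta_gamma = tg,
                 rho_lognormal = rl, growth_rate = growth_rate, seed = seed),
            class = "null_model_config")
}

#' Multilocus summary-statistic vector
#'
#' The five summaries the composite test compares: the variance across loci
#' of Tajima's D and the across-locus means of S, the mean pairwise
#' difference per locus, Fu & Li's D* and Tajima's D. Loci without
#' segregating sites contribute 0 to the S and pi means but are excluded
#' from the D-statistic means and variance (their count is recorded).
#'
#' @param loci list of [haplo_alignment] objects (one per locus).
#' @param pop optional population restriction.
#' @return A named numeric vector of class `summary_vector` with components
#'   `var_tajima_d`, `mean_S`, `mean_pi`, `mean_fu_li_dstar`,
#'   `mean_tajima_d`, and attribute `n_monomorphic`.
#' @export
summary_vector <- function(loci, pop = NULL) {
  per <- lapply(loci, locus_summary, pop = pop)
  df <- do.call(rbind, per)
  pit <- vapply(seq_along(loci), function(i)
    nucleotide_diversity(loci[[i]], pop, per_site = FALSE), 0)
  d <- df$tajima_d[!is.na(df$tajima_d)]
  ds <- df$fu_li_dstar[!is.na(df$fu_li_dstar)]
  v <- c(var_tajima_d = if (length(d) >= 2) stats::var(d) else NA_real_,
         mean_S = mean(df$S),
         mean_pi = mean(pit),
         mean_fu_li_dstar = if (length(ds)) mean(ds) else NA_real_,
         mean_tajima_d = if (length(d)) mean(d) else NA_real_)
  structure(v, n_monomorphic = sum(df$S == 0), class = "summary_vector")
}

#' Simulate summary statistics under the null model
#'
#' For each replicate dataset, a fresh theta (Gamma) and rho (log-normal)
#' are drawn independently for every locus, the loci are simulated under
#' the (optionally growing) neutral coalescent, and the five-component
#' summary vector is computed.
#'
#' @param config a [null_model_config].
#' @param progress print a dot every 50 replicates?
#' @return A matrix (`reps` x 5) of class `null_sims`, columns named as in
#'   [summary_vector].
#' @export
simulate_null <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "null_model_config"))
  with_seed(config$seed, {
    nl <- nrow(config$loci)
    out <- matrix(NA_real_, config$reps, 5,
                  dimnames = list(NULL, c("var_tajima_d", "mean_S", "mean_pi",
                                          "mean_fu_li_dstar", "mean_tajima_d")))
    for (r in seq_len(config$reps)) {
      thetas <- draw_gamma(nl, config$theta_gamma)
      rhos <- if (is.null(config$rho_lognormal)) rep(0, nl)
              else draw_lognormal(nl, config$rho_lognormal)
      loci <- lapply(seq_len(nl), function(i)
        simulate_locus(coalescent_params(config$loci$n[i],
                                         config$loci$length[i],
                                         theta = thetas[i], rho = rhos[i],
                                         growth_rate = config$growth_rate)))
      out[r, ] <- unclass(summary_vector(loci))
      if (progress && r %% 50 == 0) cat(".")
    }
    if (progress) cat("\n")
    structure(out, class = c("null_sims", "matrix"))
  })
}

#' Two-sided empirical p-value
#'
#' `p = 2 * min(P(X <= obs), P(X >= obs))` against the simulated draws,
#' with add-one smoothing `(1 + count) / (1 + reps)` so that p is never 0,
#' capped at 1. One-sided tails are available for sensitivity analyses.
#'
#' @param observed observed scalar.
#' @param null_draws vector of simulated draws.
#' @param tail `"two.sided"` (default), `"lower"` or `"upper"`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_draws,
                             tail = c("two.sided", "lower", "upper")) {
  tail <- match.arg(tail)
  null_draws <- null_draws[!is.na(null_draws)]
  stop_if(length(null_draws) == 0, "need at least one null draw")
  r <- length(null_draws)
  p_le <- (1 + sum(null_draws <= observed)) / (1 + r)
  p_ge <- (1 + sum(null_draws >= observed)) / (1 + r)
  switch(tail,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         lower = min(1, p_le),
         upper = min(1, p_ge))
}

#' Composite goodness-of-fit test of the standard neutral model
#'
#' Computes the five-statistic summary vector of the observed data, the
#' two-sided empirical p-value of each statistic against the simulated
#' null, and the composite statistic `C = sum(log(p))`. The fit p-value is
#' the proportion of simulated datasets whose own composite statistic
#' (computed leave-one-out against the remaining simulations) is at least
#' as extreme (`C_k <= C_obs`), with add-one smoothing.
#'
#' @param observed a [summary_vector], or a list of [haplo_alignment] loci
#'   (with `pop` to select the population).
#' @param sims a `null_sims` matrix from [simulate_null], or a
#'   [null_model_config] to simulate now.
#' @param pop population restriction when `observed` is a list of loci.
#' @param tail tail convention passed to [empirical_pvalue].
#' @return An object of class `neutrality_fit`: list with `observed`,
#'   `pvalues` (five named p-values), `C`, `fit_pvalue`, `reps`.
#' @export
composite_fit <- function(observed, sims, pop = NULL,
                          tail = "two.sided") {
  if (!inherits(observed, "summary_vector"))
    observed <- summary_vector(observed, pop)
  if (inherits(sims, "null_model_config")) sims <- simulate_null(sims)
  sims <- unclass(sims)
  reps <- nrow(sims)
  if (reps < 100)
    warning("fewer than 100 simulated datasets: p-values will be unstable")
  stats_names <- colnames(sims)
  usable <- !is.na(unclass(observed)[stats_names]) &
    colSums(is.na(sims)) < reps
  pvals <- vapply(stats_names[usable], function(s)
    empirical_pvalue(observed[[s]], sims[, s], tail), 0)
  C_obs <- sum(log(pvals))
  ## leave-one-out composite statistic for every simulated dataset
  logp_k <- matrix(0, reps, sum(usable))
  for (j in seq_along(stats_names[usable])) {
    x <- sims[, stats_names[usable][j]]
    ok <- !is.na(x)
    r <- sum(ok) - 1L
    cnt_le <- colSums(outer(x[ok], x[ok], "<=")) - 1L
    cnt_ge <- colSums(outer(x[ok], x[ok], ">=")) - 1L
    p_k <- pmin(1, 2 * pmin((1 + cnt_le) / (1 + r), (1 + cnt_ge) / (1 + r)))
    col <- rep(NA_real_, reps)
    col[ok] <- log(p_k)
    logp_k[, j] <- col
  }
  C_k <- rowSums(logp_k)
  C_k <- C_k[!is.na(C_k)]
  fit_p <- (1 + sum(C_k <= C_obs)) / (1 + length(C_k))
  structure(list(observed = observed, pvalues = pvals, C = C_obs,
                 fit_pvalue = fit_p, reps = reps, tail = tail,
                 dropped = stats_names[!usable]),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Composite fit to the standard neutral model\n")
  cat(sprintf("  C = %.3f over %d statistics, %d simulated datasets\n",
              x$C, length(x$pvalues), x$reps))
  cat(sprintf("  fit p-value = %.4g\n", x$fit_pvalue))
  invisible(x)
}

#' @export
summary.neutrality_fit <- function(object, ...) {
  cat("Observed summary statistics:\n")
  print(round(unclass(object$observed), 4))
  cat("\nPer-statistic empirical p-values (", object$tail, "):\n", sep = "")
  print(round(object$pvalues, 4))
  if (length(object$dropped))
    cat("dropped (undefined):", paste(object$dropped, collapse = ", "), "\n")
  cat(sprintf("\nC = %.3f; fit p-value = %.4g (%d simulations)\n",
              object$C, object$fit_pvalue, object$reps))
  invisible(object)
}
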