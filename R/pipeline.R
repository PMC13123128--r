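#' Write retained draws and a run manifest to a directory
#'
#' One delimited file per chain (columns `iteration`, `alpha`,
#' `beta.<name>`, `u.<center>`, `sigma2_u`) plus `manifest.dcf` echoing the
#' configuration, seed, per-block acceptance rates and file checksums —
#' enough to re-run the fit bit-identically.
#'
#' @param fit a fitted [mwg_logit].
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in seq_along(fit$draws$chains)) {
    d <- fit$draws$chains[[ch]]
    m <- data.frame(iteration = seq_len(d$S), alpha = d$alpha,
                    check.names = FALSE)
    if (ncol(d$beta) > 0) {
      b <- as.data.frame(d$beta)
      names(b) <- paste0("beta.", colnames(d$beta))
      m <- cbind(m, b)
    }
    if (ncol(d$u) > 0) {
      uu <- as.data.frame(d$u)
      names(uu) <- paste0("u.", colnames(d$u))
      m <- cbind(m, uu)
    }
    m$sigma2_u <- d$sigma2_u
    f <- file.path(dir, sprintf("chain_%d.tsv", ch))
    utils::write.table(m, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  manifest <- c(
    package_version = as.character(utils::packageVersion("centerprofile")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = fit$seed,
    n_chains = fit$control$n_chains, n_iter = fit$control$n_iter,
    burn_in = fit$control$burn_in, thin = fit$control$thin,
    kernel = fit$control$kernel,
    retained_per_chain = fit$draws$chains[[1]]$S,
    accept_alpha = paste(sprintf("%.3f", vapply(fit$acceptance, `[[`,
                                                numeric(1), "alpha")),
                         collapse = ","),
    checksums = paste(sprintf("%s:%s", basename(files),
                              tools::md5sum(files)), collapse = " ")
  )
  write.dcf(t(as.matrix(manifest)), file.path(dir, "manifest.dcf"))
  invisible(manifest)
}

#' Read draws written by [write_draws()]
#'
#' @param dir directory containing `chain_*.tsv`.
#' @return An `"mwg_draws"`-like object usable by [pool_draws()],
#'   [convergence_table()] and [posterior_summary()].
#' @export
read_draws <- function(dir) {
  files <- sort(list.files(dir, pattern = "^chain_\\d+\\.tsv$",
                           full.names = TRUE))
  if (!length(files))
    stop(sprintf("no draw files found in %s; run the fit step first", dir),
         call. = FALSE)
  chains <- lapply(files, function(f) {
    m <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    bcols <- grep("^beta\\.", names(m), value = TRUE)
    ucols <- grep("^u\\.", names(m), value = TRUE)
    list(alpha = m$alpha,
         beta = structure(as.matrix(m[bcols]),
                          dimnames = list(NULL, sub("^beta\\.", "", bcols))),
         u = structure(as.matrix(m[ucols]),
                       dimnames = list(NULL, sub("^u\\.", "", ucols))),
         sigma2_u = m$sigma2_u, S = nrow(m))
  })
  first <- chains[[1]]
  structure(list(chains = chains, n_chains = length(chains),
                 coef_names = colnames(first$beta),
                 center_labels = colnames(first$u)),
            class = "mwg_draws")
}

#' Run the full profiling pipeline
#'
#' Simulate (or load) a cohort, fit the hierarchical model, and write every
#' downstream artifact — draw files, convergence diagnostics, posterior
#' summaries, center profiles, funnel-plot data, shrinkage table and the
#' posterior predictive AUC — into an output directory. Idempotent given
#' the seed.
#'
#' @param data a cohort data frame, or `NULL` to simulate one with
#'   `sim_args`.
#' @param out_dir output directory.
#' @param formula model formula (default: full case-mix model of the
#'   synthetic generator's covariates).
#' @param center center column name.
#' @param control an [mwg_control].
#' @param prior an [mwg_prior].
#' @param seed master seed for simulation and fitting.
#' @param sim_args list of arguments for [simulate_cohort()] when `data` is
#'   `NULL`.
#' @param eps,alpha_level,fdr_q profiling options.
#' @param profile_draws cap on posterior draws used for the predictive,
#'   profiling and shrinkage steps (an evenly thinned subset; keeps the
#'   draw-by-patient matrices at protocol scale within memory).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the fitted model, profiles, shrinkage
#'   table, diagnostics and output paths.
#' @export
run_pipeline <- function(data = NULL, out_dir,
                         formula = outcome ~ sex + age_group + indigenous +
                           lung_disease + diabetes + cvd + late_referral +
                           obesity + mmm + period,
                         center = "center",
                         control = mwg_control(), prior = mwg_prior(),
                         seed = 1, sim_args = list(),
                         eps = 1e-6, alpha_level = 0.05, fdr_q = 0.05,
                         profile_draws = 4000, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(data)) {
      sim <- do.call(simulate_cohort, c(sim_args, list(seed = seed)))
      data <- sim$data
      write_cohort(data, file.path(out_dir, "cohort.tsv"))
      say("simulated cohort: %d patients", nrow(data))
    }
    stage <- "fit"
    say("fitting: %d chains x %d iterations", control$n_chains, control$n_iter)
    fit <- mwg_logit(formula, data, center = center, prior = prior,
                     control = control, seed = seed)
    write_draws(fit, file.path(out_dir, "draws"))
    if (!is.null(fit$cohort$encoding))
      utils::write.table(fit$cohort$encoding,
                         file.path(out_dir, "encoding_map.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    stage <- "diagnose"
    diag <- convergence_table(fit)
    utils::write.table(cbind(parameter = rownames(diag), diag),
                       file.path(out_dir, "diagnostics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (any(diag$psrf > 1.1, na.rm = TRUE))
      warning("PSRF > 1.1 for some parameters; chains may not have converged",
              call. = FALSE)
    if (any(diag$ess < 200, na.rm = TRUE))
      warning("ESS < 200 for some parameters", call. = FALSE)
    smry <- summary(fit)
    utils::write.table(cbind(parameter = rownames(smry$fixed), smry$fixed),
                       file.path(out_dir, "fixed_effects.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    stage <- "profile"
    prof <- center_profiles(fit, eps = eps, alpha_level = alpha_level,
                            fdr_q = fdr_q, max_draws = profile_draws)
    utils::write.table(as.data.frame(prof),
                       file.path(out_dir, "center_profiles.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    fd <- funnel_plot_data(prof)
    utils::write.table(fd$curves, file.path(out_dir, "funnel_curves.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stage <- "shrinkage"
    shr <- shrinkage_table(fit, max_draws = profile_draws)
    utils::write.table(shr, file.path(out_dir, "shrinkage.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    stage <- "ppc"
    ppc <- posterior_predictive_auc(fit)
    utils::write.table(
      data.frame(quantity = c(names(ppc$auc_quantiles), "mean_prob_auc"),
                 auc = c(ppc$auc_quantiles, ppc$auc_mean_prob)),
      file.path(out_dir, "ppc_auc.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    say("pipeline complete: %s", out_dir)
    list(fit = fit, profiles = prof, shrinkage = shr, diagnostics = diag,
         ppc = ppc, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s' (partial outputs in %s): %s",
                 stage, out_dir, conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
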