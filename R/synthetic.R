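#' Generate a synthetic community
#'
#' Body masses are drawn i.i.d. log-uniform over `log10_mass_bounds`, the
#' simplest emulator of the order-of-magnitude mass ranges seen in empirical
#' webs (marine communities span roughly 10^-8 to 10^6 g). Labels are
#' `s001`, `s002`, ... in draw order; the community is then mass-sorted as
#' usual.
#'
#' @param S species count, >= 2.
#' @param log10_mass_bounds length-2 (lower, upper) of log10 body mass (g).
#' @param seed integer seed; equal seeds give identical communities.
#' @return An `adbm_community`.
#' @export
generate_community <- function(S, log10_mass_bounds = c(-6, 2), seed = 1) {
  S <- as.integer(S)
  if (S < 2) stop("S must be >= 2")
  b <- as.numeric(log10_mass_bounds)
  if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
    stop("log10_mass_bounds must be a finite (lower, upper) pair")
  }
  masses <- withr::with_seed(as.integer(seed), 10^stats::runif(S, b[1], b[2]))
  community(sprintf("s%03d", seq_len(S)), masses)
}

#' Generate a ground-truth web from known parameters
#'
#' Wraps [predict_web()]: because the ADBM is deterministic, a community plus
#' a known parameter point defines a gold-standard web for testing the
#' inference machinery end to end.
#'
#' @param community an `adbm_community`.
#' @param true_params an `adbm_params`.
#' @return A `predation_matrix`.
#' @export
generate_truth <- function(community, true_params) {
  predict_web(community, true_params)
}

#' Degrade a web by random link deletion
#'
#' Emulates under-sampling: each observed link is independently deleted with
#' probability `q`; absences are never touched, so the degraded web is
#' element-wise less than or equal to the original.
#'
#' @param web a `predation_matrix`.
#' @param q removal probability in \[0, 1\].
#' @param seed integer seed; equal seeds give identical degraded webs.
#' @return A `predation_matrix`.
#' @export
degrade_web <- function(web, q, seed = 1) {
  stopifnot(inherits(web, "predation_matrix"))
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  links <- web$links
  ones <- which(links == 1L)
  if (length(ones) && q > 0) {
    drop <- withr::with_seed(as.integer(seed),
                             stats::runif(length(ones)) < q)
    links[ones[drop]] <- 0L
  }
  predation_matrix(web$community, links)
}

#' The packaged default benchmark scenario
#'
#' Reads the scenario manifest shipped with the package (a YAML file under
#' `extdata/`), so every test and example starts from the same baseline:
#' S = 20 species, log10 masses uniform on (-6, 2), true parameters
#' log10 a = -3, ai = 0.5, aj = 0.5, b = 0.1, removal probability 0.2.
#'
#' @param path optional path to an alternative scenario manifest.
#' @return A list of class `synthetic_scenario` with elements `S`,
#'   `log10_mass_bounds`, `true_params` (an `adbm_params`), `removal_prob`,
#'   `seed`.
#' @export
default_scenario <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_scenario.yaml", package = "adbmweb",
                        mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  scenario(S = y$S, log10_mass_bounds = unlist(y$log10_mass_bounds),
           true_params = do.call(adbm_params, y$true_params),
           removal_prob = y$removal_prob, seed = y$seed)
}

#' Define a synthetic scenario
#'
#' @param S species count.
#' @param log10_mass_bounds length-2 log10 mass interval.
#' @param true_params an `adbm_params` used as ground truth.
#' @param removal_prob link-removal probability q in \[0, 1\].
#' @param seed base integer seed; community generation, degradation,
#'   threshold selection and the ABC run use fixed offsets from it.
#' @return A list of class `synthetic_scenario`.
#' @export
scenario <- function(S, log10_mass_bounds, true_params, removal_prob = 0,
                     seed = 1) {
  stopifnot(inherits(true_params, "adbm_params"))
  if (removal_prob < 0 || removal_prob > 1) stop("removal_prob must be in [0, 1]")
  structure(list(S = as.integer(S),
                 log10_mass_bounds = as.numeric(log10_mass_bounds),
                 true_params = true_params,
                 removal_prob = removal_prob,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Under-sampling recovery experiment
#'
#' Builds a ground-truth web from a scenario, deletes links at random with
#' the scenario's removal probability, fits the ABC posterior to the degraded
#' web (threshold chosen by [select_threshold()]), and reports how well the
#' posterior recovers the undegraded truth: TSS of each posterior-predictive
#' web against the truth, estimated versus true and degraded connectance, and
#' whether each parameter's credible interval covers the true value. Fully
#' reproducible from the scenario seed.
#'
#' @param scn a `synthetic_scenario`.
#' @param tol_grid ascending candidate thresholds for [select_threshold()].
#' @param n_accept posterior sample size.
#' @param n_ref reference-sample size for threshold selection.
#' @param prior a `prior_spec`.
#' @param level interval coverage for the posterior summary.
#' @param max_attempts proposal cap for the ABC run.
#' @return A list of class `recovery_report` with elements `scenario`,
#'   `tol`, `true_connectance`, `degraded_connectance`,
#'   `mean_predicted_connectance`, `tss_vs_truth` (vector over posterior
#'   samples), `mean_tss_vs_truth`, `summary` (posterior summary table),
#'   `coverage` (named logical over the four parameters), `posterior`.
#' @export
recovery_experiment <- function(scn, tol_grid = seq(0.2, 1, by = 0.1),
                                n_accept = 200, n_ref = 2000,
                                prior = prior_spec(), level = 0.95,
                                max_attempts = 5e5) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  com <- generate_community(scn$S, scn$log10_mass_bounds, seed = scn$seed)
  truth <- generate_truth(com, scn$true_params)
  observed <- degrade_web(truth, scn$removal_prob, seed = scn$seed + 1L)
  sel <- select_threshold(observed, com, prior, tol_grid,
                          n_ref = n_ref, seed = scn$seed + 2L)
  cfg <- abc_config(tol = sel$tol, n_accept = n_accept,
                    seed = scn$seed + 3L, max_attempts = max_attempts)
  post <- rejection_abc(observed, com, prior, cfg)
  pp <- posterior_predictive(post, com, keep_webs = TRUE)
  os_truth <- obs_stats(truth)
  tss_truth <- vapply(pp$webs, function(w) tss_fast(w$links, os_truth),
                      numeric(1))
  summ <- summarize_posterior(post, level = level)
  true_theta <- c(log10_a = log10(scn$true_params$a),
                  ai = scn$true_params$ai,
                  aj = scn$true_params$aj,
                  log10_b = log10(scn$true_params$b))
  coverage <- vapply(names(true_theta), function(nm) {
    row <- summ[summ$quantity == nm, ]
    row$lower <= true_theta[[nm]] && true_theta[[nm]] <= row$upper
  }, logical(1))
  structure(list(scenario = scn,
                 tol = sel$tol,
                 true_connectance = connectance(truth),
                 degraded_connectance = connectance(observed),
                 mean_predicted_connectance = mean(post$samples$connectance),
                 tss_vs_truth = tss_truth,
                 mean_tss_vs_truth = mean(tss_truth),
                 summary = summ,
                 coverage = coverage,
                 posterior = post),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("Recovery experiment (S = %d, q = %.2f, tol = %.2f):\n",
                     "  connectance: true %.4f, degraded %.4f, posterior mean %.4f\n",
                     "  mean TSS of posterior webs vs truth: %.4f\n",
                     "  parameter coverage: %s\n"),
              x$scenario$S, x$scenario$removal_prob, x$tol,
              x$true_connectance, x$degraded_connectance,
              x$mean_predicted_connectance, x$mean_tss_vs_truth,
              paste(names(x$coverage)[x$coverage], collapse = ", ")))
  invisible(x)
}
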