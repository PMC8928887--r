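#' Prior specification for the ABC fit
#'
#' Independent uniform priors on the four free ADBM parameters. `ai` and `aj`
#' are uniform on their natural scale; `a` and `b` are uniform on the log10
#' scale because plausible values span many orders of magnitude (the
#' prey/predator mass ratio in a community spanning 10^-8 to 10^6 g ranges
#' over 10^-14 to 10^14, hence the wide default for log10 b). The default
#' upper bound for log10 a is 10; the lower bound is web-specific and can be
#' proposed with [elicit_a_lower_bound()] (the default -12 suits communities
#' spanning about 14 orders of magnitude in mass).
#'
#' @param ai_bounds,aj_bounds numeric length-2 (lower, upper) for the attack
#'   rate exponents.
#' @param log10_a_bounds,log10_b_bounds numeric length-2 (lower, upper) on
#'   the log10 scale.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(ai_bounds = c(-1.5, 1.5),
                       aj_bounds = c(0, 3),
                       log10_a_bounds = c(-12, 10),
                       log10_b_bounds = c(-15, 15)) {
  p <- list(ai_bounds = as.numeric(ai_bounds),
            aj_bounds = as.numeric(aj_bounds),
            log10_a_bounds = as.numeric(log10_a_bounds),
            log10_b_bounds = as.numeric(log10_b_bounds))
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2 || !all(is.finite(p[[nm]])) || p[[nm]][1] > p[[nm]][2]) {
      stop(nm, " must be a finite (lower, upper) pair with lower <= upper")
    }
  }
  structure(p, class = "prior_spec")
}

#' ABC run configuration
#'
#' @param tol distance threshold in (0, 2]; draws at distance `>= tol` are
#'   never accepted.
#' @param n_accept number of acceptances to collect (the posterior sample
#'   size; 1000 gives stable posteriors, smaller values are useful for
#'   experiments).
#' @param seed integer seed; one seeded stream drives parameter draws and
#'   acceptance uniforms in a fixed interleaved order, so runs are bitwise
#'   reproducible.
#' @param max_attempts cap on proposals before the run aborts with the best
#'   distance seen (diagnoses a `tol` below the model's attainable distance).
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(tol, n_accept = 1000, seed = 1, max_attempts = 1e6) {
  if (!is.numeric(tol) || tol <= 0 || tol > 2) stop("tol must be in (0, 2]")
  n_accept <- as.integer(n_accept)
  if (n_accept < 1) stop("n_accept must be >= 1")
  if (max_attempts < n_accept) stop("max_attempts must be >= n_accept")
  structure(list(tol = tol, n_accept = n_accept, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "abc_config")
}

# Draw one parameter point from the prior on the sampling scale, in the fixed
# order (log10_a, ai, aj, log10_b). Consumes exactly 4 uniforms.
draw_theta <- function(prior) {
  u <- stats::runif(4)
  c(log10_a = prior$log10_a_bounds[1] + u[1] * diff(prior$log10_a_bounds),
    ai = prior$ai_bounds[1] + u[2] * diff(prior$ai_bounds),
    aj = prior$aj_bounds[1] + u[3] * diff(prior$aj_bounds),
    log10_b = prior$log10_b_bounds[1] + u[4] * diff(prior$log10_b_bounds))
}

#' Draw ADBM parameters from the prior
#'
#' `ai`, `aj` are uniform on their intervals; `a = 10^u`, `b = 10^v` with
#' `u`, `v` uniform on the log10 intervals. Draws come from R's current RNG
#' stream; seed it (e.g. `set.seed()` or `withr::with_seed()`) for
#' reproducibility.
#'
#' @param prior a `prior_spec`.
#' @return An `adbm_params` with the fixed constants attached.
#' @export
sample_prior <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  th <- draw_theta(prior)
  adbm_params(a = 10^th[["log10_a"]], ai = th[["ai"]], aj = th[["aj"]],
              b = 10^th[["log10_b"]])
}

#' Epanechnikov acceptance weight
#'
#' The acceptance probability of a draw at distance `d` under threshold
#' `tol`: the Epanechnikov kernel normalized to 1 at zero distance,
#' `K(d)/K(0) = 1 - (d/tol)^2` for `d <= tol` and 0 beyond. Acceptance is
#' certain at distance 0 and impossible at or beyond the threshold.
#'
#' @param d non-negative distance(s).
#' @param tol distance threshold, > 0.
#' @return Acceptance probability in \[0, 1\], vectorized over `d`.
#' @export
kernel_weight <- function(d, tol) {
  if (tol <= 0) stop("tol must be > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  ifelse(d <= tol, 1 - (d / tol)^2, 0)
}

make_sample_df <- function(n) {
  data.frame(log10_a = numeric(n), ai = numeric(n), aj = numeric(n),
             log10_b = numeric(n), distance = numeric(n), tss = numeric(n),
             connectance = numeric(n))
}

#' Rejection ABC for the ADBM
#'
#' Repeats: draw parameters from the prior, predict the web with the ADBM,
#' compute the distance `1 - TSS` against the observed web, and accept the
#' draw with probability [kernel_weight()] (a uniform variate `alpha` is
#' drawn per proposal and the draw is accepted when `alpha <= p`). Stops
#' after `n_accept` acceptances. Because the ADBM is deterministic, every
#' accepted sample can be regenerated exactly from its parameters.
#'
#' @param observed a non-degenerate `predation_matrix` (at least one link
#'   and one absence).
#' @param community the `adbm_community` (must match the observed web).
#' @param prior a `prior_spec`.
#' @param config an `abc_config`.
#' @return An object of class `abc_posterior`: list with `samples` (a
#'   data.frame with columns `log10_a`, `ai`, `aj`, `log10_b`, `distance`,
#'   `tss`, `connectance`, one row per acceptance), `prior`, `config`, and
#'   `attempts_used`.
#' @export
rejection_abc <- function(observed, community, prior, config) {
  stopifnot(inherits(observed, "predation_matrix"),
            inherits(community, "adbm_community"),
            inherits(prior, "prior_spec"), inherits(config, "abc_config"))
  if (!same_community(observed$community, community)) {
    stop("observed web community does not match the supplied community")
  }
  os <- obs_stats(observed)
  pre <- adbm_precompute(community)
  n <- config$n_accept
  out <- make_sample_df(n)
  accepted <- 0L
  attempts <- 0L
  best_d <- Inf
  withr::with_seed(config$seed, {
    while (accepted < n) {
      if (attempts >= config$max_attempts) {
        stop(sprintf(paste0(
          "rejection ABC exhausted max_attempts = %d with %d/%d acceptances; ",
          "minimum distance seen was %.4f (tol = %.4f may be below the ",
          "model's attainable distance for this web)"),
          config$max_attempts, accepted, n, best_d, config$tol))
      }
      attempts <- attempts + 1L
      th <- draw_theta(prior)
      links <- adbm_predict_links(pre, a = 10^th[["log10_a"]],
                                  ai = th[["ai"]], aj = th[["aj"]],
                                  b = 10^th[["log10_b"]])
      d <- 1 - tss_fast(links, os)
      if (d < best_d) best_d <- d
      alpha <- stats::runif(1)
      if (alpha <= kernel_weight(d, config$tol)) {
        accepted <- accepted + 1L
        out[accepted, ] <- c(th, d, 1 - d, sum(links) / os$S2)
      }
    }
  })
  structure(list(samples = out, prior = prior, config = config,
                 attempts_used = attempts),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(paste0("ABC posterior: %d accepted samples in %d attempts ",
                     "(tol = %.3f, seed = %d)\n"),
              nrow(x$samples), x$attempts_used, x$config$tol, x$config$seed))
  cat(sprintf("  TSS range [%.3f, %.3f]; connectance range [%.3f, %.3f]\n",
              min(x$samples$tss), max(x$samples$tss),
              min(x$samples$connectance), max(x$samples$connectance)))
  invisible(x)
}

#' @export
as.data.frame.abc_posterior <- function(x, ...) x$samples

#' Write / read a posterior sample table
#'
#' Delimited text with columns `log10_a`, `ai`, `aj`, `log10_b`, `distance`,
#' `tss`, `connectance`, one row per accepted sample.
#'
#' @param post an `abc_posterior` (or its `samples` data.frame).
#' @param path file path (`.csv` comma-separated, otherwise tabs).
#' @export
write_posterior <- function(post, path) {
  df <- if (inherits(post, "abc_posterior")) post$samples else post
  write_delim_table(df, path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  df <- read_delim_table(path)
  need <- c("log10_a", "ai", "aj", "log10_b", "distance", "tss", "connectance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("posterior table missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

# Inverse-ECDF (type 1) quantiles so interval endpoints are always observed
# sample values and match a sort-based computation exactly.
interval_quantiles <- function(x, level) {
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stats::quantile(x, probs = p, type = 1, names = FALSE)
}

#' Select the ABC distance threshold from predicted connectance
#'
#' Scans an ascending grid of candidate thresholds and returns the smallest
#' one at which the interval of accepted predicted-connectance values
#' contains the observed connectance. One large reference sample of
#' (parameters, distance, connectance) is drawn from the prior and re-filtered
#' per grid value with kernel-weighted acceptance (one acceptance uniform per
#' draw, reused across thresholds, so acceptance sets are nested in `tol`);
#' for independent proposals this is statistically equivalent to running the
#' sampler once per threshold and far cheaper.
#'
#' @inheritParams rejection_abc
#' @param tol_grid ascending vector of candidate thresholds in (0, 2].
#' @param n_ref size of the reference prior sample.
#' @param seed integer seed for the reference sample.
#' @param interval_level central-interval coverage used as the "range" of
#'   predicted connectance (default 0.95, a 95% prediction interval).
#' @param interval_type `"central"` (quantile interval at `interval_level`)
#'   or `"minmax"` (full range of accepted values).
#' @param min_accept minimum number of acceptances a grid value needs before
#'   its interval is considered trustworthy.
#' @return An object of class `tol_selection`: list with `tol` (the chosen
#'   threshold), `table` (one row per grid value: `tol`, `n_accepted`,
#'   `mean`, `lower`, `upper`, `contains_observed`), `observed_connectance`.
#' @export
select_threshold <- function(observed, community, prior, tol_grid,
                             n_ref = 2000, seed = 1,
                             interval_level = 0.95,
                             interval_type = c("central", "minmax"),
                             min_accept = 20) {
  interval_type <- match.arg(interval_type)
  tol_grid <- as.numeric(tol_grid)
  if (!length(tol_grid)) stop("tol_grid must be non-empty")
  if (is.unsorted(tol_grid, strictly = TRUE)) {
    stop("tol_grid must be strictly ascending")
  }
  if (any(tol_grid <= 0 | tol_grid > 2)) stop("tol_grid values must be in (0, 2]")
  if (!same_community(observed$community, community)) {
    stop("observed web community does not match the supplied community")
  }
  os <- obs_stats(observed)
  pre <- adbm_precompute(community)
  c_obs <- os$L / os$S2
  d <- numeric(n_ref)
  cc <- numeric(n_ref)
  alpha <- numeric(n_ref)
  withr::with_seed(seed, {
    for (i in seq_len(n_ref)) {
      th <- draw_theta(prior)
      links <- adbm_predict_links(pre, a = 10^th[["log10_a"]],
                                  ai = th[["ai"]], aj = th[["aj"]],
                                  b = 10^th[["log10_b"]])
      d[i] <- 1 - tss_fast(links, os)
      cc[i] <- sum(links) / os$S2
      alpha[i] <- stats::runif(1)
    }
  })
  tab <- data.frame(tol = tol_grid, n_accepted = NA_integer_,
                    mean = NA_real_, lower = NA_real_, upper = NA_real_,
                    contains_observed = FALSE)
  for (k in seq_along(tol_grid)) {
    acc <- alpha <= kernel_weight(d, tol_grid[k])
    nk <- sum(acc)
    tab$n_accepted[k] <- nk
    if (nk == 0) next
    ck <- cc[acc]
    tab$mean[k] <- mean(ck)
    if (interval_type == "central") {
      q <- interval_quantiles(ck, interval_level)
    } else {
      q <- range(ck)
    }
    tab$lower[k] <- q[1]
    tab$upper[k] <- q[2]
    tab$contains_observed[k] <-
      nk >= min_accept && q[1] <= c_obs && c_obs <= q[2]
  }
  hit <- which(tab$contains_observed)
  if (!length(hit)) {
    stop("no threshold on the grid admitted the observed connectance ",
         sprintf("%.4f; intervals were: %s", c_obs,
                 paste(sprintf("tol %.2f -> [%.3f, %.3f] (n = %d)",
                               tab$tol, tab$lower, tab$upper, tab$n_accepted),
                       collapse = "; ")))
  }
  structure(list(tol = tol_grid[hit[1]], table = tab,
                 observed_connectance = c_obs,
                 interval_level = interval_level,
                 interval_type = interval_type),
            class = "tol_selection")
}

#' @export
print.tol_selection <- function(x, ...) {
  cat(sprintf("Selected distance threshold tol = %.3f (observed connectance %.4f)\n",
              x$tol, x$observed_connectance))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Propose a lower bound for the log10 a prior
#'
#' The best attainable TSS typically increases as log10 a decreases and then
#' plateaus; the prior's lower bound should sit at the start of that plateau,
#' covering the full variation of TSS with the smallest possible prior range.
#' For each grid value of log10 a this scans a shared set of probe draws of
#' (ai, aj, log10 b) from the prior and records the best TSS. The proposed
#' bound is the largest grid value L such that the best TSS attainable with
#' log10 a restricted to \[L, max(grid)\] is within `plateau_tol` of the best
#' over the whole grid — i.e. extending the prior below L gains less than the
#' tolerance. If only the grid minimum satisfies this (the scan is still
#' gaining at the bottom of the grid), no plateau was detected: a warning is
#' raised and the grid minimum returned.
#'
#' @inheritParams rejection_abc
#' @param log10_a_grid vector of candidate log10 a values (any order;
#'   sorted internally).
#' @param n_probe number of probe draws of the other three parameters.
#' @param seed integer seed for the probe draws.
#' @param plateau_tol TSS tolerance defining the plateau.
#' @return An object of class `a_bound_scan`: list with `bound`, `table`
#'   (columns `log10_a`, `best_tss`), `plateau_tol`.
#' @export
elicit_a_lower_bound <- function(observed, community, prior, log10_a_grid,
                                 n_probe = 200, seed = 1, plateau_tol = 0.02) {
  stopifnot(length(log10_a_grid) >= 1, n_probe >= 1)
  if (!same_community(observed$community, community)) {
    stop("observed web community does not match the supplied community")
  }
  grid <- sort(as.numeric(log10_a_grid))
  os <- obs_stats(observed)
  pre <- adbm_precompute(community)
  probes <- withr::with_seed(seed, {
    data.frame(
      ai = stats::runif(n_probe, prior$ai_bounds[1], prior$ai_bounds[2]),
      aj = stats::runif(n_probe, prior$aj_bounds[1], prior$aj_bounds[2]),
      log10_b = stats::runif(n_probe, prior$log10_b_bounds[1],
                             prior$log10_b_bounds[2])
    )
  })
  best <- vapply(grid, function(la) {
    a <- 10^la
    max(vapply(seq_len(n_probe), function(i) {
      links <- adbm_predict_links(pre, a = a, ai = probes$ai[i],
                                  aj = probes$aj[i], b = 10^probes$log10_b[i])
      tss_fast(links, os)
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(log10_a = grid, best_tss = best)
  top <- max(best)
  suffix_max <- rev(cummax(rev(best)))  # best TSS attainable on [grid[k], grid max]
  in_band <- (top - suffix_max) <= plateau_tol
  bound <- grid[max(which(in_band))]
  if (bound == grid[1] && length(grid) > 1) {
    warning("no TSS plateau detected on the log10 a grid; returning the grid minimum")
  }
  structure(list(bound = bound, table = tab, plateau_tol = plateau_tol),
            class = "a_bound_scan")
}

#' @export
print.a_bound_scan <- function(x, ...) {
  cat(sprintf("Proposed lower bound for log10 a: %.3g (plateau tolerance %.3g)\n",
              x$bound, x$plateau_tol))
  invisible(x)
}

#' Posterior-predictive link frequencies
#'
#' Regenerates every accepted web deterministically from its parameters and
#' aggregates them into a [link_frequency()] matrix, a histogram of how often
#' each species pair was linked across the accepted webs, and the count of
#' pairs never predicted to be linked.
#'
#' @param post an `abc_posterior`.
#' @param community the `adbm_community` the fit was run on.
#' @param keep_webs if `TRUE`, also return the regenerated webs (one
#'   `predation_matrix` per accepted sample).
#' @return An object of class `posterior_predictive`: list with `link_freq`,
#'   `count_histogram` (named vector over counts 0..n_webs, summing to S^2),
#'   `never_predicted`, and optionally `webs`.
#' @export
posterior_predictive <- function(post, community, keep_webs = FALSE) {
  stopifnot(inherits(post, "abc_posterior"), inherits(community, "adbm_community"))
  df <- post$samples
  if (!nrow(df)) stop("posterior is empty")
  pre <- adbm_precompute(community)
  S <- pre$S
  counts <- matrix(0L, S, S)
  webs <- if (keep_webs) vector("list", nrow(df)) else NULL
  for (i in seq_len(nrow(df))) {
    links <- adbm_predict_links(pre, a = 10^df$log10_a[i], ai = df$ai[i],
                                aj = df$aj[i], b = 10^df$log10_b[i])
    counts <- counts + links
    if (keep_webs) webs[[i]] <- predation_matrix(community, links)
  }
  lf <- link_frequency(community, counts, nrow(df))
  hist <- table(factor(counts, levels = 0:nrow(df)))
  structure(list(link_freq = lf,
                 count_histogram = hist,
                 never_predicted = sum(counts == 0L),
                 webs = webs),
            class = "posterior_predictive")
}

#' Summarize an ABC posterior
#'
#' Means and central empirical intervals (type-1/inverse-ECDF quantiles at
#' probabilities `(1 - level)/2` and `1 - (1 - level)/2`) for each parameter
#' on its sampling scale (credible intervals) and for the per-sample TSS and
#' predicted connectance (posterior-predictive intervals). `level = 1` gives
#' the min--max range.
#'
#' @param post an `abc_posterior`.
#' @param level interval coverage in (0, 1\].
#' @return A data.frame with columns `quantity`, `kind` (`"credible"` or
#'   `"prediction"`), `mean`, `lower`, `upper`.
#' @export
summarize_posterior <- function(post, level = 0.95) {
  stopifnot(inherits(post, "abc_posterior"))
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  df <- post$samples
  if (!nrow(df)) stop("posterior is empty")
  qty <- c("log10_a", "ai", "aj", "log10_b", "tss", "connectance")
  kind <- c(rep("credible", 4), rep("prediction", 2))
  rows <- lapply(seq_along(qty), function(k) {
    x <- df[[qty[k]]]
    q <- interval_quantiles(x, level)
    data.frame(quantity = qty[k], kind = kind[k], mean = mean(x),
               lower = q[1], upper = q[2])
  })
  do.call(rbind, rows)
}
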