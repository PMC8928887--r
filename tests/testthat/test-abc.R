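test_that("prior draws respect bounds, are uniform, and are seed-reproducible", {
  prior <- prior_spec()
  draws <- withr::with_seed(1, replicate(10000, {
    p <- sample_prior(prior)
    c(p$ai, p$aj, log10(p$a), log10(p$b))
  }))
  expect_true(all(draws[1, ] >= -1.5 & draws[1, ] <= 1.5))
  expect_true(all(draws[2, ] >= 0 & draws[2, ] <= 3))
  expect_true(all(draws[3, ] >= -12 & draws[3, ] <= 10))
  expect_true(all(draws[4, ] >= -15 & draws[4, ] <= 15))
  ks <- suppressWarnings(ks.test(draws[1, ], "punif", -1.5, 1.5))
  expect_gt(ks$p.value, 0.01)

  again <- withr::with_seed(1, replicate(10000, {
    p <- sample_prior(prior)
    c(p$ai, p$aj, log10(p$a), log10(p$b))
  }))
  expect_identical(draws, again)

  degen <- prior_spec(ai_bounds = c(0.5, 0.5), aj_bounds = c(1, 1),
                      log10_a_bounds = c(-3, -3), log10_b_bounds = c(-1, -1))
  p <- withr::with_seed(2, sample_prior(degen))
  expect_equal(c(p$a, p$ai, p$aj, p$b), c(1e-3, 0.5, 1, 0.1))
})

test_that("the Epanechnikov acceptance weight has the right shape", {
  expect_equal(kernel_weight(0, 0.5), 1)
  expect_equal(kernel_weight(0.5, 0.5), 0)
  expect_equal(kernel_weight(0.7, 0.5), 0)
  expect_equal(kernel_weight(0.25, 0.5), 0.75)
  d <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(kernel_weight(d, 0.5)) < 0))
})

test_that("a point-mass prior at the truth yields a posterior of exact copies", {
  scn <- default_scenario()
  com <- generate_community(10, scn$log10_mass_bounds, seed = 31)
  truth <- generate_truth(com, scn$true_params)
  point <- prior_spec(ai_bounds = c(0.5, 0.5), aj_bounds = c(0.5, 0.5),
                      log10_a_bounds = c(-3, -3), log10_b_bounds = c(-1, -1))
  post <- rejection_abc(truth, com, point, abc_config(tol = 0.5, n_accept = 25, seed = 32))
  expect_equal(nrow(post$samples), 25)
  expect_equal(post$attempts_used, 25L)   # every proposal has d = 0, p = 1
  expect_true(all(post$samples$distance == 0))
  expect_true(all(post$samples$tss == 1))
  expect_true(all(post$samples$log10_b == -1))
})

test_that("an unattainable tolerance fails with the best distance seen", {
  scn <- default_scenario()
  com <- generate_community(8, scn$log10_mass_bounds, seed = 41)
  truth <- generate_truth(com, scn$true_params)
  # point-mass prior away from the truth: every draw has the same positive distance
  off <- prior_spec(ai_bounds = c(-1, -1), aj_bounds = c(2, 2),
                    log10_a_bounds = c(5, 5), log10_b_bounds = c(3, 3))
  expect_error(
    rejection_abc(truth, com, off,
                  abc_config(tol = 1e-3, n_accept = 5, max_attempts = 50, seed = 42)),
    "minimum distance seen")
})

test_that("accepted samples regenerate their stored distances exactly", {
  scn <- default_scenario()
  com <- generate_community(scn$S, scn$log10_mass_bounds, seed = 51)
  truth <- generate_truth(com, scn$true_params)
  prior <- prior_spec()
  sel <- select_threshold(truth, com, prior, seq(0.3, 1, by = 0.1),
                          n_ref = 800, seed = 52)
  post <- rejection_abc(truth, com, prior,
                        abc_config(tol = sel$tol, n_accept = 60, seed = 53,
                                   max_attempts = 2e5))
  expect_true(all(post$samples$distance < sel$tol))
  expect_equal(post$samples$tss, 1 - post$samples$distance)
  for (i in seq_len(nrow(post$samples))) {
    s <- post$samples[i, ]
    w <- predict_web(com, adbm_params(a = 10^s$log10_a, ai = s$ai,
                                      aj = s$aj, b = 10^s$log10_b))
    expect_identical(web_distance(truth, w), s$distance)
    expect_identical(connectance(w), s$connectance)
  }
})

test_that("threshold selection returns the smallest admitting tol and widens with tol", {
  scn <- default_scenario()
  com <- generate_community(scn$S, scn$log10_mass_bounds, seed = 61)
  truth <- generate_truth(com, scn$true_params)
  sel <- select_threshold(truth, com, prior_spec(), seq(0.2, 1, by = 0.1),
                          n_ref = 1500, seed = 62)
  tab <- sel$table
  hit <- which(tab$contains_observed)
  expect_equal(sel$tol, tab$tol[hit[1]])
  expect_true(tab$lower[hit[1]] <= connectance(truth))
  expect_true(tab$upper[hit[1]] >= connectance(truth))
  # interval width non-decreasing in tol (nested acceptance sets, minmax type)
  selmm <- select_threshold(truth, com, prior_spec(), seq(0.2, 1, by = 0.1),
                            n_ref = 1500, seed = 62, interval_type = "minmax",
                            min_accept = 1)
  w <- selmm$table$upper - selmm$table$lower
  w <- w[!is.na(w)]
  expect_true(all(diff(w) >= 0))
})

test_that("the log10 a lower-bound scan finds the plateau", {
  scn <- default_scenario()
  com <- generate_community(12, scn$log10_mass_bounds, seed = 71)
  truth <- generate_truth(com, scn$true_params)
  prior <- prior_spec()
  grid <- seq(-14, 6, by = 2)
  scan <- elicit_a_lower_bound(truth, com, prior, grid, n_probe = 120, seed = 72)
  expect_true(scan$bound %in% grid)
  # restricting log10 a to [bound, grid max] loses < plateau_tol of best TSS,
  # and the bound is the largest grid value with that property
  tab <- scan$table
  top <- max(tab$best_tss)
  attainable <- function(lo) max(tab$best_tss[tab$log10_a >= lo])
  expect_lte(top - attainable(scan$bound), scan$plateau_tol)
  above <- grid[grid > scan$bound]
  if (length(above)) {
    expect_gt(top - attainable(above[1]), scan$plateau_tol)
  }
  # dense-grid oracle: an independent brute-force search over a finer grid
  # for the largest admissible bound agrees within one coarse step
  dense_tab <- elicit_a_lower_bound(truth, com, prior, seq(-14, 6, by = 1),
                                    n_probe = 120, seed = 72)$table
  dtop <- max(dense_tab$best_tss)
  ok <- vapply(dense_tab$log10_a, function(lo) {
    dtop - max(dense_tab$best_tss[dense_tab$log10_a >= lo]) <= scan$plateau_tol
  }, logical(1))
  dense_bound <- max(dense_tab$log10_a[ok])
  expect_lte(abs(dense_bound - scan$bound), 2)

  # best TSS constant over a grid confined to the saturated region:
  # the whole grid is plateau, so the grid maximum is returned
  flat <- elicit_a_lower_bound(truth, com, prior, seq(-14, -8, by = 2),
                               n_probe = 120, seed = 73)
  expect_equal(flat$bound, -8)
})

test_that("posterior-predictive frequencies match an independent recount", {
  scn <- default_scenario()
  com <- generate_community(scn$S, scn$log10_mass_bounds, seed = 81)
  truth <- generate_truth(com, scn$true_params)
  prior <- prior_spec()
  post <- rejection_abc(truth, com, prior,
                        abc_config(tol = 0.8, n_accept = 40, seed = 82,
                                   max_attempts = 2e5))
  pp <- posterior_predictive(post, com, keep_webs = TRUE)
  recount <- Reduce(`+`, lapply(pp$webs, function(w) w$links))
  expect_equal(unname(pp$link_freq$counts), unname(recount))
  expect_equal(sum(pp$count_histogram), scn$S^2)
  expect_equal(unname(pp$count_histogram[["0"]]), pp$never_predicted)
  expect_true(all(pp$link_freq$counts >= 0 & pp$link_freq$counts <= 40))

  # posterior of identical params -> counts only 0 or n_webs
  point <- prior_spec(ai_bounds = c(0.5, 0.5), aj_bounds = c(0.5, 0.5),
                      log10_a_bounds = c(-3, -3), log10_b_bounds = c(-1, -1))
  postp <- rejection_abc(truth, com, point, abc_config(tol = 0.5, n_accept = 10, seed = 83))
  ppp <- posterior_predictive(postp, com)
  expect_true(all(ppp$link_freq$counts %in% c(0L, 10L)))
})

test_that("posterior summaries match a sort-based quantile oracle", {
  scn <- default_scenario()
  com <- generate_community(scn$S, scn$log10_mass_bounds, seed = 91)
  truth <- generate_truth(com, scn$true_params)
  post <- rejection_abc(truth, com, prior_spec(),
                        abc_config(tol = 0.8, n_accept = 50, seed = 92,
                                   max_attempts = 2e5))
  s <- summarize_posterior(post, level = 0.9)
  x <- sort(post$samples$log10_b)
  n <- length(x)
  lo <- x[max(1, ceiling(n * 0.05))]
  hi <- x[max(1, ceiling(n * 0.95))]
  row <- s[s$quantity == "log10_b", ]
  expect_equal(row$lower, lo)
  expect_equal(row$upper, hi)
  expect_equal(row$mean, mean(post$samples$log10_b))

  # level = 1 gives the min-max range; constant samples give zero width
  s1 <- summarize_posterior(post, level = 1)
  expect_equal(s1[s1$quantity == "ai", ]$lower, min(post$samples$ai))
  expect_equal(s1[s1$quantity == "ai", ]$upper, max(post$samples$ai))
  const <- post
  const$samples$ai <- 0.25
  sc <- summarize_posterior(const)
  expect_equal(sc[sc$quantity == "ai", ]$lower, 0.25)
  expect_equal(sc[sc$quantity == "ai", ]$upper, 0.25)
})

test_that("posterior tables round-trip through delimited text", {
  scn <- default_scenario()
  com <- generate_community(8, scn$log10_mass_bounds, seed = 95)
  truth <- generate_truth(com, scn$true_params)
  post <- rejection_abc(truth, com, prior_spec(),
                        abc_config(tol = 0.9, n_accept = 15, seed = 96,
                                   max_attempts = 2e5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_posterior(post, f)
  df <- read_posterior(f)
  expect_equal(df$log10_b, post$samples$log10_b, tolerance = 1e-12)
  expect_equal(df$distance, post$samples$distance, tolerance = 1e-12)
})
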