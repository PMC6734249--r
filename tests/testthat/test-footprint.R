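# brute-force oracle: evaluate both multinomial likelihoods as direct
# products and take the log ratio
brute_log_ratio <- function(X, lambda) {
  S <- length(lambda)
  log(prod(lambda^X) / prod((1 / S)^X))
}

test_that("multinomial_log_ratio matches hand arithmetic and the product oracle", {
  lam <- c(0.4, 0.1, 0.1, 0.4)
  X <- c(2, 0, 0, 2)
  expect_equal(multinomial_log_ratio(X, lam), 4 * log(1.6))
  expect_equal(multinomial_log_ratio(X, lam), log(6.5536 / 1),
               tolerance = 1e-12)
  expect_equal(multinomial_log_ratio(X, lam), brute_log_ratio(X, lam))
  set.seed(9)
  for (i in 1:20) {
    S <- sample(3:6, 1)
    lam <- runif(S); lam <- lam / sum(lam)
    X <- rpois(S, 2)
    expect_equal(multinomial_log_ratio(X, lam), brute_log_ratio(X, lam),
                 tolerance = 1e-10)
  }
  expect_equal(multinomial_log_ratio(rep(0, 4), lam = c(.4, .1, .1, .4)), 0)
  expect_equal(multinomial_log_ratio(c(3, 1, 7, 2), rep(0.25, 4)), 0)
  expect_error(multinomial_log_ratio(c(-1, 0, 0, 0), rep(0.25, 4)),
               "negative")
  expect_error(multinomial_log_ratio(c(1, 0), rep(0.25, 4)), "length")
})

test_that("EM recovers the generator's parameters and keeps the likelihood monotone", {
  p <- simulation_params(n_bound_sites = 300L, n_unbound_sites = 200L,
                         nb_mean_bound = 40, nb_mean_unbound = 8,
                         seed = 11L)
  sim <- simulate_fragments(p)
  cm <- build_cut_matrix(sim$fragments, sim$sites, flank = p$flank)
  model <- fit_footprint_model(cm)
  expect_true(all(diff(model$loglik_trace) > -1e-6))
  expect_equal(sum(model$lambda), 1, tolerance = 1e-9)
  expect_gt(cor(model_profile(model), p$lambda_truth), 0.95)
  expect_equal(model$pi, 0.6, tolerance = 0.1)
  # determinism: the fit has no random element
  model2 <- fit_footprint_model(cm)
  expect_identical(model$lambda, model2$lambda)
  expect_identical(model$loglik_trace, model2$loglik_trace)
})

test_that("null-only data leaves lambda uniform within sampling error", {
  # At ~2e5 ends the multinomial sampling scale is 0.4*sqrt(S/N) ~ 0.02 in
  # total variation; a 2-3x margin covers the mixture's tendency to absorb
  # sampling structure into the bound component at finite depth. Both
  # components see the same uniform world, so pi itself is unidentifiable
  # here and is not asserted.
  p <- simulation_params(n_bound_sites = 0L, n_unbound_sites = 200L,
                         nb_mean_unbound = 1000, nb_size_unbound = 50,
                         seed = 21L)
  sim <- simulate_fragments(p)
  cm <- build_cut_matrix(sim$fragments, sim$sites, flank = p$flank)
  model <- suppressWarnings(fit_footprint_model(cm))
  S <- model$S
  expect_lt(0.5 * sum(abs(model$lambda - 1 / S)), 0.06)
  expect_lt(max(abs(model$lambda - 1 / S)) * S, 0.6)
  expect_true(all(diff(model$loglik_trace) > -1e-6))
})

test_that("fit_footprint_model rejects degenerate input", {
  empty <- matrix(0, 30, 10)
  expect_error(fit_footprint_model(empty), "all zero")
  few <- matrix(rpois(10 * 8, 3), 10, 8)
  expect_error(fit_footprint_model(few), ">= 20 sites")
})

test_that("score_sites reduces to the multinomial term when other ratios cancel", {
  nb <- list(mean = 10, size = 2, poisson = FALSE)
  model <- structure(list(S = 4L, W = 2L, lambda = c(0.4, 0.1, 0.1, 0.4),
                          pi = 0.5, nb_bound = nb, nb_null = nb,
                          loglik_trace = 0, converged = TRUE),
                     class = "FootprintModel")
  X <- matrix(c(2, 0, 0, 2), 1, 4)
  sc <- score_sites(model, X)
  expect_equal(sc$log_odds, 4 * log(1.6))
  expect_equal(sc$posterior, plogis(4 * log(1.6)))
  expect_equal(sc$posterior, 0.868, tolerance = 1e-3)
  # R = 0 with equal components: all ratios are 1
  sc0 <- score_sites(model, matrix(0, 1, 4))
  expect_equal(sc0$log_odds, 0)
  expect_equal(sc0$posterior, 0.5)
})

test_that("scores are invariant under joint column permutation", {
  set.seed(14)
  lam <- runif(6); lam <- lam / sum(lam)
  model <- structure(list(S = 6L, W = 3L, lambda = lam, pi = 0.3,
                          nb_bound = list(mean = 20, size = 3,
                                          poisson = FALSE),
                          nb_null = list(mean = 5, size = 1,
                                         poisson = FALSE),
                          loglik_trace = 0, converged = TRUE),
                     class = "FootprintModel")
  X <- matrix(rpois(5 * 6, 4), 5, 6)
  base <- score_sites(model, X)$log_odds
  perm <- sample(6)
  model_p <- model
  model_p$lambda <- lam[perm]
  expect_equal(score_sites(model_p, X[, perm, drop = FALSE])$log_odds, base)
})

test_that("log-odds grow monotonically as lambda-shaped counts are scaled", {
  lam <- c(0.05, 0.1, 0.2, 0.3, 0.2, 0.1, 0.05)
  model <- structure(list(S = 7L, W = 3L, lambda = lam, pi = 0.5,
                          nb_bound = list(mean = 10, size = 2,
                                          poisson = FALSE),
                          nb_null = list(mean = 10, size = 2,
                                         poisson = FALSE),
                          loglik_trace = 0, converged = TRUE),
                     class = "FootprintModel")
  base <- 20 * lam
  lo <- vapply(c(1, 2, 4, 8), function(k) {
    score_sites(model, matrix(k * base, 1))$log_odds
  }, numeric(1))
  expect_true(all(diff(lo) > 0))
})

test_that("synthetic strong-signal log-odds separate truth labels (AUROC)", {
  p <- small_sim_params(seed = 77L)
  sim <- simulate_fragments(p)
  cm <- build_cut_matrix(sim$fragments, sim$sites, flank = p$flank)
  model <- fit_footprint_model(cm)
  sc <- score_sites(model, cm)
  truth <- sim$truth$bound[match(sc$site_id, sim$truth$site_id)]
  expect_gte(auroc(sc$log_odds, truth), 0.95)
  # clipping keeps everything finite
  expect_true(all(is.finite(sc$log_odds)) && all(is.finite(sc$posterior)))
})

test_that("model JSON round-trips through disk", {
  p <- small_sim_params(seed = 3L)
  sim <- simulate_fragments(p)
  cm <- build_cut_matrix(sim$fragments, sim$sites, flank = p$flank)
  model <- fit_footprint_model(cm)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$lambda, model$lambda)
  expect_equal(back$pi, model$pi)
  expect_equal(back$nb_bound$mean, model$nb_bound$mean)
  sc1 <- score_sites(model, cm)
  sc2 <- score_sites(back, cm)
  expect_equal(sc2$log_odds, sc1$log_odds)
})
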