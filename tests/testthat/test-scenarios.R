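test_that("scenario generators reproduce the published signature inventories", {
  counts <- function(gen) {
    vapply(gen$studies, function(s) length(s$empirical_signatures), integer(1))
  }
  expect_equal(sum(counts(generate_scenario(scenario_config(1, seed = 2)))), 12)
  expect_equal(sum(counts(generate_scenario(scenario_config(2, seed = 2)))), 9)
  expect_equal(sum(counts(generate_scenario(scenario_config(3, seed = 2)))), 9)
  expect_equal(sum(counts(generate_scenario(scenario_config(4, seed = 2)))), 6)
  expect_equal(counts(generate_scenario(scenario_config(5, seed = 2))), c(6, 7, 11))
  expect_equal(sum(counts(generate_scenario(scenario_config(6, seed = 2)))), 7)
  g7 <- generate_scenario(scenario_config(7, seed = 2))
  expect_equal(sum(counts(g7)), 10)
  expect_length(g7$between$empirical, 1)
})

test_that("scenario generation is seed-reproducible and truth is recorded", {
  g1 <- generate_scenario(scenario_config(1, seed = 9))
  g2 <- generate_scenario(scenario_config(1, seed = 9))
  expect_identical(g1$studies[[2]]$empirical_signatures,
                   g2$studies[[2]]$empirical_signatures)
  expect_equal(g1$truth$beta,
               c(b0 = 1, b_x1 = 1, b_x2 = 1, b_x3 = 1, sigma = 1))
  g3 <- generate_scenario(scenario_config(1, seed = 10))
  expect_false(identical(g1$studies[[1]]$empirical_signatures,
                         g3$studies[[1]]$empirical_signatures))
  expect_error(scenario_config(12), "id")
})

test_that("published studies use independent seed branches", {
  g <- generate_scenario(scenario_config(2, seed = 5))
  sigs <- lapply(g$studies, function(s) unname(s$empirical_signatures))
  expect_false(identical(sigs[[1]], sigs[[2]]))
})

test_that("a single noisy replication cycle runs end to end", {
  rep <- run_scenario(scenario_config(2, R = 2, seed = 4, S = 25, S_final = 80,
                                      n_weight_reps = 250))
  expect_equal(rep$R_effective, 2)
  expect_identical(rep$summary$parameter,
                   c("b0", "b_x1", "b_x2", "b_x3", "sigma"))
  expect_true(all(is.finite(rep$summary$bias)))
  expect_true(all(rep$summary$coverage >= 0 & rep$summary$coverage <= 1))
  expect_false(rep$flagged)
})

test_that("DerSimonian-Laird matches its closed form and edge cases", {
  dl <- dersimonian_laird(c(0.1, 0.3, 0.5), c(0.01, 0.01, 0.01))
  expect_equal(dl$tau2_hat, 0.03, tolerance = 1e-12)
  expect_equal(dl$mu_hat, 0.3, tolerance = 1e-12)
  same <- dersimonian_laird(rep(0.4, 4), c(0.01, 0.02, 0.04, 0.08))
  expect_equal(same$tau2_hat, 0)
  w <- 1 / c(0.01, 0.02, 0.04, 0.08)
  expect_equal(same$mu_hat, 0.4)
  # equal variances: the summary effect is the arithmetic mean
  eq <- dersimonian_laird(c(0.2, 0.5, 0.8), rep(0.05, 3))
  expect_equal(eq$mu_hat, 0.5, tolerance = 1e-12)
  expect_error(dersimonian_laird(0.3, 0.01), "at least two")
})

test_that("DerSimonian-Laird agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(14)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    y <- rnorm(L, 0.3, 0.3)
    v <- runif(L, 0.01, 0.2)
    dl <- dersimonian_laird(y, v)
    rm <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(dl$mu_hat, as.numeric(rm$beta), tolerance = 1e-8)
    expect_equal(dl$tau2_hat, rm$tau2, tolerance = 1e-8)
    expect_equal(dl$se_mu, rm$se, tolerance = 1e-8)
  }
})

test_that("random-effects generation matches its declared moments", {
  cfg <- scenario_config(7, seed = 30, tau2 = 0.04)
  gen <- generate_scenario(cfg)
  expect_equal(gen$truth$beta[["tau"]], 0.2)
  # replicated effect draws have variance tau2 + sigma^2 / n_l
  plan <- fix_fast_plan(seed = 1)
  M <- simulate_signatures(gen$model, gen$truth$beta, gen$studies, plan,
                           between = gen$between, S = 3000)
  v1 <- var(M["study1:effect", ])
  expect_equal(v1, 0.04 + 1 / 20, tolerance = 0.15)
  # between-study variance of effects sits in the first stacked row
  expect_match(rownames(M)[1], "^between:")
  expect_gt(mean(M[1, ]), 0.03)
})

test_that("the nonlinear-surface comparison favors the aggregated meta-model", {
  cmp <- scenario6_surface_comparison(scenario_config(6, seed = 8, S = 30,
                                                      S_final = 100,
                                                      n_weight_reps = 300))
  expect_gt(cmp$cor_meta, max(cmp$cor_priors))
  expect_length(cmp$cor_priors, 2)
})
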