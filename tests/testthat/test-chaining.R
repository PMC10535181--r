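test_that("chain_priors maps posterior summaries onto the next study", {
  src <- data.frame(compound_id = c("C1", "C2"),
                    posterior_median = c(0.8, -0.2),
                    post_sd = c(0.2, 0.5),
                    stringsAsFactors = FALSE)
  pr <- chain_priors(src, source_label = "study1")
  expect_equal(pr$location, c(0.8, -0.2))
  expect_equal(pr$scale, c(0.2, 0.5))
  expect_true(all(pr$provenance == "chained-from:study1"))

  pairs <- data.frame(compound_id_a = "C2", compound_id_b = "Z9")
  pr2 <- chain_priors(src, pairs, source_label = "study1")
  expect_equal(pr2$compound_id, "Z9")
  expect_equal(pr2$location, -0.2)

  src$post_sd[1] <- 0
  expect_error(chain_priors(src), "degenerate.*C1")
})

test_that("compounds absent from the source fall back to default priors", {
  d <- make_autoscaled(n_per_group = 15, effects = c(0.5, 0), seed = 3)
  priors <- data.frame(compound_id = "C1", location = 0.4, scale = 0.1,
                       provenance = "chained-from:src",
                       stringsAsFactors = FALSE)
  res <- run_bayes(d, priors, mcmc_config(2, 600, 200, seed = 2))
  expect_equal(res$prior_provenance,
               c("chained-from:src", "default"))
})

test_that("full propagation with known variance equals the pooled posterior", {
  # worked toy: prior N(0,1); each of two studies is one unit observation
  # (likelihood N(1,1) for beta), so the chained posterior is N(2/3, 1/3)
  st <- list(y = 1, X = matrix(1, 1, 1))
  ch <- chain_known_variance(list(st, st), prior_mean = 0,
                             prior_cov = matrix(1), sigma = 1)
  expect_equal(ch$final$mean, 2 / 3, tolerance = 1e-12)
  expect_equal(ch$final$cov[1, 1], 1 / 3, tolerance = 1e-12)

  # chaining over a random 2-way partition reproduces the pooled fit
  set.seed(10)
  n <- 30
  X <- cbind(1, rep(c(1, 0), n / 2), rnorm(n))
  y <- drop(X %*% c(0.2, 0.8, -0.4)) + rnorm(n)
  pm <- c(0, 0, 0); pc <- diag(3)
  idx <- sample(n, n / 2)
  split_fit <- chain_known_variance(
    list(list(y = y[idx], X = X[idx, , drop = FALSE]),
         list(y = y[-idx], X = X[-idx, , drop = FALSE])),
    pm, pc, sigma = 1.3)
  pooled <- posterior_known(y, X, pm, pc, sigma = 1.3)
  expect_lt(max(abs(split_fit$final$mean - pooled$mean)), 1e-10)
  expect_lt(max(abs(split_fit$final$cov - pooled$cov)), 1e-10)
})

test_that("beta-only chaining is order-sensitive by design", {
  sim <- simulate_cohorts(simulation_config(
    n_studies = 2, n_cases = 20, n_controls = 20, n_compounds = 12,
    null_fraction = 0.5, lod_quantile = 0, seed = 42))
  proc <- lapply(sim$studies, function(s) preprocess(s)$data)
  cfg <- mcmc_config(2, 600, 200, seed = 5)
  fwd <- run_chain(proc, cfg)
  bwd <- run_chain(rev(proc), cfg)
  # the final posterior of the forward chain differs from the backward one
  fin_fwd <- fwd$results[[2]]
  fin_bwd <- bwd$results[[2]]
  expect_false(isTRUE(all.equal(fin_fwd$posterior_median,
                                fin_bwd$posterior_median)))
})

test_that("run_chain accumulates information across studies", {
  sim <- simulate_cohorts(simulation_config(
    n_studies = 3, n_cases = 25, n_controls = 25, n_compounds = 20,
    null_fraction = 0.3, effect_sd = 0.8, lod_quantile = 0, seed = 8))
  proc <- lapply(sim$studies, function(s) preprocess(s)$data)
  ch <- run_chain(proc, mcmc_config(2, 800, 300, seed = 9))
  expect_length(ch$results, 3L)
  expect_equal(ch$manifest[[1]]$n_chained, 0L)
  expect_gt(ch$manifest[[2]]$n_chained, 0L)
  # posterior uncertainty shrinks for most non-null shared compounds
  nul <- sim$truth$effects$null[match(ch$results[[1]]$compound_id,
                                      sim$truth$effects$compound_id)]
  sd1 <- ch$results[[1]]$post_sd[!nul]
  sd3 <- ch$results[[3]]$post_sd[!nul]
  expect_gte(mean(sd3 <= sd1), 0.8)
})

test_that("run_chain validates its inputs", {
  sim <- simulate_cohorts(simulation_config(
    n_studies = 2, n_cases = 10, n_controls = 10, n_compounds = 5,
    lod_quantile = 0, seed = 2))
  expect_error(run_chain(sim$studies[1]), "two studies")
  empty <- sim$studies[[2]]
  empty$abundance <- empty$abundance[0, , drop = FALSE]
  empty$samples <- empty$samples[0, ]
  expect_error(run_chain(list(sim$studies[[1]], empty)), "zero samples")
})
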