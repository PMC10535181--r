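test_that("default prior scales follow 2.5 * sd(y) / sd(x)", {
  # binary column engineered to have sd exactly 0.5, y with sd exactly 1
  g <- rep(c(0, 1), each = 4)
  g <- g * sqrt(0.25 / var(g)) # rescale so sd(g) == 0.5
  y <- as.numeric(scale(rnorm(8)))
  X <- cbind("(Intercept)" = 1, group = g)
  pr <- default_prior(X, y)
  expect_equal(pr$scale[pr$terms == "group"], 2.5 * 1 / 0.5,
               tolerance = 1e-12)
  expect_equal(pr$location[pr$terms == "(Intercept)"], mean(y))
  expect_equal(pr$scale[pr$terms == "(Intercept)"], 2.5 * sd(y))

  # intercept prior scale follows sd(y)
  y2 <- y * 2
  expect_equal(default_prior(X, y2)$scale[1], 5.0, tolerance = 1e-12)

  # determinism: identical inputs, identical spec
  expect_identical(default_prior(X, y), default_prior(X, y))

  # a constant non-intercept column is rejected, not silently absorbed
  Xbad <- cbind("(Intercept)" = 1, group = g, flat = rep(2, 8))
  expect_error(default_prior(Xbad, y), "zero-variance.*flat")
})

test_that("prior_spec validates scales and noise parameters", {
  expect_error(prior_spec("group", 0, -1), "scale")
  expect_error(prior_spec("group", 0, 1, sigma_shape = 0), "shape")
  expect_error(prior_spec("group", 0, 1, form = "known"), "sigma_known")
  pr <- prior_spec("group", 0.8, 0.2, provenance = "chained-from:study1")
  expect_s3_class(pr, "prior_spec")
  expect_equal(pr$provenance, "chained-from:study1")
})

test_that("the sampler is deterministic given the seed", {
  set.seed(99)
  g <- rep(c(1, 0), each = 15)
  y <- 0.6 * g + rnorm(30)
  X <- cbind("(Intercept)" = 1, group = g)
  cfg <- mcmc_config(2, 500, 200, seed = 77)
  p1 <- sample_posterior(y, X, config = cfg)
  p2 <- sample_posterior(y, X, config = cfg)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$sigma2, p2$sigma2)
  p3 <- sample_posterior(y, X, config = mcmc_config(2, 500, 200, seed = 78))
  expect_false(identical(p1$draws, p3$draws))
})

test_that("flat-prior limit reproduces the OLS estimate", {
  set.seed(14)
  n <- 200
  g <- rep(c(1, 0), each = n / 2)
  y <- 0.5 * g + rnorm(n)
  X <- cbind("(Intercept)" = 1, group = g)
  pr <- prior_spec(colnames(X), c(0, 0), c(1e6, 1e6),
                   sigma_shape = 0.01, sigma_rate = 0.01)
  post <- sample_posterior(y, X, pr, mcmc_config(4, 2000, 1000, seed = 5))
  ols <- fit_ols(y, X)
  d <- post$draws[, "group"]
  expect_lt(abs(mean(d) - ols$beta_p), 3 * sd(d) / sqrt(length(d) / 5))
})

test_that("known-variance conjugate updating matches the closed form", {
  # prior N(0,1); a single unit observation with sigma = 1 has likelihood
  # N(1,1) for beta, so the posterior is N(0.5, 0.5)
  X <- matrix(1, 1, 1, dimnames = list(NULL, "group"))
  y <- 1
  pr <- prior_spec("group", 0, 1, sigma_known = 1, form = "known")
  ap <- analytic_posterior(y, X, pr)
  expect_equal(ap$beta_p$mean, 0.5, tolerance = 1e-12)
  expect_equal(ap$beta_p$sd^2, 0.5, tolerance = 1e-12)
  post <- sample_posterior(y, X, pr, mcmc_config(4, 3000, 1000, seed = 3))
  d <- post$draws[, "group"]
  expect_lt(abs(mean(d) - 0.5), 3 * sd(d) / sqrt(length(d)))
  expect_equal(var(d), 0.5, tolerance = 0.05)
})

test_that("analytic posterior handles limits and rejects what it cannot do", {
  set.seed(8)
  X <- cbind(group = rep(c(1, 0), 10))
  y <- rnorm(20)
  # dogmatic prior: posterior collapses onto the prior location
  pr0 <- prior_spec("group", 0.7, 1e-8, sigma_known = 1, form = "known")
  expect_equal(analytic_posterior(y, X, pr0)$beta_p$mean, 0.7,
               tolerance = 1e-6)
  expect_error(analytic_posterior(numeric(0), X[0, , drop = FALSE],
                                  pr0), "no observations")
  pr_ind <- prior_spec("group", 0, 1)
  expect_error(analytic_posterior(y, X, pr_ind), "unsupported|conjugate")
})

test_that("Gibbs draws agree with the conjugate oracle on random problems", {
  res <- evaluate_sampler_agreement(
    n_problems = 25, config = mcmc_config(4, 1500, 500, 1), seed = 2024)
  expect_gte(res$agreement_rate, 0.9)
})

test_that("summary statistics follow their definitions", {
  sym <- fake_posterior(c(seq(-1, -0.01, length.out = 500),
                          seq(0.01, 1, length.out = 500)))
  # ordered fake draws trip the split-R-hat screen by construction
  s <- suppressWarnings(summarize_posterior(sym))
  expect_equal(s$pd, 0.5)
  expect_false(s$altered)
  expect_equal(s$direction, "none")

  pos <- fake_posterior(runif(2000, 0.5, 1.5))
  sp <- summarize_posterior(pos)
  expect_equal(sp$pd, 1.0)
  expect_true(sp$altered)
  expect_equal(sp$direction, "up")
  expect_true(sp$ci_low <= sp$posterior_median &&
              sp$posterior_median <= sp$ci_high)

  expect_error(summarize_posterior(fake_posterior(rep(1, 2000))),
               "degenerate")
  expect_error(summarize_posterior(fake_posterior(rnorm(50))),
               "at least")
})

test_that("no-data Savage-Dickey limit returns BF10 of 1", {
  res <- evaluate_savage_dickey(n_toys = 2, seed = 31)
  expect_lt(abs(res$no_data_bf10 - 1), 0.10)
})

test_that("Jeffreys bins cut exactly at 1/10, 1/3, 3 and 10", {
  bf <- c(0.05, 1 / 10, 0.2, 1 / 3, 1, 3, 5, 10, 30)
  expect_equal(as.character(jeffreys_bin(bf)),
               c("strong_null", "strong_null", "moderate_null",
                 "moderate_null", "anecdotal", "anecdotal",
                 "moderate_alt", "moderate_alt", "strong_alt"))
})

test_that("altered compounds have pd above 0.975 up to draw resolution", {
  d <- make_autoscaled(n_per_group = 30, effects = c(0, 0.5, 1, -1, 0.2),
                       seed = 17)
  res <- run_bayes(d, config = mcmc_config(2, 1000, 500, seed = 4))
  tol <- 1 / sqrt(res$n_draws[1])
  expect_true(all(res$pd[res$altered] >= 0.975 - tol))
  # decision rule is exactly the CI-exclusion rule
  expect_equal(res$altered, res$ci_low > 0 | res$ci_high < 0)
  expect_equal(res$direction == "down",
               res$altered & res$posterior_median < 0)
})

test_that("widening the group prior cannot favor the alternative on null data", {
  set.seed(55)
  g <- rep(c(1, 0), each = 20)
  X <- cbind("(Intercept)" = 1, group = g)
  bf_narrow <- bf_wide <- numeric(30)
  for (i in 1:30) {
    y <- as.numeric(scale(rnorm(40)))
    for (w in c(1, 4)) {
      pr <- prior_spec(colnames(X), c(0, 0), c(2.5, w),
                       sigma_shape = 2, sigma_rate = 1)
      post <- sample_posterior(y, X, pr, mcmc_config(2, 1000, 500, seed = i))
      s <- suppressWarnings(summarize_posterior(post))
      if (w == 1) bf_narrow[i] <- s$bf10 else bf_wide[i] <- s$bf10
    }
  }
  expect_lt(mean(bf_wide), mean(bf_narrow))
})

test_that("per-compound seeding makes results subset-stable", {
  d <- make_autoscaled(n_per_group = 15, effects = c(0.3, 0, -0.5), seed = 6)
  cfg <- mcmc_config(2, 600, 200, seed = 10)
  full <- run_bayes(d, config = cfg)
  sub <- d
  sub$abundance <- sub$abundance[, c(1, 3)]
  sub$compounds <- sub$compounds[c(1, 3), ]
  part <- run_bayes(sub, config = cfg)
  expect_equal(part$posterior_median,
               full$posterior_median[c(1, 3)], tolerance = 1e-15)
})
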