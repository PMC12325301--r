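test_that("the default initialization carries the empirical values", {
  init <- gmm_init_default()
  expect_equal(init$means, c(0.15, 1.5, 4))
  expect_equal(init$sds, c(0.02, 0.1, 1.5))
  expect_equal(init$weights, c(0.45, 0.5, 0.05))
  expect_length(init$means, 3L)
  expect_equal(sum(init$weights), 1.0)
  expect_error(mixture_params(c(0, 1), c(1, 1), c(0.7, 0.2)), "sum to 1")
  expect_error(mixture_params(c(0, 1), c(1, -1), c(0.5, 0.5)), "positive")
})

test_that("posterior responsibilities are normalized and correct", {
  # K = 1: posteriors identically 1
  p1 <- mixture_params(2, 0.5, 1)
  expect_equal(responsibilities(c(-1, 0, 5), p1), matrix(1, 3, 1))
  # symmetric two-component mixture: sample at 0 splits 50/50
  p2 <- mixture_params(c(-2, 2), c(0.7, 0.7), c(0.5, 0.5))
  expect_equal(responsibilities(0, p2)[1, ], c(0.5, 0.5))
  # sample at the bright default mean is claimed by the bright component
  post <- responsibilities(4, gmm_init_default())
  expect_gt(post[1, 3], 0.99)
  # rows always sum to 1, even for extreme samples (log-domain stability)
  set.seed(31)
  x <- c(rnorm(50), 1e3, -1e3, 0.15, 4)
  rs <- rowSums(responsibilities(x, gmm_init_default()))
  expect_equal(rs, rep(1, length(x)), tolerance = 1e-9)
  expect_equal(nrow(responsibilities(numeric(0), gmm_init_default())), 0L)
})

test_that("EM increases the log-likelihood monotonically on random data", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(50:300, 1)
    x <- abs(rnorm(n, sample(1:4, 1), runif(1, 0.1, 2)))
    fit <- gmm_fit(x, tol = 1e-8, max_iter = 200)
    dll <- diff(fit$loglik_trace)
    expect_true(all(dll >= -1e-8), info = paste("seed", seed))
    expect_equal(sum(fit$params$weights), 1, tolerance = 1e-9)
  }
})

test_that("a single-component fit recovers the closed-form MLE", {
  set.seed(32)
  x <- rnorm(500, 1, 0.1)
  fit <- gmm_fit(x, init = mixture_params(0.5, 1, 1), tol = 1e-12,
                 max_iter = 100)
  expect_equal(fit$params$means, mean(x), tolerance = 1e-6)
  expect_equal(fit$params$sds, sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
  expect_equal(fit$params$weights, 1)
})

test_that("EM is deterministic and invariant to sample order", {
  set.seed(33)
  x <- c(rnorm(200, 0.15, 0.02), rnorm(200, 1.5, 0.1), rnorm(40, 4, 1.5))
  f1 <- gmm_fit(x)
  f2 <- gmm_fit(x)
  expect_identical(f1$params, f2$params)
  xp <- sample(x)
  f3 <- gmm_fit(xp)
  expect_equal(f3$params$means, f1$params$means, tolerance = 1e-12)
  expect_equal(f3$params$weights, f1$params$weights, tolerance = 1e-12)
  expect_equal(logLik(f3), logLik(f1), tolerance = 1e-12)
})

test_that("EM recovers parameters of data simulated at the default init", {
  set.seed(2024)
  n <- 30000
  init <- gmm_init_default()
  comp <- sample.int(3, n, replace = TRUE, prob = init$weights)
  x <- rnorm(n, init$means[comp], init$sds[comp])
  fit <- gmm_fit(x)
  expect_true(all(abs(fit$params$means - init$means) < 0.1))
  expect_true(all(abs(fit$params$weights - init$weights) < 0.03))
})

test_that("degenerate inputs engage the variance floor, not failure", {
  fit <- gmm_fit(c(1, 1), init = mixture_params(c(0.9, 1.1), c(0.1, 0.1),
                                                c(0.5, 0.5)))
  expect_equal(sum(fit$params$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$params$sds >= 1e-4))
  expect_true(fit$sd_clamped)
  expect_error(gmm_fit(c(1, 2), init = gmm_init_default()), "at least K")
})

test_that("EM agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(34)
  init <- gmm_init_default()
  comp <- sample.int(3, 2000, replace = TRUE, prob = init$weights)
  x <- rnorm(2000, init$means[comp], init$sds[comp])
  fit <- gmm_fit(x, tol = 1e-12, max_iter = 2000)
  ref <- mclust::em(modelName = "V", data = x,
                    parameters = list(pro = init$weights, mean = init$means,
                                      variance = list(modelName = "V", d = 1,
                                                      G = 3,
                                                      sigmasq = init$sds^2)),
                    control = mclust::emControl(tol = 1e-10, itmax = 2000))
  expect_equal(fit$loglik_trace[fit$n_iter], ref$loglik, tolerance = 1e-6)
  expect_equal(fit$params$means, as.numeric(ref$parameters$mean),
               tolerance = 1e-4)
})

test_that("hard assignment selects the brightest fitted component", {
  init <- gmm_init_default()
  expect_true(all(assign_cp(rep(4, 5), init)))
  expect_false(any(assign_cp(rep(0.15, 5), init)))
  expect_length(assign_cp(numeric(0), init), 0L)
  # the CP role follows the FITTED means even if component order swaps
  swapped <- mixture_params(c(4, 1.5, 0.15), c(1.5, 0.1, 0.02),
                            c(0.05, 0.5, 0.45))
  expect_equal(cp_component(swapped), 1L)
  expect_true(all(assign_cp(c(3.8, 4.2), swapped)))
  # equal-mean tie goes to the heavier component
  tied <- mixture_params(c(2, 2), c(0.5, 0.5), c(0.3, 0.7))
  expect_equal(cp_component(tied), 2L)
})
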