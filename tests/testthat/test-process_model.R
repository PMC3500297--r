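state_for <- function(m, Tn, alpha = rep(0, m), beta = rep(0, m),
                      eta = matrix(0, m, Tn), gamma = matrix(0, m, Tn)) {
  list(alpha = alpha, beta = beta, eta = eta, gamma = gamma)
}

test_that("linear predictor composes the additive log-mean", {
  st <- state_for(2, 5)
  expect_equal(linear_predictor(st, 1, 3), 0)       # all effects zero: mu = 1
  st$alpha[1] <- log(10); st$beta[1] <- 0.05
  expect_equal(linear_predictor(st, 1, 2, x_t = 20), log(10) + 1)
  st$eta[1, 2] <- 0.3; st$gamma[1, 2] <- -0.1
  expect_equal(linear_predictor(st, 1, 2), log(10) + 0.05 + 0.3 - 0.1)
  expect_equal(linear_predictor(st, 1, 2, spatial_on = FALSE,
                                temporal_on = FALSE), log(10) + 0.05)
  expect_error(linear_predictor(st, 3, 1), "out of range")
  expect_error(linear_predictor(st, 1, 9), "out of range")
})

test_that("simulated cell means agree with the ZINB mean formula", {
  set.seed(15)
  st <- state_for(1, 2, alpha = log(4), beta = 0.1,
                  eta = matrix(0.2, 1, 2), gamma = matrix(-0.3, 1, 2))
  lp <- linear_predictor(st, 1, 2)
  p <- 0.25
  y <- rzinb(10000, mu = exp(lp), size_n = 2, p_zero = p)
  expect_lt(abs(mean(y) - (1 - p) * exp(lp)) / ((1 - p) * exp(lp)), 0.05)
})

test_that("cumulative change is the endpoint difference of the fitted trend", {
  st <- state_for(3, 10, alpha = c(0, 1, 2), beta = c(0, 0.1, -0.2))
  expect_identical(cumulative_change(st, 1, 10), 0)   # flat trend
  # doubling from a unit baseline: change = 1
  st2 <- state_for(1, 11, alpha = 0, beta = log(2) / 10)
  expect_equal(cumulative_change(st2, 1, 11), 1)
  # endpoint-evaluation oracle for random parameters
  set.seed(16)
  for (rep in 1:20) {
    a <- runif(1, -1, 2); b <- runif(1, -0.1, 0.1); Tn <- sample(2:60, 1)
    st3 <- state_for(1, Tn, alpha = a, beta = b)
    expect_equal(cumulative_change(st3, 1, Tn),
                 exp(a + b * (Tn - 1)) - exp(a))
  }
  expect_error(cumulative_change(st, 5, 10), "out of range")
  expect_error(cumulative_change(st, 1, 0), "span_years")
})

test_that("segments within a cell are exchangeable for the likelihood", {
  set.seed(17)
  y <- rzinb(30, 4, 2, 0.2)
  mu <- rep(4, 30)
  perm <- sample(30)
  expect_identical(deviance_counts(y, mu, 2, 0.2, "zinb"),
                   deviance_counts(y[perm], mu[perm], 2, 0.2, "zinb"))
})

test_that("switching a field off equals conditioning it to zero", {
  set.seed(18)
  m <- 3; Tn <- 6
  st_off <- state_for(m, Tn, alpha = runif(m), beta = runif(m, -0.1, 0.1),
                      eta = matrix(rnorm(m * Tn), m, Tn))
  st_zero <- st_off; st_zero$eta <- matrix(0, m, Tn)
  lp_off <- sapply(seq_len(Tn), function(t)
    sapply(seq_len(m), function(j)
      linear_predictor(st_off, j, t, spatial_on = FALSE)))
  lp_zero <- sapply(seq_len(Tn), function(t)
    sapply(seq_len(m), function(j) linear_predictor(st_zero, j, t)))
  expect_identical(lp_off, lp_zero)
})

test_that("model specifications validate and expose the case-study grid", {
  sp <- model_spec("zinb", "both")
  expect_true(sp$spatial_on && sp$temporal_on)
  expect_false(model_spec("nb", "none")$spatial_on)
  expect_error(model_spec("zinb", "both", lam_mode = 1.2), "lam")
  expect_error(model_spec("zinb", "both", lam_mode = "wrong"), "lam_mode")
  expect_error(prior_config(tau_shape = -1), "positive")
  ps <- preset_specs("zinb")
  expect_named(ps, c("none", "spatial", "temporal", "both"))
  expect_identical(ps$temporal$data_model, "zinb")
  expect_false(ps$temporal$spatial_on)
  expect_true(ps$temporal$temporal_on)
})

test_that("a YAML or JSON config drives the model specification", {
  tmp <- withr::local_tempdir()
  yml <- file.path(tmp, "cfg.yaml")
  writeLines(c("data_model: nb", "effects: spatial", "lam_mode: 0.4",
               "priors:", "  beta_prec: 0.1"), yml)
  sp <- model_spec_from_config(yml)
  expect_identical(sp$data_model, "nb")
  expect_identical(sp$effects, "spatial")
  expect_equal(sp$lam_mode, 0.4)
  expect_equal(sp$priors$beta_prec, 0.1)
  jsn <- file.path(tmp, "cfg.json")
  jsonlite::write_json(list(data_model = "zinb", effects = "both"), jsn,
                       auto_unbox = TRUE)
  expect_identical(model_spec_from_config(jsn)$effects, "both")
})
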