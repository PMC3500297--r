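small_sim <- function(seed = 31, m = 4, Tn = 8, segs = 6) {
  simulate_dataset(sim_config(
    m = m, T_occasions = Tn, segments_per_stratum = segs,
    alpha_range = c(log(3), log(8)), beta_range = c(-0.05, 0.05),
    tau_eta = 10, lam = 0.6, tau_gamma = 4, rho = 0.5,
    p_zero = 0.15, theta = log(5), seed = seed))
}

test_that("degenerate designs and bad inputs are rejected", {
  sim <- small_sim()
  rec1 <- sim$records[sim$records$year_index == 1, ]
  expect_error(fit_model(rec1, sim$graph), "two occasions")
  bad <- sim$records; bad$stratum[1] <- "nope"
  expect_error(fit_model(bad, sim$graph), "absent from the graph")
  expect_error(fit_model(sim$records, sim$graph, chains = 1), "2 chains")
  gi <- suppressWarnings(build_proximity_matrix(rbind(c(0, 0), c(1, 0),
                                                      c(50, 0)), 2))
  rec <- sim$records; rec$stratum <- rep(gi$stratum_ids,
                                         length.out = nrow(rec))
  expect_error(fit_model(rec, gi, model_spec("zinb", "both")), "connected")
})

test_that("fits are reproducible given a seed", {
  sim <- small_sim()
  f1 <- fit_model(sim$records, sim$graph, model_spec("zinb", "both"),
                  iterations = 60, warmup = 60, chains = 2, seed = 5,
                  diagnostics = "none")
  f2 <- fit_model(sim$records, sim$graph, model_spec("zinb", "both"),
                  iterations = 60, warmup = 60, chains = 2, seed = 5,
                  diagnostics = "none")
  expect_identical(f1$draws$hyper, f2$draws$hyper)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$deviance_draws, f2$deviance_draws)
})

test_that("posterior matches an independent JAGS oracle on a tiny NB fit", {
  sim <- simulate_dataset(sim_config(
    m = 3, T_occasions = 8, segments_per_stratum = 12,
    alpha_range = c(log(2), log(8)), beta_range = c(-0.1, 0.1),
    theta = log(3), data_model = "nb", effects = "none", seed = 11))
  fit <- fit_model(sim$records, sim$graph, model_spec("nb", "none"),
                   iterations = 3000, warmup = 1000, chains = 2, seed = 5,
                   diagnostics = "none")
  s <- fit$summary

  library(rjags)
  jm <- "model{
    for (i in 1:N) {
      y[i] ~ dnegbin(pnb[i], n)
      pnb[i] <- n / (n + mu[i])
      log(mu[i]) <- alpha[j[i]] + beta[j[i]] * x[i]
    }
    for (s in 1:m) { alpha[s] ~ dnorm(0, 0.001); beta[s] ~ dnorm(0, 0.001) }
    theta ~ dnorm(0, 0.01); n <- exp(theta)
  }"
  d <- list(y = sim$records$count,
            j = match(sim$records$stratum, sim$graph$stratum_ids),
            x = sim$records$year_index - 1, N = nrow(sim$records), m = 3)
  mod <- jags.model(textConnection(jm), data = d, n.chains = 2, quiet = TRUE,
                    inits = list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = 99))
  update(mod, 1500, progress.bar = "none")
  samp <- coda.samples(mod, c("alpha", "beta", "theta"), n.iter = 4000,
                       progress.bar = "none")
  js <- summary(samp)$statistics
  ord <- c(paste0("alpha[", 1:3, "]"), paste0("beta[", 1:3, "]"), "theta")
  mine <- s[match(c(paste0("alpha[S", 1:3, "]"), paste0("beta[S", 1:3, "]"),
                    "theta"), s$parameter), ]
  # agreement within a few Monte-Carlo standard errors of both samplers
  tol <- 4 * sqrt(js[ord, "Naive SE"]^2 * 20 + (mine$sd / sqrt(200))^2)
  expect_true(all(abs(mine$mean - js[ord, "Mean"]) < pmax(tol, 0.02)))
  expect_true(all(abs(mine$sd - js[ord, "SD"]) / js[ord, "SD"] < 0.2))
})

test_that("the sampler and the R deviance are the same likelihood", {
  sim <- small_sim(seed = 33)
  fit <- fit_model(sim$records, sim$graph, model_spec("zinb", "both"),
                   iterations = 40, warmup = 100, chains = 2, seed = 9,
                   diagnostics = "none")
  Tn <- fit$T
  j_idx <- match(sim$records$stratum, fit$stratum_ids)
  cell <- (j_idx - 1L) * Tn + sim$records$year_index
  for (k in c(1, 25, 80)) {
    lp_cells <- rep(fit$draws$alpha[k, ], each = Tn) +
      rep(fit$draws$beta[k, ], each = Tn) * rep(fit$x, fit$m) +
      fit$draws$eta[k, ] + fit$draws$gamma[k, ]
    dev_r <- deviance_counts(sim$records$count, exp(lp_cells)[cell],
                             exp(fit$draws$hyper[k, "theta"]),
                             fit$draws$hyper[k, "p_zero"], "zinb")
    expect_equal(dev_r, fit$deviance_draws[k], tolerance = 1e-8)
  }
})

test_that("tight priors dominate flat data (prior-dominance limit)", {
  sim <- simulate_dataset(sim_config(
    m = 3, T_occasions = 8, segments_per_stratum = 20,
    alpha_range = c(log(5), log(5)), beta_range = c(0, 0),
    tau_eta = 1e8, tau_gamma = 1e8, rho = 0, lam = 0, p_zero = 0,
    theta = log(20), data_model = "nb", effects = "none", seed = 35))
  pr <- prior_config(beta_mean = 0, beta_prec = 1e8)
  fit <- fit_model(sim$records, sim$graph,
                   model_spec("nb", "none", priors = pr),
                   iterations = 300, warmup = 300, chains = 2, seed = 3,
                   diagnostics = "none")
  b <- fit$summary[grepl("^beta", fit$summary$parameter), ]
  expect_lt(max(abs(b$mean)), 5e-4)
  expect_lt(max(b$sd), 5e-4)
})

test_that("different seeds agree within Monte-Carlo error", {
  sim <- small_sim(seed = 36, m = 5, Tn = 10, segs = 8)
  fits <- lapply(c(101, 202), function(sd)
    fit_model(sim$records, sim$graph, model_spec("zinb", "both"),
              iterations = 800, warmup = 800, chains = 2, seed = sd))
  for (par in c("tau_gamma", "rho", "p_zero", "theta")) {
    rows <- lapply(fits, function(f) f$summary[f$summary$parameter == par, ])
    mcse <- sqrt(sum(vapply(rows, function(r) r$sd^2 / max(r$ess, 4),
                            numeric(1))))
    expect_lt(abs(rows[[1]]$mean - rows[[2]]$mean), 3.5 * mcse)
  }
})

test_that("DIC components are internally consistent", {
  sim <- small_sim(seed = 37)
  fit <- fit_model(sim$records, sim$graph, model_spec("zinb", "both"),
                   iterations = 150, warmup = 150, chains = 2, seed = 2,
                   diagnostics = "none")
  expect_equal(unname(fit$dic["DIC"]),
               unname(fit$dic["Dbar"] + fit$dic["pD"]))
  re <- compute_dic(fit)
  expect_equal(re, fit$dic)
  broken <- fit; broken$deviance_draws <- numeric(0)
  expect_error(compute_dic(broken), "deviance trace")
})

test_that("model comparison is deterministic and survives failed fits", {
  sim <- small_sim(seed = 38)
  specs <- list(a = model_spec("zinb", "temporal"),
                b = model_spec("zinb", "temporal"))
  tab <- compare_models(sim$records, sim$graph, specs,
                        iterations = 100, warmup = 100, chains = 2, seed = 4,
                        diagnostics = "none")
  expect_equal(tab$DIC[tab$model == "a"], tab$DIC[tab$model == "b"])
  expect_equal(tab$dDIC, c(0, 0))
  # an invalid spec is reported per-row, the comparison proceeds
  rec1 <- sim$records
  specs2 <- list(none = model_spec("nb", "none"),
                 both = model_spec("nb", "both"))
  gi <- sim$graph; gi$isolated <- gi$stratum_ids[1]   # force one failure
  tab2 <- compare_models(rec1, gi, specs2, iterations = 80, warmup = 80,
                         chains = 2, seed = 4, diagnostics = "none")
  expect_true(any(!is.na(tab2$error)))
  expect_true(any(is.finite(tab2$DIC)))
})

test_that("fit results serialise to summary, DIC and settings files", {
  sim <- small_sim(seed = 39)
  fit <- fit_model(sim$records, sim$graph, model_spec("nb", "temporal"),
                   iterations = 60, warmup = 60, chains = 2, seed = 8,
                   diagnostics = "none")
  tmp <- withr::local_tempdir()
  write_fit(fit, tmp)
  s <- read.csv(file.path(tmp, "summary.csv"))
  expect_true(all(c("parameter", "mean", "q2.5", "q97.5") %in% names(s)))
  dic <- jsonlite::read_json(file.path(tmp, "dic.json"))
  expect_equal(dic$DIC, unname(fit$dic["DIC"]))
})
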