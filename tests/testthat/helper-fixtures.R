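# Shared fixtures built in code.

# Independent O(m^2) brute-force neighbourhood construction, kept deliberately
# separate from the package implementation (double loop, no dist()).
brute_force_graph <- function(centroids, threshold) {
  m <- nrow(centroids)
  W <- matrix(0, m, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (j != k) {
        dd <- sqrt(sum((centroids[j, ] - centroids[k, ])^2))
        if (dd <= threshold) W[j, k] <- 1
      }
    }
  }
  list(W = W, D = diag(rowSums(W), m))
}

# A minimal pt_fit-shaped object with user-supplied draws, for testing the
# reporting layer without running MCMC.
fake_fit <- function(alpha_draws, beta_draws, hyper_draws = NULL,
                     eta_draws = NULL, gamma_draws = NULL,
                     Tn = 10L, spec = model_spec("zinb", "none")) {
  m <- ncol(beta_draws)
  nd <- nrow(beta_draws)
  ids <- paste0("S", seq_len(m))
  if (is.null(hyper_draws)) {
    hyper_draws <- matrix(rep(c(10, 10, 0.5, 0.5, 0, 0), each = nd), nrow = nd)
  }
  colnames(hyper_draws) <- c("tau_eta", "tau_gamma", "rho", "lam",
                             "p_zero", "theta")
  draws <- list(alpha = alpha_draws, beta = beta_draws, hyper = hyper_draws)
  if (!is.null(eta_draws)) draws$eta <- eta_draws
  if (!is.null(gamma_draws)) draws$gamma <- gamma_draws
  qs <- function(mm) t(apply(mm, 2, stats::quantile,
                             probs = c(0.025, 0.5, 0.975), names = FALSE))
  par_mat <- cbind(alpha_draws, beta_draws)
  colnames(par_mat) <- c(paste0("alpha[", ids, "]"), paste0("beta[", ids, "]"))
  q <- qs(par_mat)
  summ <- data.frame(parameter = colnames(par_mat), mean = colMeans(par_mat),
                     sd = apply(par_mat, 2, stats::sd),
                     q2.5 = q[, 1], q50 = q[, 2], q97.5 = q[, 3],
                     ess = NA_real_, rhat = NA_real_,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(draws = draws, summary = summ,
                 deviance_draws = rep(0, nd),
                 dic = c(Dbar = 0, pD = 0, DIC = 0),
                 dhat_inputs = NULL,
                 stratum_ids = ids, m = m, T = Tn, x = seq_len(Tn) - 1,
                 spec = spec,
                 settings = list(iterations = nd, warmup = 0, chains = 1,
                                 thin = 1, seed = 1),
                 n_records = 0L), class = "pt_fit")
}

# The frozen reduced-scale recovery design (see the methods vignette): the
# latent fields dominate segment-level noise and the spatial field is much
# weaker than the temporal one, mirroring the survey case study.
recovery_config <- function(seed) {
  sim_config(m = 8, T_occasions = 15, segments_per_stratum = 10,
             alpha_range = c(log(5), log(15)), beta_range = c(-0.04, 0.04),
             tau_eta = 20, lam = 0.7, tau_gamma = 2, rho = 0.6,
             p_zero = 0.15, theta = log(10), seed = seed)
}
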