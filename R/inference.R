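#' Fit the hierarchical spatio-temporal count model by MCMC
#'
#' Approximates the joint posterior of the stratum intercepts and trends, the
#' CAR spatial field, the AR(1) temporal residuals and all hyperparameters,
#' using an adaptive Metropolis-within-Gibbs sampler with conjugate Gamma
#' updates for the two field precisions. Segment counts are collapsed to
#' per-(stratum, year) sufficient statistics, so cost per sweep is O(mT)
#' regardless of the number of segments.
#'
#' @param records count records (data frame with `stratum`, `year_index`,
#'   `count`), e.g. from [read_counts()] or [simulate_dataset()].
#' @param graph a `strata_graph` covering every stratum in `records`.
#' @param spec a [model_spec()].
#' @param iterations kept iterations per chain.
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param chains number of chains (>= 2, for split-Rhat diagnostics).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param diagnostics `"hyper"` (effective size and split-Rhat for the
#'   intercepts, slopes and hyperparameters only), `"all"`, or `"none"`.
#' @return an object of class `pt_fit`: merged posterior draws, a summary
#'   table (`mean`, `sd`, `q2.5`, `q50`, `q97.5`, `ess`, `rhat` per
#'   parameter), the per-draw deviance trace, DIC components, and the inputs
#'   needed to re-evaluate the deviance at the posterior means.
#' @export
fit_model <- function(records, graph, spec = model_spec(),
                      iterations = 1000L, warmup = 1000L, chains = 4L,
                      thin = 1L, seed = 20121116L,
                      diagnostics = c("hyper", "all", "none")) {
  stopifnot(inherits(graph, "strata_graph"), inherits(spec, "model_spec"))
  diagnostics <- match.arg(diagnostics)
  if (chains < 2L) stop("at least 2 chains are required for diagnostics")
  if (iterations < 2L || warmup < 0L || thin < 1L) stop("invalid sampler settings")
  check_counts(records$count)

  ids <- graph$stratum_ids
  j_idx <- match(as.character(records$stratum), ids)
  if (anyNA(j_idx)) {
    stop("records reference strata absent from the graph: ",
         paste(unique(records$stratum[is.na(j_idx)]), collapse = ", "))
  }
  Tn <- max(records$year_index)
  if (Tn < 2L) stop("at least two occasions are required to define a trend")
  if (min(records$year_index) < 1L) stop("year_index must be >= 1")
  m <- length(ids)
  x <- as.numeric(seq_len(Tn) - 1L)

  if (spec$spatial_on && length(graph$isolated) > 0L) {
    stop("spatial effect requires a connected graph; isolated strata: ",
         paste(graph$isolated, collapse = ", "))
  }

  # per-cell sufficient statistics (cell = (j-1)*T + t, flattened stratum-major)
  cell <- (j_idx - 1L) * Tn + records$year_index
  nc <- m * Tn
  y <- as.integer(records$count)
  nzero <- tabulate(cell[y == 0L], nbins = nc)
  npos <- tabulate(cell[y > 0L], nbins = nc)
  sumy <- numeric(nc)
  agg <- rowsum(as.numeric(y), cell)
  sumy[as.integer(rownames(agg))] <- agg[, 1L]
  tab <- table(y[y > 0L])
  hist_y <- as.integer(names(tab))
  hist_cnt <- as.integer(tab)
  const_lg <- sum(lgamma(y + 1))

  # graph arrays for the sampler
  if (spec$spatial_on) {
    W <- graph$W
    d <- rowSums(W)
    adj <- lapply(seq_len(m), function(j) which(W[j, ] == 1) - 1L)
    adj_ptr <- c(0L, cumsum(lengths(adj)))
    adj <- as.integer(unlist(adj))
    sc <- 1 / sqrt(d)
    wev <- eigen(sc * t(sc * W), symmetric = TRUE, only.values = TRUE)$values
  } else {
    d <- rep(1, m); adj <- integer(0); adj_ptr <- integer(m + 1L)
    wev <- rep(0, m)
  }

  lam_est <- identical(spec$lam_mode, "estimated")
  lam_init <- if (lam_est) 0.5 else as.numeric(spec$lam_mode)

  data_list <- list(m = m, T = Tn, nzero = nzero, npos = npos, sumy = sumy,
                    hist_y = hist_y, hist_cnt = hist_cnt,
                    const_lgamma_y1 = const_lg, x = x)
  graph_list <- list(adj = adj, adj_ptr = as.integer(adj_ptr), d = as.numeric(d),
                     wev = as.numeric(wev))
  flags <- list(spatial_on = spec$spatial_on, temporal_on = spec$temporal_on,
                zinb = spec$data_model == "zinb", lam_est = lam_est)
  priors <- unclass(spec$priors)

  # empirical intercept starting values
  cellmean <- sumy / pmax(nzero + npos, 1L)
  a_emp <- vapply(seq_len(m), function(j) {
    mu0 <- mean(cellmean[((j - 1L) * Tn + 1L):(j * Tn)])
    log(max(mu0, 0.05))
  }, numeric(1L))
  xbar <- mean(x)

  run_chain <- function(ch) {
    set.seed(seed + ch - 1L)
    init <- list(
      ac = a_emp + stats::rnorm(m, 0, 0.1),
      b = stats::rnorm(m, 0, 0.002),
      # start the fields away from exactly zero: a zero field would make the
      # first conjugate precision draw enormous and trap the sampler in the
      # "collapsed field" mode of the funnel
      eta = stats::rnorm(nc, 0, 0.2), gamma = stats::rnorm(nc, 0, 0.2),
      tau_eta = exp(log(20) + stats::rnorm(1, 0, 0.2)),
      tau_gamma = exp(log(20) + stats::rnorm(1, 0, 0.2)),
      rho = 0.3, lam = lam_init,
      p_zero = 0.05, theta = stats::rnorm(1, 0, 0.1)
    )
    out <- .sampler_run(data_list, graph_list, flags, priors, init,
                        as.integer(warmup), as.integer(iterations),
                        as.integer(thin))
    if (!all(is.finite(out$deviance))) {
      stop("non-finite deviance encountered in chain ", ch,
           "; check the data and initial values")
    }
    out
  }
  chains_out <- lapply(seq_len(chains), run_chain)

  merge_mat <- function(name) do.call(rbind, lapply(chains_out, `[[`, name))
  draws <- list(alpha = merge_mat("alpha"), beta = merge_mat("beta"),
                hyper = merge_mat("hyper"))
  colnames(draws$alpha) <- paste0("alpha[", ids, "]")
  colnames(draws$beta) <- paste0("beta[", ids, "]")
  colnames(draws$hyper) <- c("tau_eta", "tau_gamma", "rho", "lam",
                             "p_zero", "theta")
  if (spec$spatial_on) {
    draws$eta <- merge_mat("eta")
    colnames(draws$eta) <- paste0("eta[", rep(ids, each = Tn), ",",
                                  rep(seq_len(Tn), m), "]")
  }
  if (spec$temporal_on) {
    draws$gamma <- merge_mat("gamma")
    colnames(draws$gamma) <- paste0("gamma[", rep(ids, each = Tn), ",",
                                    rep(seq_len(Tn), m), "]")
  }
  dev <- unlist(lapply(chains_out, `[[`, "deviance"))
  mu_bar <- Reduce(`+`, lapply(chains_out, `[[`, "mu_bar")) / chains

  # which hyperparameters are active in this configuration
  hyp_active <- c(tau_eta = spec$spatial_on, tau_gamma = spec$temporal_on,
                  rho = spec$temporal_on, lam = spec$spatial_on && lam_est,
                  p_zero = spec$data_model == "zinb", theta = TRUE)

  par_mat <- cbind(draws$alpha, draws$beta,
                   draws$hyper[, names(hyp_active)[hyp_active], drop = FALSE])
  if (diagnostics == "all") {
    if (spec$spatial_on) par_mat <- cbind(par_mat, draws$eta)
    if (spec$temporal_on) par_mat <- cbind(par_mat, draws$gamma)
  }
  nk <- iterations
  summ <- summarise_draws(par_mat, chains, nk,
                          with_diag = diagnostics != "none")
  # append field summaries without diagnostics when not requested
  if (diagnostics == "hyper") {
    extra <- NULL
    if (spec$spatial_on) extra <- cbind(extra, draws$eta)
    if (spec$temporal_on) extra <- cbind(extra, draws$gamma)
    if (!is.null(extra)) {
      s2 <- summarise_draws(extra, chains, nk, with_diag = FALSE)
      summ <- rbind(summ, s2)
    }
  }

  # deviance at the posterior means of the likelihood inputs
  theta_bar <- mean(draws$hyper[, "theta"])
  p_bar <- if (spec$data_model == "zinb") mean(draws$hyper[, "p_zero"]) else 0
  mu_rec <- mu_bar[cell]
  dhat <- deviance_counts(y, mu_rec, exp(theta_bar), p_bar,
                          model = spec$data_model)
  dbar <- mean(dev)
  pd <- dbar - dhat
  if (pd < 0) warning("negative pD (", format(pd), "): Dhat exceeds the mean ",
                      "deviance; the posterior may be poorly behaved")

  structure(list(
    draws = draws, summary = summ, deviance_draws = dev,
    dic = c(Dbar = dbar, pD = pd, DIC = dbar + pd),
    dhat_inputs = list(y = y, cell = cell, mu_bar = mu_bar,
                       p_bar = p_bar, theta_bar = theta_bar),
    stratum_ids = ids, m = m, T = Tn, x = x, spec = spec,
    settings = list(iterations = iterations, warmup = warmup,
                    chains = chains, thin = thin, seed = seed),
    n_records = length(y)
  ), class = "pt_fit")
}

#' @export
print.pt_fit <- function(x, ...) {
  cat("pt_fit:", toupper(x$spec$data_model), "data model, effects:",
      x$spec$effects, "\n")
  cat("  ", x$m, "strata x", x$T, "occasions,", x$n_records, "records\n")
  cat("  ", x$settings$chains, "chains x", x$settings$iterations,
      "kept iterations (warmup", x$settings$warmup, ")\n")
  cat("  DIC:", round(x$dic["DIC"], 1), "(Dbar", round(x$dic["Dbar"], 1),
      ", pD", round(x$dic["pD"], 1), ")\n")
  hy <- x$summary[x$summary$parameter %in%
                    c("rho", "tau_eta", "tau_gamma", "p_zero", "theta", "lam"), ]
  if (nrow(hy)) {
    cat("  hyperparameters:\n")
    print(hy[, c("parameter", "mean", "sd", "q2.5", "q97.5", "rhat")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

summarise_draws <- function(par_mat, chains, n_keep, with_diag = TRUE) {
  qs <- t(apply(par_mat, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  out <- data.frame(
    parameter = colnames(par_mat),
    mean = colMeans(par_mat),
    sd = apply(par_mat, 2L, stats::sd),
    q2.5 = qs[, 1L], q50 = qs[, 2L], q97.5 = qs[, 3L],
    ess = NA_real_, rhat = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (with_diag) {
    for (i in seq_len(ncol(par_mat))) {
      per_chain <- lapply(seq_len(chains), function(ch) {
        par_mat[((ch - 1L) * n_keep + 1L):(ch * n_keep), i]
      })
      out$ess[i] <- sum(vapply(per_chain, function(v)
        as.numeric(coda::effectiveSize(v)), numeric(1L)))
      out$rhat[i] <- split_rhat(per_chain)
    }
  }
  out
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half; the standard between/within variance ratio
#' is computed over the resulting 2C sequences. Returns 1 for a parameter
#' with zero variance.
#'
#' @param chains_list list of numeric vectors, one per chain.
#' @export
split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(v) {
    n2 <- floor(length(v) / 2L)
    list(v[seq_len(n2)], v[(length(v) - n2 + 1L):length(v)])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  xs <- vapply(halves, function(v) mean(v[seq_len(n)]), numeric(1L))
  s2 <- vapply(halves, function(v) stats::var(v[seq_len(n)]), numeric(1L))
  W <- mean(s2)
  B <- n * stats::var(xs)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' DIC components of a fitted model
#'
#' `Dbar` is the posterior mean deviance; `Dhat` the deviance re-evaluated at
#' the posterior means of every quantity entering the likelihood (the
#' per-record mean, the zero-inflation probability and the log size);
#' `pD = Dbar - Dhat` and `DIC = Dbar + pD`. Negative `pD` is reported with a
#' warning, never clipped.
#'
#' @param result a `pt_fit` from [fit_model()].
#' @return named vector `c(Dbar, pD, DIC)`.
#' @export
compute_dic <- function(result) {
  if (is.null(result$deviance_draws) || !length(result$deviance_draws)) {
    stop("deviance trace is missing")
  }
  di <- result$dhat_inputs
  dhat <- deviance_counts(di$y, di$mu_bar[di$cell], exp(di$theta_bar),
                          di$p_bar, model = result$spec$data_model)
  dbar <- mean(result$deviance_draws)
  pd <- dbar - dhat
  if (pd < 0) warning("negative pD (", format(pd), ")")
  c(Dbar = dbar, pD = pd, DIC = dbar + pd)
}

#' Fit and rank several model specifications by DIC
#'
#' @param records,graph as in [fit_model()].
#' @param specs named list of [model_spec()] objects (>= 2).
#' @param ... sampler settings passed to [fit_model()].
#' @return data frame `(model, Dbar, pD, DIC, dDIC, error)` sorted by DIC;
#'   rows for failed fits carry the error message and NA values.
#' @export
compare_models <- function(records, graph, specs, ...) {
  if (length(specs) < 2L) stop("at least two model specifications are required")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("model", seq_along(specs))
  }
  rows <- lapply(names(specs), function(nm) {
    res <- tryCatch(fit_model(records, graph, specs[[nm]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(model = nm, Dbar = NA_real_, pD = NA_real_, DIC = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      d <- res$dic
      data.frame(model = nm, Dbar = d[["Dbar"]], pD = d[["pD"]],
                 DIC = d[["DIC"]], error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$DIC), ]
  tab$dDIC <- tab$DIC - min(tab$DIC, na.rm = TRUE)
  rownames(tab) <- NULL
  tab[, c("model", "Dbar", "pD", "DIC", "dDIC", "error")]
}

#' The four case-study random-effect configurations as named presets
#'
#' @param data_model `"zinb"` or `"nb"`.
#' @param ... passed to [model_spec()] (e.g. `lam_mode`, `priors`).
#' @return named list of four [model_spec()] objects:
#'   `none`, `spatial`, `temporal`, `both`.
#' @export
preset_specs <- function(data_model = "zinb", ...) {
  effects <- c("none", "spatial", "temporal", "both")
  stats::setNames(lapply(effects, function(e)
    model_spec(data_model = data_model, effects = e, ...)), effects)
}

#' Serialise a fitted model to a directory
#'
#' Writes `summary.csv`, `dic.json` and `settings.json`.
#'
#' @param result a `pt_fit`.
#' @param dir output directory.
#' @export
write_fit <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(result$dic), file.path(dir, "dic.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
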