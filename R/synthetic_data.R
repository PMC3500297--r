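#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the scale and design of the May Breeding Pair Survey case
#' study: 52 strata, 53 annual occasions, around 50 segments per stratum per
#' year (over 2500 per year overall), counts of breeding pairs per 28.8 km
#' segment that are overdispersed with excess zeros, a spatially correlated
#' stratum field and temporally autocorrelated stratum residuals. The
#' magnitudes of the default hyperparameters follow the case study's reported
#' estimates where available (weak spatial field, moderate temporal field,
#' small zero-inflation), with first-year mean counts of a fraction of a pair
#' to a couple of pairs per segment.
#'
#' @param m number of strata (>= 2).
#' @param T_occasions number of annual occasions (>= 2).
#' @param segments_per_stratum segments per stratum per year in the balanced
#'   design (single integer). Ignored when `unbalanced = TRUE`.
#' @param unbalanced if `TRUE`, each stratum's yearly segment count is the sum
#'   over `transects_per_stratum` transects of Uniform{1..35} segments,
#'   mimicking the survey's 1-35 segments per transect.
#' @param transects_per_stratum transects per stratum in unbalanced mode.
#' @param centroid_layout `"random"` (uniform in a box scaled to hold m
#'   strata), `"grid"`, or a user-supplied m x 2 matrix.
#' @param alpha_range range of stratum first-year log mean counts (uniform).
#' @param beta_range range of stratum per-year log-scale trends (uniform).
#' @param tau_eta,lam CAR precision multiplier and dependence of the spatial
#'   field.
#' @param tau_gamma,rho innovation precision and autocorrelation of the
#'   AR(1) temporal residuals.
#' @param p_zero zero-inflation probability (used when `data_model="zinb"`).
#' @param theta log of the negative binomial size parameter.
#' @param data_model `"zinb"` or `"nb"`.
#' @param effects which random fields enter the generative mean:
#'   `"both"`, `"spatial"`, `"temporal"` or `"none"`.
#' @param gamma_center_weight soft sum-to-zero weight on each temporal
#'   residual series; keep equal to the fitting prior's
#'   `gamma_center_weight` so the generative and fitted priors coincide.
#' @param base_year calendar year of occasion 1.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(m = 52L, T_occasions = 53L,
                       segments_per_stratum = 50L,
                       unbalanced = FALSE, transects_per_stratum = 4L,
                       centroid_layout = "random",
                       alpha_range = c(log(0.3), log(2)),
                       beta_range = c(-0.03, 0.03),
                       tau_eta = 80, lam = 0.7,
                       tau_gamma = 12, rho = 0.5,
                       p_zero = 0.02, theta = 0,
                       data_model = c("zinb", "nb"),
                       effects = c("both", "none", "spatial", "temporal"),
                       gamma_center_weight = 10,
                       base_year = 1957L, seed = 1L) {
  data_model <- match.arg(data_model)
  effects <- match.arg(effects)
  stopifnot(m >= 2L, T_occasions >= 2L, segments_per_stratum >= 1L,
            transects_per_stratum >= 1L,
            tau_eta > 0, lam >= 0, lam < 1,
            tau_gamma > 0, abs(rho) < 1,
            p_zero >= 0, p_zero <= 1,
            length(alpha_range) == 2L, length(beta_range) == 2L,
            gamma_center_weight >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a survey dataset from the full generative model
#'
#' Draws stratum centroids, builds the neighbourhood graph at the smallest
#' all-connected threshold, draws stratum intercepts/slopes and the latent
#' spatial (CAR, independent per year) and temporal (AR(1) per stratum)
#' fields, forms each stratum-year mean through [linear_predictor()], and
#' draws segment counts from the chosen data model. Ground truth is returned
#' alongside the records so recovery tests never re-derive it.
#'
#' @param config a [sim_config()].
#' @return list with `records` (data frame `segment,stratum,year,year_index,
#'   count`), `graph` (a `strata_graph`), and `truth` (true latent state,
#'   hyperparameters and the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- as.integer(config$m); Tn <- as.integer(config$T_occasions)

  centroids <- make_centroids(config$centroid_layout, m)
  thr <- min_connecting_threshold(centroids)
  graph <- build_proximity_matrix(centroids, thr)
  if (length(graph$isolated) > 0L) {
    stop("disconnected graph at chosen threshold; use min_connecting_threshold")
  }

  alpha <- stats::runif(m, config$alpha_range[1], config$alpha_range[2])
  beta <- stats::runif(m, config$beta_range[1], config$beta_range[2])
  spatial_on <- config$effects %in% c("spatial", "both")
  temporal_on <- config$effects %in% c("temporal", "both")
  eta <- if (spatial_on) t(sample_car(graph, config$tau_eta, config$lam, n = Tn))
         else matrix(0, m, Tn)
  gamma <- if (temporal_on) {
    simulate_ar1(config$rho, config$tau_gamma, Tn, n_series = m,
                 center_weight = config$gamma_center_weight)
  } else matrix(0, m, Tn)

  n_seg <- if (config$unbalanced) {
    vapply(seq_len(m), function(j)
      sum(sample(1:35, config$transects_per_stratum, replace = TRUE)), integer(1L))
  } else rep(as.integer(config$segments_per_stratum), m)

  state <- list(alpha = alpha, beta = beta, eta = eta, gamma = gamma)
  size_n <- exp(config$theta)
  pz <- if (config$data_model == "zinb") config$p_zero else 0

  recs <- vector("list", m)
  for (j in seq_len(m)) {
    lp <- vapply(seq_len(Tn), function(t)
      linear_predictor(state, j, t, spatial_on = spatial_on,
                       temporal_on = temporal_on), numeric(1L))
    mu <- exp(lp)
    k <- n_seg[j]
    counts <- rzinb(k * Tn, mu = rep(mu, each = k), size_n = size_n, p_zero = pz)
    recs[[j]] <- data.frame(
      segment = rep(paste0(graph$stratum_ids[j], "_seg", seq_len(k)), times = Tn),
      stratum = graph$stratum_ids[j],
      year = rep(config$base_year + seq_len(Tn) - 1L, each = k),
      year_index = rep(seq_len(Tn), each = k),
      count = counts,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  truth <- list(
    alpha = alpha, beta = beta, eta = eta, gamma = gamma,
    tau_eta = config$tau_eta, lam = config$lam,
    tau_gamma = config$tau_gamma, rho = config$rho,
    p_zero = pz, theta = config$theta,
    effects = config$effects, data_model = config$data_model,
    threshold = thr, seed = config$seed, config = unclass(config)
  )
  list(records = records, graph = graph, truth = truth)
}

make_centroids <- function(layout, m) {
  if (is.matrix(layout) || is.data.frame(layout)) {
    cc <- as.matrix(layout)
    if (nrow(cc) != m || ncol(cc) != 2L) stop("user centroids must be m x 2")
    return(cc)
  }
  # box side scaled with sqrt(m) so average density is layout-independent
  side <- 5 * sqrt(m)
  if (identical(layout, "random")) {
    cbind(x = stats::runif(m, 0, side), y = stats::runif(m, 0, side))
  } else if (identical(layout, "grid")) {
    k <- ceiling(sqrt(m))
    g <- expand.grid(x = seq_len(k), y = seq_len(k))[seq_len(m), ]
    as.matrix(g) * side / k
  } else stop("unknown centroid layout")
}

#' Write a simulated dataset to a directory
#'
#' Writes `counts.csv` (`segment,stratum,year,count`), `centroids.csv`
#' (`stratum,x,y`) and `truth.json` (all true parameters including the seed).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$records[, c("segment", "stratum", "year", "count")],
                   file.path(dir, "counts.csv"), row.names = FALSE)
  cents <- data.frame(stratum = sim$graph$stratum_ids,
                      x = sim$graph$centroids[, 1],
                      y = sim$graph$centroids[, 2])
  utils::write.csv(cents, file.path(dir, "centroids.csv"), row.names = FALSE)
  tr <- sim$truth
  tr$eta <- as.vector(tr$eta); tr$gamma <- as.vector(tr$gamma)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
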