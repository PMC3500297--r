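#' Model specification: data model, random-effect configuration, priors
#'
#' The four random-effect configurations compared in the case study are
#' `"none"`, `"spatial"`, `"temporal"` and `"both"`; each can be paired with
#' the `"nb"` or `"zinb"` data model.
#'
#' @param data_model `"nb"` or `"zinb"`.
#' @param effects one of `"none"`, `"spatial"`, `"temporal"`, `"both"`.
#' @param lam_mode `"estimated"`, or a fixed numeric value in `[0, 1)` for
#'   the CAR dependence parameter.
#' @param priors a [prior_config()].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(data_model = c("zinb", "nb"),
                       effects = c("both", "none", "spatial", "temporal"),
                       lam_mode = "estimated",
                       priors = prior_config()) {
  data_model <- match.arg(data_model)
  effects <- match.arg(effects)
  if (is.character(lam_mode)) {
    if (!identical(lam_mode, "estimated")) stop("lam_mode must be 'estimated' or a value in [0,1)")
  } else {
    if (!is.numeric(lam_mode) || length(lam_mode) != 1L ||
        lam_mode < 0 || lam_mode >= 1) stop("fixed lam must lie in [0, 1)")
  }
  structure(
    list(data_model = data_model,
         spatial_on = effects %in% c("spatial", "both"),
         temporal_on = effects %in% c("temporal", "both"),
         effects = effects,
         lam_mode = lam_mode,
         priors = priors),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", toupper(x$data_model), "data model, random effects:",
      x$effects, "\n")
  if (x$spatial_on) {
    cat("  CAR lam:", if (identical(x$lam_mode, "estimated")) "estimated"
        else paste("fixed at", x$lam_mode), "\n")
  }
  invisible(x)
}

#' Prior hyperparameters
#'
#' Weakly informative defaults: Gaussian priors on the stratum intercepts and
#' slopes; Gamma priors on the field precisions; Gaussian prior on the log
#' overdispersion theta = log(n); standard normal priors on the transformed
#' autocorrelation (Fisher z of rho) and CAR dependence (logit of lam);
#' Beta(1, 1) on the zero-inflation probability.
#'
#' @param alpha_mean,alpha_prec Gaussian prior on stratum intercepts.
#' @param beta_mean,beta_prec Gaussian prior on stratum slopes.
#' @param tau_shape,tau_rate Gamma prior on tau_eta and tau_gamma.
#' @param theta_mean,theta_prec Gaussian prior on log size.
#' @param rho_z_mean,rho_z_sd Gaussian prior on z = log((1+rho)/(1-rho)).
#' @param lam_z_mean,lam_z_sd Gaussian prior on logit(lam).
#' @param p_zero_a,p_zero_b Beta prior on the zero-inflation probability.
#' @param gamma_center_weight weight of the soft sum-to-zero pull on each
#'   stratum's temporal-residual series (rank-one precision term
#'   `tau_gamma * weight/T * 11'`); 0 disables it.
#' @return an object of class `prior_config` (a named list).
#' @export
prior_config <- function(alpha_mean = 0, alpha_prec = 0.001,
                         beta_mean = 0, beta_prec = 0.001,
                         tau_shape = 1, tau_rate = 0.02,
                         theta_mean = 0, theta_prec = 0.01,
                         rho_z_mean = 0, rho_z_sd = 1,
                         lam_z_mean = 0, lam_z_sd = 1,
                         p_zero_a = 1, p_zero_b = 1,
                         gamma_center_weight = 10) {
  pr <- list(alpha_mean = alpha_mean, alpha_prec = alpha_prec,
             beta_mean = beta_mean, beta_prec = beta_prec,
             tau_shape = tau_shape, tau_rate = tau_rate,
             theta_mean = theta_mean, theta_prec = theta_prec,
             rho_z_mean = rho_z_mean, rho_z_sd = rho_z_sd,
             lam_z_mean = lam_z_mean, lam_z_sd = lam_z_sd,
             p_zero_a = p_zero_a, p_zero_b = p_zero_b,
             gamma_center_weight = gamma_center_weight)
  bad <- names(pr)[!vapply(pr, function(v) is.numeric(v) && length(v) == 1L &&
                             is.finite(v), logical(1L))]
  if (length(bad)) stop("non-finite prior hyperparameters: ", paste(bad, collapse = ", "))
  if (alpha_prec <= 0 || beta_prec <= 0 || tau_shape <= 0 || tau_rate <= 0 ||
      theta_prec <= 0 || rho_z_sd <= 0 || lam_z_sd <= 0 ||
      p_zero_a <= 0 || p_zero_b <= 0 || gamma_center_weight < 0) {
    stop("prior precisions/shapes/rates must be positive")
  }
  structure(pr, class = "prior_config")
}

#' Build a model_spec from a YAML or JSON config file
#'
#' The file may contain keys `data_model`, `effects`, `lam_mode` and a
#' `priors` block whose entries override [prior_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @export
model_spec_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  priors <- do.call(prior_config, as.list(cfg$priors %||% list()))
  model_spec(data_model = cfg$data_model %||% "zinb",
             effects = cfg$effects %||% "both",
             lam_mode = cfg$lam_mode %||% "estimated",
             priors = priors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-linear predictor of the stratum-year mean
#'
#' `log(mu_jt) = alpha_j + beta_j * x_t + eta_jt + gamma_jt`, with the field
#' terms included only when the corresponding effect is switched on. All
#' segments within a (stratum, year) cell share this mean: segments are
#' replicate observations of the stratum-year abundance.
#'
#' @param state a latent state: list with `alpha`, `beta` (length m), `eta`,
#'   `gamma` (m x T matrices, may be NULL when the effect is off).
#' @param j stratum index (1..m).
#' @param t occasion index (1..T).
#' @param x_t time covariate; defaults to `t - 1` (years since the first
#'   occasion), so `alpha_j` is the first-year log mean and `beta_j` a
#'   per-year log-scale trend.
#' @param spatial_on,temporal_on whether each field enters the predictor.
#' @return the log mean `log(mu_jt)`.
#' @export
linear_predictor <- function(state, j, t, x_t = t - 1,
                             spatial_on = TRUE, temporal_on = TRUE) {
  m <- length(state$alpha)
  if (j < 1L || j > m) stop("stratum index out of range")
  if (t < 1L) stop("occasion index out of range")
  lp <- state$alpha[j] + state$beta[j] * x_t
  if (spatial_on) {
    if (is.null(state$eta) || t > ncol(state$eta)) stop("occasion index out of range")
    lp <- lp + state$eta[j, t]
  }
  if (temporal_on) {
    if (is.null(state$gamma) || t > ncol(state$gamma)) stop("occasion index out of range")
    lp <- lp + state$gamma[j, t]
  }
  lp
}

#' Trend-only change in mean counted pairs over the study span
#'
#' `exp(alpha_j + beta_j * x_T) - exp(alpha_j + beta_j * x_1)`: the change in
#' the fitted mean count per segment between the first and last occasion,
#' from the fixed-effect trend alone (random fields excluded). Negative
#' values are pairs lost, positive values pairs gained.
#'
#' @param state latent state with `alpha`, `beta`.
#' @param j stratum index.
#' @param span_years number of occasions spanned (T); the covariate runs
#'   `x_1 = 0` to `x_T = span_years - 1`.
#' @export
cumulative_change <- function(state, j, span_years) {
  if (span_years < 1) stop("span_years must be >= 1")
  if (j < 1L || j > length(state$alpha)) stop("stratum index out of range")
  x1 <- 0
  xT <- span_years - 1
  exp(state$alpha[j] + state$beta[j] * xT) - exp(state$alpha[j] + state$beta[j] * x1)
}
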