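#' Precision matrix of a stationary AR(1) series
#'
#' Tridiagonal precision of a stationary first-order autoregressive process
#' with autocorrelation `rho` and innovation precision `tau`: diagonal
#' `tau * c(1, rep(1 + rho^2, T-2), 1)`, off-diagonal `-tau * rho`. Its
#' inverse is the stationary covariance with entries
#' `rho^|t-s| / (tau * (1 - rho^2))`. On the log scale of abundance this is
#' the latent Gompertz structure: the residual at year t has conditional mean
#' `rho` times the residual at year t-1.
#'
#' @param rho autocorrelation, |rho| < 1.
#' @param tau innovation precision, > 0.
#' @param T_occasions number of occasions, >= 1.
#' @return dense T x T precision matrix.
#' @export
ar1_precision <- function(rho, tau, T_occasions) {
  check_ar1(rho, tau, T_occasions)
  T_occasions <- as.integer(T_occasions)
  if (T_occasions == 1L) return(matrix(tau * (1 - rho^2), 1L, 1L))
  Q <- diag(c(1, rep(1 + rho^2, T_occasions - 2L), 1))
  idx <- seq_len(T_occasions - 1L)
  Q[cbind(idx, idx + 1L)] <- -rho
  Q[cbind(idx + 1L, idx)] <- -rho
  tau * Q
}

check_ar1 <- function(rho, tau, T_occasions) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop("|rho| must be < 1")
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be > 0")
  }
  if (length(T_occasions) != 1L || T_occasions < 1 ||
      T_occasions != as.integer(T_occasions)) {
    stop("T_occasions must be a positive integer")
  }
  invisible(TRUE)
}

#' Log-determinant of the AR(1) precision (closed form)
#'
#' `T * log(tau) + log(1 - rho^2)` for the stationary AR(1) precision of
#' [ar1_precision()]. For T = 1 the marginal precision is `tau * (1 - rho^2)`
#' and the same expression holds.
#'
#' @inheritParams ar1_precision
#' @export
ar1_logdet <- function(rho, tau, T_occasions) {
  check_ar1(rho, tau, T_occasions)
  T_occasions * log(tau) + log(1 - rho^2)
}

#' Simulate stationary AR(1) series
#'
#' Draws `n_series` independent stationary series of length `T_occasions`.
#' The first occasion is drawn from the marginal distribution
#' Normal(0, 1/(tau (1 - rho^2))) rather than a diffuse start, so the
#' closed-form covariance `rho^|t-s|/(tau (1 - rho^2))` holds exactly at all
#' lags.
#'
#' With `center_weight > 0` the draw is instead from the soft sum-to-zero
#' variant used as the latent-residual prior in [fit_model()]: the precision
#' is augmented by the rank-one term `tau * (center_weight / T) * 11'`,
#' which pulls the series mean towards zero (see the methods vignette). The
#' default 0 gives the pure AR(1).
#'
#' @inheritParams ar1_precision
#' @param n_series number of independent series.
#' @param center_weight non-negative weight of the soft sum-to-zero penalty.
#' @return `n_series` x `T_occasions` matrix.
#' @export
simulate_ar1 <- function(rho, tau, T_occasions, n_series = 1L,
                         center_weight = 0) {
  check_ar1(rho, tau, T_occasions)
  T_occasions <- as.integer(T_occasions)
  n_series <- as.integer(n_series)
  stopifnot(n_series >= 1L, center_weight >= 0)
  if (center_weight > 0) {
    Q <- ar1_precision(rho, tau, T_occasions) +
      tau * (center_weight / T_occasions) *
        matrix(1, T_occasions, T_occasions)
    R <- chol(Q)
    z <- matrix(stats::rnorm(n_series * T_occasions), nrow = T_occasions)
    return(t(backsolve(R, z)))
  }
  sd_marg <- 1 / sqrt(tau * (1 - rho^2))
  sd_innov <- 1 / sqrt(tau)
  out <- matrix(0, n_series, T_occasions)
  out[, 1L] <- stats::rnorm(n_series, 0, sd_marg)
  if (T_occasions > 1L) {
    for (t in 2:T_occasions) {
      out[, t] <- rho * out[, t - 1L] + stats::rnorm(n_series, 0, sd_innov)
    }
  }
  out
}
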