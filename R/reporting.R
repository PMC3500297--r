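#' Classify per-stratum trends by credible interval
#'
#' A stratum is `increasing` when the lower bound of the equal-tailed
#' credible interval for its slope is above zero, `decreasing` when the upper
#' bound is below zero, and `no_change` otherwise — the interval rule used to
#' declare "significant" trends; no multiple-comparison adjustment is applied
#' across strata (a deliberate caveat: each stratum is reported on its own
#' evidence).
#'
#' @param result a `pt_fit` from [fit_model()].
#' @param level credibility level in (0, 1); 0.95 gives the 2.5/97.5 bounds.
#' @return a `trend_table` data frame: `stratum`, `beta_mean`, `beta_sd`,
#'   `q2.5`, `q97.5` (bounds at the requested level, columns named for the
#'   default), `class`, `pairs_change` (posterior mean trend-only change in
#'   counted pairs over the study span), plus an attribute `class_fractions`.
#' @export
classify_trends <- function(result, level = 0.95) {
  stopifnot(inherits(result, "pt_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)")
  }
  bdraw <- result$draws$beta
  adraw <- result$draws$alpha
  lo_p <- (1 - level) / 2
  hi_p <- 1 - lo_p
  lo <- apply(bdraw, 2L, stats::quantile, probs = lo_p, names = FALSE)
  hi <- apply(bdraw, 2L, stats::quantile, probs = hi_p, names = FALSE)
  cls <- ifelse(lo > 0, "increasing", ifelse(hi < 0, "decreasing", "no_change"))
  xT <- max(result$x)
  change <- colMeans(exp(adraw + bdraw * xT) - exp(adraw))
  out <- data.frame(
    stratum = result$stratum_ids,
    beta_mean = colMeans(bdraw),
    beta_sd = apply(bdraw, 2L, stats::sd),
    q2.5 = lo, q97.5 = hi,
    class = cls,
    pairs_change = change,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "class_fractions") <-
    c(increasing = mean(cls == "increasing"),
      decreasing = mean(cls == "decreasing"),
      no_change = mean(cls == "no_change"))
  attr(out, "level") <- level
  class(out) <- c("trend_table", "data.frame")
  out
}

#' Posterior predictive trajectory for one stratum
#'
#' For each year, pushes every posterior draw through the data model to
#' obtain the predictive distribution of a new segment count in the stratum:
#' the reported mean is the posterior mean of `(1 - p_zero) * mu_jt` (the
#' ZINB mean; `p_zero = 0` under the NB model) and the interval is the
#' equal-tailed quantile interval of simulated new counts.
#'
#' @param result a `pt_fit`.
#' @param j stratum identifier (as in the graph) or index.
#' @param level credibility level for the predictive interval.
#' @param base_year calendar year of occasion 1 (for the `year` column).
#' @return data frame `year`, `mean`, `q2.5`, `q97.5` (column names fixed to
#'   the conventional 95% labels; bounds follow `level`).
#' @export
posterior_predict_stratum <- function(result, j, level = 0.95,
                                      base_year = 1957L) {
  stopifnot(inherits(result, "pt_fit"))
  if (is.character(j)) {
    jj <- match(j, result$stratum_ids)
    if (is.na(jj)) stop("unknown stratum: ", j)
  } else {
    jj <- as.integer(j)
    if (jj < 1L || jj > result$m) stop("unknown stratum index: ", j)
  }
  Tn <- result$T
  nd <- nrow(result$draws$beta)
  sp <- result$spec$spatial_on
  te <- result$spec$temporal_on
  zi <- result$spec$data_model == "zinb"
  cols <- ((jj - 1L) * Tn + 1L):(jj * Tn)
  lp <- result$draws$alpha[, jj] + outer(result$draws$beta[, jj], result$x)
  if (sp) lp <- lp + result$draws$eta[, cols, drop = FALSE]
  if (te) lp <- lp + result$draws$gamma[, cols, drop = FALSE]
  mu <- exp(lp)
  pz <- if (zi) result$draws$hyper[, "p_zero"] else rep(0, nd)
  size_n <- exp(result$draws$hyper[, "theta"])
  pm <- colMeans((1 - pz) * mu)
  lo_p <- (1 - level) / 2
  qs <- vapply(seq_len(Tn), function(t) {
    yrep <- rzinb(nd, mu = mu[, t], size_n = size_n, p_zero = pz)
    stats::quantile(yrep, probs = c(lo_p, 1 - lo_p), names = FALSE)
  }, numeric(2L))
  data.frame(year = base_year + seq_len(Tn) - 1L,
             mean = pm, q2.5 = qs[1L, ], q97.5 = qs[2L, ])
}

#' Write the trend table to CSV
#'
#' Columns: `stratum, beta_mean, beta_sd, q2.5, q97.5, class, pairs_change`.
#'
#' @param trends a `trend_table` from [classify_trends()].
#' @param path output CSV path.
#' @export
write_trend_table <- function(trends, path) {
  utils::write.csv(as.data.frame(trends), path, row.names = FALSE)
  invisible(path)
}
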