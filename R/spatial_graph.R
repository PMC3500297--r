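#' Build the stratum neighbourhood graph from centroid coordinates
#'
#' Constructs the binary proximity matrix `W` used by the conditional
#' autoregressive (CAR) spatial random effect. Two strata are neighbours when
#' the Euclidean distance between their centroids (in the raw coordinate
#' units, typically decimal degrees) is less than or equal to `threshold`.
#' Distances are deliberately plain Euclidean on the coordinate values — no
#' great-circle correction — matching the survey convention of thresholding
#' centroid separation in decimal degrees.
#'
#' @param centroids numeric matrix or data frame with m rows and 2 columns
#'   (x, y); row names (or a `stratum` column via [read_centroids()]) give the
#'   stratum identifiers.
#' @param threshold neighbour distance; pairs at exactly this distance count
#'   as neighbours.
#' @param stratum_ids optional character vector of identifiers; defaults to
#'   row names or `"S1"..."Sm"`.
#' @param require_connected if `TRUE`, an isolated stratum (zero neighbours)
#'   is an error rather than a warning flag.
#'
#' @return An object of class `strata_graph`: a list with `stratum_ids`,
#'   `centroids`, `threshold`, `W` (m x m binary symmetric), `D` (diagonal
#'   row-sum matrix) and `isolated` (character vector of strata with no
#'   neighbour, possibly empty).
#' @export
build_proximity_matrix <- function(centroids, threshold, stratum_ids = NULL,
                                   require_connected = FALSE) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  m <- nrow(centroids)
  if (m < 2L) stop("at least two strata are required")
  if (ncol(centroids) != 2L) stop("centroids must have two columns (x, y)")
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  if (is.null(stratum_ids)) {
    stratum_ids <- rownames(centroids)
    if (is.null(stratum_ids)) stratum_ids <- paste0("S", seq_len(m))
  }
  stratum_ids <- as.character(stratum_ids)
  if (length(stratum_ids) != m) stop("stratum_ids length must match centroids")
  if (anyDuplicated(stratum_ids)) stop("duplicate stratum ids")

  dmat <- as.matrix(stats::dist(centroids, method = "euclidean"))
  if (any(dmat[upper.tri(dmat)] == 0)) {
    warning("coincident centroids present: zero-distance pairs are neighbours")
  }
  W <- (dmat <= threshold) * 1
  diag(W) <- 0
  dimnames(W) <- list(stratum_ids, stratum_ids)
  d <- rowSums(W)
  D <- diag(d, nrow = m)
  dimnames(D) <- dimnames(W)

  isolated <- stratum_ids[d == 0]
  if (length(isolated) > 0L) {
    msg <- paste0("isolated strata (no neighbour at threshold ", threshold, "): ",
                  paste(isolated, collapse = ", "))
    if (require_connected) stop(msg) else warning(msg)
  }

  structure(
    list(stratum_ids = stratum_ids, centroids = centroids,
         threshold = threshold, W = W, D = D, isolated = isolated),
    class = "strata_graph"
  )
}

#' @export
print.strata_graph <- function(x, ...) {
  cat("strata_graph:", length(x$stratum_ids), "strata, threshold",
      format(x$threshold), "\n")
  cat("  neighbour counts:", paste(range(diag(x$D)), collapse = "-"),
      "(min-max);", sum(x$W) / 2, "edges\n")
  if (length(x$isolated)) cat("  isolated:", paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}

#' Smallest threshold at which every stratum has a neighbour
#'
#' Returns the max over strata of the distance to its nearest other stratum:
#' the shortest neighbour threshold at which all strata have at least one
#' neighbour (ties at the threshold count as neighbours).
#'
#' @inheritParams build_proximity_matrix
#' @return a single distance.
#' @export
min_connecting_threshold <- function(centroids) {
  centroids <- as.matrix(centroids)
  m <- nrow(centroids)
  if (m < 2L) stop("at least two strata are required")
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  dmat <- as.matrix(stats::dist(centroids))
  diag(dmat) <- Inf
  max(apply(dmat, 1L, min))
}

#' Proper-CAR precision matrix for the spatial field
#'
#' The spatial random effect at one time slice is Gaussian with precision
#' `Q = tau * (D - lam * W)`, the proper CAR model on the stratum
#' neighbourhood graph. `Q` is strictly diagonally dominant (hence positive
#' definite) whenever every stratum has at least one neighbour and
#' `0 <= lam < 1`.
#'
#' @param graph a `strata_graph` from [build_proximity_matrix()].
#' @param tau precision multiplier, > 0.
#' @param lam spatial-dependence parameter in `[0, 1)`.
#' @return dense m x m precision matrix with stratum-id dimnames.
#' @export
car_precision <- function(graph, tau, lam) {
  stopifnot(inherits(graph, "strata_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a single positive number")
  }
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 0 || lam >= 1) {
    stop("lam must lie in [0, 1)")
  }
  if (length(graph$isolated) > 0L && lam > 0) {
    stop("CAR precision is singular: isolated strata ",
         paste(graph$isolated, collapse = ", "),
         " have zero conditional precision; increase the threshold ",
         "(see min_connecting_threshold)")
  }
  Q <- tau * (graph$D - lam * graph$W)
  # exact symmetry: W is stored symmetric, D diagonal
  Q
}

#' Draw spatial fields from the CAR model
#'
#' Samples `n` independent realisations of the m-vector spatial field with
#' distribution Normal(0, Q^-1), Q from [car_precision()].
#'
#' @inheritParams car_precision
#' @param n number of independent field draws.
#' @return n x m matrix; each row one field.
#' @export
sample_car <- function(graph, tau, lam, n = 1L) {
  Q <- car_precision(graph, tau, lam)
  R <- chol(Q)                         # Q = R'R, R upper triangular
  z <- matrix(stats::rnorm(n * ncol(Q)), nrow = ncol(Q))
  x <- backsolve(R, z)                 # x ~ N(0, Q^-1)
  t(x)
}

#' Read stratum centroids from CSV
#'
#' Expects columns `stratum,x,y`; stratum ids are read as character.
#'
#' @param path CSV file path.
#' @return matrix of centroids with stratum ids as row names.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, colClasses = c(stratum = "character"))
  need <- c("stratum", "x", "y")
  if (!all(need %in% names(df))) stop("centroid file must have columns stratum,x,y")
  out <- as.matrix(df[, c("x", "y")])
  rownames(out) <- df$stratum
  out
}

#' Write the proximity and row-sum matrices to CSV for inspection
#'
#' @param graph a `strata_graph`.
#' @param w_path,d_path output CSV paths (row/column labels = stratum ids).
#' @export
write_graph_matrices <- function(graph, w_path, d_path) {
  stopifnot(inherits(graph, "strata_graph"))
  utils::write.csv(graph$W, w_path)
  utils::write.csv(graph$D, d_path)
  invisible(c(w_path, d_path))
}
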