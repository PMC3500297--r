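test_that("proximity matrix matches hand-worked configurations", {
  # two strata too far apart: no edges, isolated-stratum warning
  expect_warning(
    g <- build_proximity_matrix(rbind(c(0, 0), c(10, 0)), threshold = 7.75),
    "isolated"
  )
  expect_equal(unname(g$W), matrix(0, 2, 2))
  expect_identical(g$isolated, g$stratum_ids)

  # three collinear strata: band structure forced by the spacing
  g3 <- build_proximity_matrix(cbind(c(0, 1, 2), 0), threshold = 1.5)
  expect_equal(unname(g3$W), rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(diag(g3$D)), c(1, 2, 1))
  expect_length(g3$isolated, 0)
})

test_that("proximity matrix validates its inputs", {
  cc <- rbind(c(0, 0), c(1, 0))
  expect_error(build_proximity_matrix(cc[1, , drop = FALSE], 1), "two strata")
  expect_error(build_proximity_matrix(cc, -1), "positive")
  expect_error(build_proximity_matrix(rbind(c(0, 0), c(NA, 0)), 1), "finite")
  expect_error(build_proximity_matrix(cc, 2, stratum_ids = c("a", "a")),
               "duplicate")
  expect_error(
    suppressWarnings(build_proximity_matrix(rbind(c(0, 0), c(9, 0)), 1,
                                            require_connected = TRUE)),
    "isolated"
  )
  # coincident centroids: permitted neighbours, but flagged
  expect_warning(build_proximity_matrix(rbind(c(0, 0), c(0, 0), c(1, 0)), 2),
                 "coincident")
})

test_that("W and D agree with an independent brute-force oracle on random graphs", {
  set.seed(41)
  for (rep in 1:50) {
    m <- sample(3:30, 1)
    cc <- cbind(runif(m, 0, 10), runif(m, 0, 10))
    thr <- min_connecting_threshold(cc)
    g <- build_proximity_matrix(cc, thr)
    oracle <- brute_force_graph(cc, thr)
    expect_identical(unname(g$W), oracle$W)
    expect_identical(unname(g$D), oracle$D)
    expect_true(all(rowSums(g$W) >= 1))   # all connected at d*
    expect_identical(g$W, t(g$W))
    expect_true(all(diag(g$W) == 0))
  }
})

test_that("min_connecting_threshold is the nearest-neighbour maximum", {
  expect_equal(min_connecting_threshold(cbind(c(0, 1, 5), 0)), 4)
  # coincident pair plus a distant point: the distant gap decides
  expect_equal(min_connecting_threshold(cbind(c(0, 0, 3), 0)), 3)
  expect_error(min_connecting_threshold(cbind(1, 1)), "two strata")

  # below d*, at least one stratum is isolated; at d*, none
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(4:25, 1)
    cc <- cbind(runif(m, 0, 10), runif(m, 0, 10))
    dstar <- min_connecting_threshold(cc)
    dmat <- as.matrix(dist(cc)); diag(dmat) <- Inf
    expect_equal(dstar, max(apply(dmat, 1, min)))   # oracle recomputation
    W_at <- (dmat <= dstar) * 1
    expect_true(all(rowSums(W_at) >= 1))
    W_below <- (dmat <= dstar * (1 - 1e-9)) * 1
    expect_true(any(rowSums(W_below) == 0))
  }
})

test_that("CAR precision has the proper-CAR form and is positive definite", {
  g3 <- build_proximity_matrix(cbind(c(0, 1, 2), 0), threshold = 1.5)
  # dependence switched off: tau * D
  expect_equal(unname(car_precision(g3, tau = 2.5, lam = 0)),
               2.5 * unname(g3$D))
  # 3-node path, direct substitution
  expect_equal(unname(car_precision(g3, tau = 1, lam = 0.5)),
               rbind(c(1, -0.5, 0), c(-0.5, 2, -0.5), c(0, -0.5, 1)))
  # exact symmetry, not approximate
  Q <- car_precision(g3, tau = 3.7, lam = 0.9)
  expect_identical(Q, t(Q))

  expect_error(car_precision(g3, tau = 1, lam = 1), "lam")
  expect_error(car_precision(g3, tau = 1, lam = -0.1), "lam")
  expect_error(car_precision(g3, tau = 0, lam = 0.5), "tau")
  gi <- suppressWarnings(build_proximity_matrix(rbind(c(0, 0), c(9, 0), c(9.5, 0)), 1))
  expect_error(car_precision(gi, 1, 0.5), "S1")

  # Cholesky succeeds on connected graphs up to m = 60 for a grid of lam
  set.seed(43)
  for (m in c(10, 35, 60)) {
    cc <- cbind(runif(m, 0, 10), runif(m, 0, 10))
    g <- build_proximity_matrix(cc, min_connecting_threshold(cc))
    for (lam in c(0, 0.25, 0.5, 0.9)) {
      expect_no_error(chol(car_precision(g, tau = 1.3, lam = lam)))
    }
  }
})

test_that("sampled CAR fields recover the dense-inversion covariance", {
  set.seed(44)
  cc <- cbind(runif(6, 0, 4), runif(6, 0, 4))
  g <- build_proximity_matrix(cc, min_connecting_threshold(cc))
  tau <- 1.5; lam <- 0.7
  Sigma <- solve(car_precision(g, tau, lam))
  n <- 50000
  x <- sample_car(g, tau, lam, n = n)
  emp <- crossprod(x) / n
  # Monte-Carlo error of a covariance entry
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n)
  expect_lt(max(abs(emp - Sigma) / se), 6)
})

test_that("centroid and matrix files round-trip", {
  tmp <- withr::local_tempdir()
  cents <- data.frame(stratum = c("A", "B", "C"), x = c(0, 1, 2), y = 0)
  write.csv(cents, file.path(tmp, "cent.csv"), row.names = FALSE)
  cc <- read_centroids(file.path(tmp, "cent.csv"))
  expect_identical(rownames(cc), c("A", "B", "C"))
  g <- build_proximity_matrix(cc, 1.5)
  write_graph_matrices(g, file.path(tmp, "W.csv"), file.path(tmp, "D.csv"))
  W2 <- as.matrix(read.csv(file.path(tmp, "W.csv"), row.names = 1))
  expect_equal(unname(W2), unname(g$W))
})
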