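# Feature ranking (GSO, ReliefF, SIMBA), vote aggregation, PCA projection.

test_that("GSO selects a duplicated label column first", {
  set.seed(1)
  n <- 100
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 7] <- ifelse(y == 1, 1, -1)
  rk <- gso_rank(X, y)
  expect_equal(rk$order[1], 7)
})

test_that("GSO on orthonormal columns ranks by absolute correlation", {
  set.seed(2)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 10), n, 10)))   # orthonormal columns
  y <- as.integer(Q[, 3] + 0.5 * Q[, 8] + 0.25 * Q[, 1] > 0)
  rk <- gso_rank(Q, y, k = 10)
  r <- ifelse(y == 1, 1, -1); r <- r - mean(r)
  Z <- pdvoice:::standardize_cols(Q)
  brute <- order(as.numeric(crossprod(Z, r)^2 / colSums(Z^2)),
                 decreasing = TRUE)
  expect_equal(rk$order[1:3], brute[1:3])
})

test_that("GSO zeroes the score of a duplicated column after selection", {
  set.seed(3)
  n <- 80
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 2] <- ifelse(y == 1, 1.5, -1.5) + 0.1 * rnorm(n)
  X[, 5] <- X[, 2]                                # exact copy
  rk <- gso_rank(X, y, k = 3)
  expect_true(rk$order[1] %in% c(2, 5))
  copy <- setdiff(c(2, 5), rk$order[1])
  expect_false(copy %in% rk$order[2:3])           # residual ~ 0 after twin
})

test_that("ReliefF finds the informative feature and zeroes constants", {
  hits <- 0
  for (rep_i in 1:25) {
    set.seed(100 + rep_i)
    n <- 400
    y <- rep(c(0, 1), n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 11] <- y + 0.3 * rnorm(n)
    X[, 4] <- 2.5                                  # constant
    rk <- relief_rank(X, y)
    if (rk$order[1] == 11) hits <- hits + 1
    if (rep_i == 1) {
      expect_equal(rk$scores[4], 0)
      # permutation of samples leaves weights unchanged
      perm <- sample(n)
      rk2 <- relief_rank(X[perm, ], y[perm])
      expect_equal(rk$scores, rk2$scores, tolerance = 1e-10)
    }
  }
  expect_gte(hits, 24)
})

test_that("SIMBA finds the informative feature deterministically", {
  hits <- 0
  for (rep_i in 1:25) {
    set.seed(200 + rep_i)
    n <- 300
    y <- rep(c(0, 1), n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 13] <- y + 0.3 * rnorm(n)
    rk <- simba_rank(X, y, seed = rep_i)
    if (rk$order[1] == 13) hits <- hits + 1
    if (rep_i == 1)
      expect_identical(rk$order, simba_rank(X, y, seed = rep_i)$order)
  }
  expect_gte(hits, 24)
})

test_that("SIMBA treats identical feature copies symmetrically", {
  set.seed(5)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  base <- y + 0.4 * rnorm(n)
  X <- cbind(base, base, base, matrix(rnorm(n * 5), n, 5))
  rk <- simba_rank(X, y, seed = 2)
  w2 <- rk$scores[1:3]
  expect_lt((max(w2) - min(w2)) / max(w2), 0.10)
})

test_that("vote() equals a brute-force tally with the documented tie-breaks", {
  mk <- function(ord) pdvoice:::feature_ranking("gso", ord, rev(seq_along(ord)))
  p <- 40
  set.seed(6)
  rankings <- lapply(1:3, function(i) mk(sample(p)))
  tally <- vote(rankings, top_k = 10)
  votes_bf <- numeric(p)
  ranks_bf <- matrix(0, 3, p)
  for (i in 1:3) {
    votes_bf[rankings[[i]]$order[1:10]] <-
      votes_bf[rankings[[i]]$order[1:10]] + 1
    ranks_bf[i, rankings[[i]]$order] <- 1:p
  }
  expect_equal(tally$votes, votes_bf)
  bf_order <- order(-votes_bf, colMeans(ranks_bf), seq_len(p))
  expect_equal(tally$final_order, bf_order)
  # identical rankings aggregate to themselves; ubiquitous features get R votes
  same <- lapply(1:4, function(i) mk(1:p))
  t2 <- vote(same, top_k = 10)
  expect_equal(t2$final_order, 1:p)
  expect_true(all(t2$votes[1:10] == 4))
  expect_error(vote(list()), "empty")
})

test_that("PCA projection is fit on training data only", {
  set.seed(7)
  X <- matrix(rnorm(100 * 12), 100, 12)
  pr <- pca_project(X, X, n_components = 10)
  v <- apply(pr$train, 2, var)
  expect_true(all(diff(v) < 1e-10))          # non-increasing variance
  # rank-2 data: components 3+ carry ~ zero variance
  X2 <- cbind(rnorm(50), rnorm(50)) %*% matrix(rnorm(2 * 8), 2, 8)
  pr2 <- pca_project(X2, X2, n_components = 6)
  v2 <- apply(pr2$train, 2, var)
  expect_lt(v2[3] / v2[1], 1e-20)
  # the rotation applied to new data uses training centering
  held <- matrix(rnorm(20 * 12), 20, 12)
  pr3 <- pca_project(X, held, n_components = 3)
  expect_equal(dim(pr3$apply), c(20, 3))
})

test_that("rankers follow a feature permutation", {
  set.seed(8)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 3] <- y + 0.3 * rnorm(n)
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  Xp <- X[, perm]
  for (fn in list(gso_rank, relief_rank)) {
    r1 <- fn(X, y)
    r2 <- fn(Xp, y)
    expect_equal(perm[r2$order[1]], r1$order[1])
  }
})
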