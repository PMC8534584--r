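# Feature ranking (Gram-Schmidt orthogonalization, ReliefF, SIMBA), vote
# aggregation over cross-validation runs, and the 30-component PCA
# alternative.

feature_ranking <- function(method, order, scores) {
  stopifnot(length(order) == length(scores),
            setequal(order, seq_along(scores)))
  structure(list(method = method, order = as.integer(order),
                 scores = as.numeric(scores)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s over %d features; top 5: %s\n",
              x$method, length(x$order),
              paste(x$order[1:min(5, length(x$order))], collapse = ", ")))
  invisible(x)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Gram-Schmidt orthogonalization forward feature ranking
#'
#' Forward selection on standardized columns with the label encoded +/-1:
#' at each step the feature whose (orthogonalized) column maximizes the
#' squared correlation with the (orthogonalized) label residual is
#' selected, and its direction is projected out of all remaining columns
#' and the residual. Features not selected within `k` steps are ranked
#' after the selected ones by their final-step score.
#'
#' @param X Feature matrix (rows = recordings).
#' @param y Binary labels in `{0, 1}`.
#' @param k Number of forward-selection steps (default 30).
#' @return A `feature_ranking`.
#' @export
gso_rank <- function(X, y, k = 30) {
  X <- standardize_cols(as.matrix(X))
  n <- nrow(X); p <- ncol(X)
  stopifnot(n > 1, length(y) == n)
  r <- ifelse(y == 1, 1, -1)
  r <- r - mean(r)
  k <- min(k, p)
  selected <- integer(0)
  remaining <- seq_len(p)
  last_scores <- rep(NA_real_, p)
  for (step in seq_len(k)) {
    nrm2 <- colSums(X[, remaining, drop = FALSE]^2)
    live <- nrm2 > 1e-10
    if (!any(live)) break                      # rank-deficient: stop early
    sc <- rep(0, length(remaining))
    sc[live] <- (crossprod(X[, remaining[live], drop = FALSE], r)^2 /
                   nrm2[live])
    last_scores[remaining] <- sc
    j <- remaining[which.max(sc)]
    selected <- c(selected, j)
    q <- X[, j] / sqrt(sum(X[, j]^2))
    remaining <- setdiff(remaining, j)
    if (length(remaining) > 0) {
      proj <- crossprod(X[, remaining, drop = FALSE], q)
      X[, remaining] <- X[, remaining, drop = FALSE] -
        tcrossprod(q, as.numeric(proj))
    }
    r <- r - q * sum(q * r)
  }
  rest <- setdiff(seq_len(p), selected)
  rest <- rest[base::order(last_scores[rest], decreasing = TRUE)]
  scores <- numeric(p)
  scores[selected] <- seq(p, p - length(selected) + 1)   # rank-coded
  scores[rest] <- last_scores[rest]
  feature_ranking("gso", c(selected, rest), scores)
}

#' ReliefF feature ranking
#'
#' Classical ReliefF with `n_neighbors` nearest hits and misses in the
#' standardized Euclidean metric: each feature's weight accumulates the
#' mean per-feature distance to the misses minus the mean distance to the
#' hits, normalized by the feature range. Constant features get weight 0.
#'
#' @param X Feature matrix.
#' @param y Binary labels in `{0, 1}` (>= 2 samples per class).
#' @param n_neighbors Neighborhood size (reduced with a warning when a
#'   class is too small).
#' @return A `feature_ranking`.
#' @export
relief_rank <- function(X, y, n_neighbors = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, min(table(y)) >= 2)
  k_max <- min(table(y)) - 1
  if (n_neighbors > k_max) {
    warning("n_neighbors reduced to ", k_max, " (small class)")
    n_neighbors <- k_max
  }
  rng <- apply(X, 2, function(col) diff(range(col)))
  rng[rng < 1e-12] <- Inf                       # constant feature -> 0 weight
  Z <- standardize_cols(X)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cl <- which(y != y[i])
    hits <- same[base::order(D[i, same])][seq_len(n_neighbors)]
    misses <- diff_cl[base::order(D[i, diff_cl])][seq_len(n_neighbors)]
    dh <- colMeans(abs(sweep(X[hits, , drop = FALSE], 2, X[i, ])))
    dm <- colMeans(abs(sweep(X[misses, , drop = FALSE], 2, X[i, ])))
    w <- w + (dm - dh) / rng
  }
  w <- w / n
  feature_ranking("relief", base::order(w, decreasing = TRUE), w)
}

#' SIMBA feature ranking
#'
#' Margin-based iterative weight learning: starting from unit weights, the
#' samples are visited in random order; for each, the nearest hit and miss
#' in the current weighted metric define the hypothesis margin, and the
#' weights take a gradient-ascent step on it (linear utility, learning
#' rate `lr / sqrt(t)`). Features are ranked by the squared final weights.
#'
#' @param X Feature matrix (standardized internally).
#' @param y Binary labels in `{0, 1}`.
#' @param n_passes Passes over the data (default 5).
#' @param lr Base learning rate (default 0.1).
#' @param seed Seed for the visiting order.
#' @return A `feature_ranking`.
#' @export
simba_rank <- function(X, y, n_passes = 5, lr = 0.1, seed = 1L) {
  Z <- standardize_cols(as.matrix(X))
  n <- nrow(Z)
  stopifnot(length(y) == n, min(table(y)) >= 2)
  ord <- with_local_seed(seed,
    unlist(lapply(seq_len(n_passes), function(i) sample.int(n))))
  w <- simba_weights(Z, as.integer(y), as.integer(ord), lr)
  w2 <- w^2
  feature_ranking("simba", base::order(w2, decreasing = TRUE), w2)
}

#' Aggregate per-run rankings with top-k voting
#'
#' Each run casts one vote for every feature in its top `top_k`; the final
#' order sorts by descending votes, breaking ties by mean within-run rank
#' and then by feature index.
#'
#' @param rankings Non-empty list of `feature_ranking`s over the same
#'   feature set.
#' @param top_k Vote list length (default 30).
#' @return An object of class `vote_tally`: `votes` (per feature),
#'   `final_order`, `mean_rank`, `n_runs`.
#' @export
vote <- function(rankings, top_k = 30) {
  if (length(rankings) == 0) stop("empty ranking list")
  p <- length(rankings[[1]]$order)
  stopifnot(all(vapply(rankings, function(r) length(r$order) == p,
                       logical(1))))
  votes <- numeric(p)
  rank_sum <- numeric(p)
  for (r in rankings) {
    votes[r$order[seq_len(min(top_k, p))]] <-
      votes[r$order[seq_len(min(top_k, p))]] + 1
    rank_sum[r$order] <- rank_sum[r$order] + seq_len(p)
  }
  mean_rank <- rank_sum / length(rankings)
  final_order <- base::order(-votes, mean_rank, seq_len(p))
  structure(list(votes = votes, final_order = final_order,
                 mean_rank = mean_rank, n_runs = length(rankings)),
            class = "vote_tally")
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf("<vote_tally> %d runs; top 10 features: %s\n", x$n_runs,
              paste(x$final_order[1:min(10, length(x$final_order))],
                    collapse = ", ")))
  invisible(x)
}

#' Principal-component projection fit on training data only
#'
#' Centers and scales with training statistics, fits the rotation on the
#' training matrix, and applies it to both matrices.
#'
#' @param X_train Training feature matrix (`nrow > n_components`).
#' @param X_apply Matrix to project with the training rotation.
#' @param n_components Number of components (default 30).
#' @return List with `train`, `apply` (projected matrices) and `rotation`.
#' @export
pca_project <- function(X_train, X_apply, n_components = 30) {
  X_train <- as.matrix(X_train)
  stopifnot(nrow(X_train) > n_components)
  sdv <- apply(X_train, 2, stats::sd)
  keep_scale <- ifelse(sdv < 1e-12, 1, sdv)
  pc <- stats::prcomp(X_train, center = TRUE, scale. = keep_scale,
                      rank. = n_components)
  proj <- function(M) {
    M <- sweep(sweep(as.matrix(M), 2, pc$center), 2, pc$scale, "/")
    M %*% pc$rotation
  }
  list(train = proj(X_train), apply = proj(X_apply), rotation = pc$rotation)
}
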