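#' Distance metrics available to the KNN classifier
#' @export
knn_metrics <- c("minkowski", "chebyshev", "euclidean",
                 "standardized_euclidean", "cosine", "jaccard", "manhattan",
                 "hamming", "correlation")

# n_query x n_train distance matrix; metrics on continuous feature vectors.
# Conventions for the set-style metrics on real vectors: hamming = fraction
# of unequal coordinates; jaccard = fraction unequal among coordinates where
# either value is nonzero. Minkowski uses exponent p = 3 (euclidean and
# manhattan cover p = 2 and p = 1 separately).
knn_distance_matrix <- function(query_X, train_X, metric,
                                train_sd = NULL, minkowski_p = 3) {
  nq <- nrow(query_X); nt <- nrow(train_X)
  switch(
    metric,
    euclidean = {
      cross <- query_X %*% t(train_X)
      d2 <- outer(rowSums(query_X^2), rowSums(train_X^2), `+`) - 2 * cross
      sqrt(pmax(d2, 0))
    },
    standardized_euclidean = {
      if (is.null(train_sd)) train_sd <- apply(train_X, 2, stats::sd)
      if (any(train_sd == 0)) {
        stop("standardized_euclidean: zero-variance training column",
             call. = FALSE)
      }
      knn_distance_matrix(sweep(query_X, 2, train_sd, `/`),
                          sweep(train_X, 2, train_sd, `/`), "euclidean")
    },
    manhattan = pair_reduce(query_X, train_X,
                            function(dq, dt) sum(abs(dq - dt))),
    chebyshev = pair_reduce(query_X, train_X,
                            function(dq, dt) max(abs(dq - dt))),
    minkowski = pair_reduce(query_X, train_X, function(dq, dt) {
      sum(abs(dq - dt)^minkowski_p)^(1 / minkowski_p)
    }),
    cosine = {
      qn <- sqrt(rowSums(query_X^2)); tn <- sqrt(rowSums(train_X^2))
      sim <- (query_X %*% t(train_X)) /
        (pmax(qn, .Machine$double.xmin) %o% pmax(tn, .Machine$double.xmin))
      d <- 1 - sim
      # zero-norm rows: identical zeros at distance 0, else 1
      zq <- qn == 0; zt <- tn == 0
      if (any(zq) || any(zt)) {
        d[zq, ] <- 1; d[, zt] <- 1
        d[zq, zt] <- 0
      }
      d
    },
    correlation = {
      dq <- query_X - rowMeans(query_X)
      dt <- train_X - rowMeans(train_X)
      qn <- sqrt(rowSums(dq^2)); tn <- sqrt(rowSums(dt^2))
      sim <- (dq %*% t(dt)) /
        (pmax(qn, .Machine$double.xmin) %o% pmax(tn, .Machine$double.xmin))
      d <- 1 - sim
      zq <- qn == 0; zt <- tn == 0   # constant vectors
      if (any(zq) || any(zt)) {
        d[zq, ] <- 1; d[, zt] <- 1
        d[zq, zt] <- 0
      }
      d
    },
    hamming = pair_reduce(query_X, train_X,
                          function(dq, dt) mean(dq != dt)),
    jaccard = pair_reduce(query_X, train_X, function(dq, dt) {
      support <- dq != 0 | dt != 0
      if (!any(support)) return(0)
      mean(dq[support] != dt[support])
    }),
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

pair_reduce <- function(query_X, train_X, f) {
  out <- matrix(0, nrow(query_X), nrow(train_X))
  for (i in seq_len(nrow(query_X))) {
    qi <- query_X[i, ]
    out[i, ] <- apply(train_X, 1, function(t) f(qi, t))
  }
  out
}

#' K-nearest-neighbour classification
#'
#' Majority vote among the `k` nearest training points under the chosen
#' metric. Distance ties at the k-th neighbour include all co-distant
#' points; a tied vote is broken by the label of the single nearest
#' neighbour (earliest training row on an exact distance tie), so
#' prediction is deterministic.
#'
#' @param train_X Numeric matrix of training rows (standardised upstream).
#' @param train_y `"healthy"` / `"septic"` per training row.
#' @param query_X Numeric matrix of query rows (same columns).
#' @param k Neighbourhood size, `1 <= k <= nrow(train_X)`.
#' @param metric One of [knn_metrics].
#' @param train_sd Column standard deviations for
#'   `"standardized_euclidean"`; computed from `train_X` when omitted.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_X, train_y, query_X, k = 1L,
                        metric = "euclidean", train_sd = NULL) {
  train_X <- as.matrix(train_X); query_X <- as.matrix(query_X)
  metric <- match.arg(metric, knn_metrics)
  if (k < 1 || k > nrow(train_X)) {
    stop("k must lie in [1, n_train]", call. = FALSE)
  }
  d <- knn_distance_matrix(query_X, train_X, metric, train_sd)
  apply(d, 1, function(di) {
    kth <- sort(di, partial = k)[k]
    nb <- which(di <= kth)
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    train_y[nb[which.min(di[nb])]]
  })
}
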