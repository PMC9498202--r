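#' Hyperparameter search space for a classifier
#'
#' KNN tunes the neighbourhood size `k` (integers 1--20) and the distance
#' metric (nine-way categorical); the SVM tunes kernel scale and box
#' constraint, both log-uniform over \[1e-3, 1e3\].
#'
#' @param model_kind `"KNN"` or `"SVM"`.
#' @param k_max Upper bound of the KNN neighbourhood range (default 20).
#' @param metric_set Subset of [knn_metrics] (default all nine).
#' @param scale_range,box_range Ranges for the SVM parameters.
#' @return An object of class `hp_space`: list of parameter descriptors.
#' @export
hyperparameter_space <- function(model_kind = c("KNN", "SVM"), k_max = 20L,
                                 metric_set = knn_metrics,
                                 scale_range = c(1e-3, 1e3),
                                 box_range = c(1e-3, 1e3)) {
  model_kind <- match.arg(model_kind)
  params <- if (model_kind == "KNN") {
    stopifnot(all(metric_set %in% knn_metrics), length(metric_set) >= 1,
              k_max >= 1)
    list(
      list(name = "k", type = "integer", lower = 1, upper = k_max),
      list(name = "metric", type = "categorical", values = metric_set)
    )
  } else {
    stopifnot(all(scale_range > 0), all(box_range > 0))
    list(
      list(name = "kernel_scale", type = "numeric", lower = scale_range[1],
           upper = scale_range[2], log = TRUE),
      list(name = "box_constraint", type = "numeric", lower = box_range[1],
           upper = box_range[2], log = TRUE)
    )
  }
  structure(list(model_kind = model_kind, params = params),
            class = "hp_space")
}

# ---- encoding helpers: unit-cube coordinates <-> parameter lists ----------

space_dim <- function(space) {
  sum(vapply(space$params, function(p) {
    if (p$type == "categorical") length(p$values) else 1L
  }, integer(1)))
}

decode_point <- function(space, z) {
  out <- list()
  i <- 1L
  for (p in space$params) {
    if (p$type == "categorical") {
      block <- z[i:(i + length(p$values) - 1L)]
      out[[p$name]] <- p$values[which.max(block)]
      i <- i + length(p$values)
    } else {
      v <- if (isTRUE(p$log)) {
        exp(log(p$lower) + z[i] * (log(p$upper) - log(p$lower)))
      } else {
        p$lower + z[i] * (p$upper - p$lower)
      }
      if (p$type == "integer") v <- as.integer(round(v))
      out[[p$name]] <- min(max(v, p$lower), p$upper)
      i <- i + 1L
    }
  }
  out
}

#' Bayesian hyperparameter optimisation
#'
#' Minimises a (possibly noisy) objective over a classifier search space
#' with a Gaussian-process surrogate and the expected-improvement
#' acquisition. Continuous ranges are log-scaled where declared; the
#' categorical metric is one-hot encoded. The budget counts every objective
#' evaluation, including the space-filling initial design (Latin hypercube
#' over the unit cube). An objective returning a non-finite value is
#' recorded with a large penalty and the search continues.
#'
#' @param objective Function taking a named parameter list, returning a
#'   scalar to minimise (e.g. cross-validated misclassification rate).
#' @param space An [hyperparameter_space()].
#' @param budget Total evaluations (default 30).
#' @param seed Integer seed for the search's randomness.
#' @param n_init Initial-design size (default `min(8, budget)`).
#' @return An object of class `bhpo_trace`: data frame `evaluations`
#'   (decoded parameters, objective, incumbent), `best_params`,
#'   `best_objective`, `budget`, `seed`.
#' @export
bayesian_optimize <- function(objective, space, budget = 30L, seed = 1L,
                              n_init = NULL) {
  stopifnot(inherits(space, "hp_space"), budget >= 1)
  if (is.null(n_init)) n_init <- min(8L, budget)
  n_init <- min(n_init, budget)
  d <- space_dim(space)
  penalty <- 10 # objective scale is an error rate; any finite value loses

  run <- function() {
    Z <- lhs::randomLHS(n_init, d)
    y <- numeric(0)
    params <- list()
    eval_at <- function(z) {
      p <- decode_point(space, z)
      v <- tryCatch(objective(p), error = function(e) NaN)
      if (!is.finite(v)) v <- penalty
      list(p = p, v = v)
    }
    for (i in seq_len(n_init)) {
      r <- eval_at(Z[i, ])
      params[[i]] <- r$p
      y <- c(y, r$v)
    }
    while (length(y) < budget) {
      cand <- matrix(stats::runif(512 * d), ncol = d)
      ei <- gp_expected_improvement(Z, y, cand)
      z_next <- cand[which.max(ei), ]
      r <- eval_at(z_next)
      Z <- rbind(Z, z_next)
      params[[length(params) + 1L]] <- r$p
      y <- c(y, r$v)
    }
    list(Z = Z, y = y, params = params)
  }
  res <- with_seed(seed, run())

  best_i <- which.min(res$y)
  evals <- do.call(rbind, lapply(seq_along(res$y), function(i) {
    data.frame(iteration = i,
               as.data.frame(res$params[[i]], stringsAsFactors = FALSE),
               objective = res$y[i],
               incumbent = min(res$y[1:i]))
  }))
  structure(
    list(evaluations = evals, best_params = res$params[[best_i]],
         best_objective = res$y[best_i], budget = budget, seed = seed),
    class = "bhpo_trace"
  )
}

#' @export
print.bhpo_trace <- function(x, ...) {
  cat(sprintf("<bhpo_trace: %d evaluations, best objective %.4f at %s>\n",
              nrow(x$evaluations), x$best_objective,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# GP surrogate with squared-exponential kernel on the unit cube; y is
# standardised, the lengthscale picked from a small grid by marginal
# likelihood. Returns EI of candidate points against the best observation.
gp_expected_improvement <- function(Z, y, cand) {
  n <- length(y)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) {
    return(stats::runif(nrow(cand)))  # flat objective: explore at random
  }
  ys <- (y - mu_y) / sd_y
  nugget <- 1e-6 + 1e-4
  best_ll <- -Inf
  K_best <- NULL; ell_best <- 0.3
  for (ell in c(0.1, 0.2, 0.3, 0.5, 1)) {
    K <- se_kernel(Z, Z, ell) + diag(nugget, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (ll > best_ll) {
      best_ll <- ll; K_best <- ch; ell_best <- ell
    }
  }
  if (is.null(K_best)) return(stats::runif(nrow(cand)))
  ch <- K_best
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  Ks <- se_kernel(cand, Z, ell_best)
  mu <- as.numeric(Ks %*% alpha)
  V <- forwardsolve(t(ch), t(Ks))
  s2 <- pmax(1 - colSums(V^2), 1e-12)
  s <- sqrt(s2)
  f_best <- min(ys)
  imp <- f_best - mu
  zed <- imp / s
  imp * stats::pnorm(zed) + s * stats::dnorm(zed)
}

se_kernel <- function(A, B, ell) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-0.5 * pmax(d2, 0) / ell^2)
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
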