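#' One-dimensional fuzzy c-means clustering
#'
#' Clusters a scalar feature into `c` fuzzy subsets. Memberships satisfy the
#' fuzzy c-partition constraints: `u_ik` in \[0, 1\], columns summing to 1,
#' row sums strictly inside `(0, n)`. Initialisation is deterministic
#' (centers at the 10th and 90th percentiles for `c = 2`, equally spaced
#' quantiles otherwise), so results are reproducible without an RNG.
#'
#' @param values Finite numeric vector (length >= `c`, not all identical).
#' @param c Number of clusters (default 2).
#' @param m Fuzzifier exponent > 1 (default 2).
#' @param tol Convergence tolerance on center movement, relative to the
#'   data range (default 1e-5), making the iteration affine-equivariant.
#' @param max_iter Iteration cap (default 100).
#' @return List with `u` (`c x n` membership matrix), `centers`,
#'   `iterations`.
#' @export
fuzzy_cmeans_1d <- function(values, c = 2L, m = 2, tol = 1e-5,
                            max_iter = 100L) {
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  n <- length(values)
  if (n < c) stop("need at least c samples", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("degenerate feature: all values identical", call. = FALSE)
  }
  probs <- if (c == 2L) c(0.1, 0.9) else seq(0.1, 0.9, length.out = c)
  centers <- as.numeric(stats::quantile(values, probs, names = FALSE))
  # quantile collisions (heavily tied data): spread over the range instead
  if (anyDuplicated(centers)) {
    centers <- seq(min(values), max(values), length.out = c + 2)[2:(c + 1)]
  }
  tol_abs <- tol * diff(range(values))
  exp_u <- 2 / (m - 1)
  u <- matrix(0, c, n)
  for (iter in seq_len(max_iter)) {
    d <- abs(outer(centers, values, `-`))            # c x n distances
    inv <- (1 / pmax(d, .Machine$double.xmin))^exp_u
    u <- sweep(inv, 2, colSums(inv), `/`)
    zero_hit <- d < 1e-300
    if (any(zero_hit)) {
      hit_cols <- which(colSums(zero_hit) > 0)
      u[, hit_cols] <- zero_hit[, hit_cols, drop = FALSE] /
        rep(colSums(zero_hit)[hit_cols], each = c)
    }
    um <- u^m
    new_centers <- as.numeric((um %*% values) / rowSums(um))
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < tol_abs) break
  }
  list(u = u, centers = centers, iterations = iter)
}

#' Matching degree of a fuzzy cluster with a class
#'
#' `D_c` is the fraction of a cluster's total membership mass carried by the
#' samples of the target class:
#' `D_c = sum_{k in class} u(k) / sum_k u(k)`, in \[0, 1\].
#'
#' @param u_row Membership vector of one cluster (one row of `u`).
#' @param labels Class label per sample.
#' @param target_class The class whose mass is measured.
#' @return `D_c` in \[0, 1\].
#' @export
matching_degree <- function(u_row, labels, target_class) {
  if (length(u_row) != length(labels)) {
    stop("memberships and labels differ in length", call. = FALSE)
  }
  total <- sum(u_row)
  if (total <= 0) stop("degenerate cluster: zero total membership",
                       call. = FALSE)
  sum(u_row[labels == target_class]) / total
}

#' Fuzzy-entropy component of a matching degree
#'
#' `FE_c = -D_c log2 D_c`, with `FE(0) := 0`. Low values mean the cluster's
#' mass is concentrated in (or absent from) the class, i.e. the feature is
#' informative.
#'
#' @param D_c Matching degree in \[0, 1\].
#' @return `FE_c >= 0`.
#' @export
fuzzy_entropy_component <- function(D_c) {
  if (any(D_c < 0 | D_c > 1)) stop("D_c must lie in [0, 1]", call. = FALSE)
  ifelse(D_c > 0, -D_c * log2(D_c), 0)
}

#' Fuzzy entropy of one feature
#'
#' Runs 1-D fuzzy c-means (`c = 2`) on the feature values, assigns the two
#' clusters to the two classes by the bijection maximising
#' `D_healthy + D_septic`, and returns
#' `FE = FE_healthy + FE_septic` with its components. A feature that
#' cleanly separates the classes has `FE` near 0; a pure-noise feature is
#' near the two-class maximum.
#'
#' @param values Feature values (finite, not all identical).
#' @param labels `"healthy"` / `"septic"` per sample; both classes required.
#' @param ... Passed to [fuzzy_cmeans_1d()].
#' @return List with `fe`, `fe_healthy`, `fe_septic`, `d_healthy`,
#'   `d_septic`, `cluster_class_map`.
#' @export
feature_fe <- function(values, labels, ...) {
  classes <- c("healthy", "septic")
  if (!all(classes %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  cm <- fuzzy_cmeans_1d(values, c = 2L, ...)
  # two candidate bijections cluster -> class
  d11 <- matching_degree(cm$u[1, ], labels, "healthy")
  d22 <- matching_degree(cm$u[2, ], labels, "septic")
  d12 <- matching_degree(cm$u[1, ], labels, "septic")
  d21 <- matching_degree(cm$u[2, ], labels, "healthy")
  if (d11 + d22 >= d12 + d21) {
    map <- c(healthy = 1L, septic = 2L)
    d_h <- d11; d_s <- d22
  } else {
    map <- c(healthy = 2L, septic = 1L)
    d_h <- d21; d_s <- d12
  }
  fe_h <- fuzzy_entropy_component(d_h)
  fe_s <- fuzzy_entropy_component(d_s)
  list(fe = fe_h + fe_s, fe_healthy = fe_h, fe_septic = fe_s,
       d_healthy = d_h, d_septic = d_s, cluster_class_map = map)
}

#' Mean-threshold fuzzy-entropy feature selection
#'
#' Scores every feature column with [feature_fe()], sets the threshold at
#' the mean FE across features, and retains the features with FE strictly
#' below it. Constant (degenerate) columns are assigned the maximal observed
#' FE, guaranteeing their removal. If the strict rule selects nothing (all
#' FE equal), all features are kept with a warning.
#'
#' @param table A `feature_table` with labeled rows.
#' @param ... Passed to [feature_fe()].
#' @return An object of class `fe_selection`: list with `feature`, `fe`,
#'   `fe_healthy`, `fe_septic`, `threshold`, `selected` (logical mask),
#'   `fallback` flag.
#' @export
select_features <- function(table, ...) {
  feats <- feature_names(table)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)
  labels <- table$label
  if (!all(c("healthy", "septic") %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  fe <- fe_h <- fe_s <- rep(NA_real_, length(feats))
  for (j in seq_along(feats)) {
    v <- table[[feats[j]]]
    if (diff(range(v)) == 0) next  # degenerate; patched below
    r <- feature_fe(v, labels, ...)
    fe[j] <- r$fe; fe_h[j] <- r$fe_healthy; fe_s[j] <- r$fe_septic
  }
  if (all(is.na(fe))) {
    warning("all features constant; keeping all", call. = FALSE)
    fe[] <- 0
  }
  degenerate <- is.na(fe)
  fe[degenerate] <- max(fe, na.rm = TRUE)
  threshold <- mean(fe)
  selected <- fe < threshold
  fallback <- !any(selected)
  if (fallback) {
    warning("mean-FE rule selected no features; keeping all", call. = FALSE)
    selected <- rep(TRUE, length(feats))
  }
  structure(
    list(feature = feats, fe = fe, fe_healthy = fe_h, fe_septic = fe_s,
         degenerate = degenerate, threshold = threshold, selected = selected,
         fallback = fallback),
    class = "fe_selection"
  )
}

#' @export
print.fe_selection <- function(x, ...) {
  cat(sprintf("<fe_selection: kept %d/%d features, threshold %.4f%s>\n",
              sum(x$selected), length(x$feature), x$threshold,
              if (x$fallback) " (fallback: empty selection)" else ""))
  invisible(x)
}

#' Apply an FE selection to a feature table
#'
#' @param table A `feature_table`.
#' @param selection An `fe_selection` from [select_features()].
#' @return The table restricted to the selected feature columns.
#' @export
apply_selection <- function(table, selection) {
  keep <- selection$feature[selection$selected]
  out <- table[, c("id", "label", keep), drop = FALSE]
  structure(out, dataset_tag = attr(table, "dataset_tag"),
            class = c("feature_table", "data.frame"))
}

#' Write an FE selection report
#'
#' Delimited text `feature,fe,fe_healthy,fe_septic,selected` preceded by a
#' `#`-commented summary block (threshold, kept/total).
#'
#' @param selection An `fe_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fuzzy-entropy selection report"),
    sprintf("# threshold: %.17g", selection$threshold),
    sprintf("# kept: %d/%d", sum(selection$selected),
            length(selection$feature)),
    "feature,fe,fe_healthy,fe_septic,selected"
  ), con)
  writeLines(sprintf("%s,%.17g,%.17g,%.17g,%s", selection$feature,
                     selection$fe, selection$fe_healthy, selection$fe_septic,
                     ifelse(selection$selected, "TRUE", "FALSE")), con)
  invisible(path)
}
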