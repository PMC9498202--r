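# Fixture builders and independent oracles shared across test files.

# a pure tone segment of given duration
tone_segment <- function(freq, duration_s = 0.05, fs = 44100, id = "tone",
                         type = "EXP", label = "healthy", amp = 0.8) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  cry_segment(id, amp * sin(2 * pi * freq * t), fs, type, label)
}

# a deterministic labeled feature table (no audio involved)
toy_feature_table <- function(n_per_class = 50, n_informative = 2,
                              n_noise = 2, effect = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("healthy", "septic"), each = n_per_class)
  cols <- list()
  for (i in seq_len(n_informative)) {
    cols[[paste0("inf", i)]] <- rnorm(n, ifelse(lab == "septic", effect, 0))
  }
  for (i in seq_len(n_noise)) {
    cols[[paste0("noise", i)]] <- rnorm(n)
  }
  tab <- cbind(data.frame(id = sprintf("s%03d", seq_len(n)), label = lab,
                          stringsAsFactors = FALSE),
               as.data.frame(cols))
  structure(tab, class = c("feature_table", "data.frame"))
}

# brute-force sliding-index frame counter (oracle for the closed formula)
count_frames_brute <- function(n_samples, frame, hop) {
  count <- 0L
  start <- 1L
  while (start + frame - 1L <= n_samples) {
    count <- count + 1L
    start <- start + hop
  }
  count
}

# plain per-pair distance functions, written independently of the package's
# vectorised implementations
oracle_dist <- function(a, b, metric, train_sd = NULL) {
  switch(metric,
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b)),
    chebyshev = max(abs(a - b)),
    minkowski = (sum(abs(a - b)^3))^(1 / 3),
    standardized_euclidean = sqrt(sum(((a - b) / train_sd)^2)),
    cosine = 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))),
    correlation = 1 - cor(a, b),
    hamming = mean(a != b),
    jaccard = {
      s <- a != 0 | b != 0
      if (!any(s)) 0 else mean(a[s] != b[s])
    }
  )
}

# loop-based KNN with the package's tie conventions, built on oracle_dist
oracle_knn <- function(train_X, train_y, query_X, k, metric) {
  train_sd <- apply(train_X, 2, sd)
  sapply(seq_len(nrow(query_X)), function(i) {
    d <- sapply(seq_len(nrow(train_X)), function(j) {
      oracle_dist(query_X[i, ], train_X[j, ], metric, train_sd)
    })
    kth <- sort(d)[k]
    nb <- which(d <= kth)
    tt <- table(train_y[nb])
    winners <- names(tt)[tt == max(tt)]
    if (length(winners) == 1) winners else train_y[nb[which.min(d[nb])]]
  })
}
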