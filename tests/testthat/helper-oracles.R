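# Independent brute-force oracles and tiny fixture builders.
# Oracles deliberately use naive loops / enumeration, never the package's own
# code paths.

make_log <- function(ts, key, type, subject = "s1", state = "rested",
                     repetition = 1L, duration_ms = max(ts)) {
  keystroke_log(
    data.frame(timestamp_ms = ts, key_id = key, event_type = type,
               stringsAsFactors = FALSE),
    subject_id = subject, state = state, repetition = repetition,
    duration_ms = duration_ms
  )
}

random_series <- function(n, t_max = 1000, ht_max = 400) {
  hold_time_series(t = sort(runif(n, 0, t_max)),
                   ht = runif(n, 1, ht_max))
}

# per-sample window assignment, one sample at a time
oracle_partition <- function(t, ht, N, Q, duration_ms) {
  n_win <- ceiling(duration_ms / N)
  out <- rep(list(numeric(0)), n_win)
  for (i in seq_along(t)) {
    w <- min(floor(t[i] / N), n_win - 1) + 1
    out[[w]] <- c(out[[w]], ht[i])
  }
  keep <- which(vapply(out, length, 1L) >= Q)
  list(windows = out[keep], indices = keep - 1L)
}

# per-sample bin counting
oracle_histogram <- function(w, k, M) {
  counts <- numeric(k)
  width <- M / k
  for (h in w) {
    j <- k
    for (b in 1:(k - 1)) {
      if (h >= (b - 1) * width && h < b * width) { j <- b; break }
    }
    counts[j] <- counts[j] + 1
  }
  counts / length(w)
}

oracle_peak <- function(K, k, M) {
  width <- M / k
  reps <- numeric(ncol(K))
  for (j in seq_len(ncol(K))) {
    best <- 1
    for (b in 2:k) if (K[b, j] > K[best, j]) best <- b
    reps[j] <- if (best == k) M + width / 2 else (best - 0.5) * width
  }
  mean(reps)
}

# double-loop pairwise distances
oracle_selfsim <- function(K, L) {
  z <- ncol(K)
  raw <- matrix(0, z, z)
  for (i in seq_len(z)) for (j in seq_len(z))
    raw[i, j] <- sqrt(sum((K[, i] - K[, j])^2))
  list(raw = raw, norm = pmin(raw / L, 1))
}

oracle_offdiag_mean <- function(S) {
  z <- nrow(S); acc <- 0
  for (i in seq_len(z)) for (j in seq_len(z))
    if (i != j) acc <- acc + S[i, j]
  acc / (z * (z - 1))
}

# ROC by exhaustive threshold enumeration (predict positive if score >= thr),
# trapezoid over operating points sorted by fpr
oracle_sweep_auc <- function(scores, positive) {
  thr <- c(sort(unique(scores)), Inf)
  n1 <- sum(positive); n0 <- sum(!positive)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !positive) / n0, tpr = sum(pred & positive) / n1)
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(1, 1), pts)
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  sum(diff(pts[, "fpr"]) * (pts[-1, "tpr"] + pts[-nrow(pts), "tpr"]) / 2)
}

oracle_sector <- function(angle, n_sectors) {
  a <- angle
  while (a <= -pi) a <- a + 2 * pi
  while (a > pi) a <- a - 2 * pi
  breaks <- seq(-pi, pi, length.out = n_sectors + 1)
  for (s in seq_len(n_sectors)) if (a > breaks[s] && a <= breaks[s + 1]) return(s)
  1L
}

# small complete 2x2 feature table for dataset-construction tests
toy_features <- function(n_subjects = 3, seed = 42) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject = sprintf("S%d", seq_len(n_subjects)),
                        state = c("rested", "sleep_inertia"),
                        repetition = 1:2, stringsAsFactors = FALSE)
    grid$khte_peak <- runif(nrow(grid), 80, 140)
    grid$khte_selfsim <- runif(nrow(grid), 0.3, 0.9)
    grid$median_ht <- runif(nrow(grid), 80, 140)
    grid$typing_speed <- runif(nrow(grid), 120, 280)
    grid
  })
}
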