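test_that("partitioning bins samples by floor(t/N) and filters by Q", {
  s <- hold_time_series(t = c(10, 20), ht = c(100, 110))
  ws <- partition_windows(s, khte_params(N = 100, Q = 1), duration_ms = 200)
  expect_equal(length(ws$windows), 1L)
  expect_equal(ws$indices, 0L)
  expect_equal(sort(ws$windows[[1]]), c(100, 110))

  # occupancy filter: sizes (5, 2, 4) with Q = 3 keeps windows 0 and 2
  t <- c(runif(5, 0, 99), runif(2, 100, 199), runif(4, 200, 299))
  s <- hold_time_series(t = t, ht = rep(100, 11))
  ws <- partition_windows(s, khte_params(N = 100, Q = 3), duration_ms = 300)
  expect_equal(ws$indices, c(0L, 2L))
  expect_equal(lengths(ws$windows), c(5L, 4L))

  expect_error(partition_windows(s, khte_params(N = 1000, Q = 1),
                                 duration_ms = 500), "shorter")
})

test_that("partitioning matches a per-sample oracle on random streams", {
  withr::local_seed(21)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    dur <- runif(1, 500, 3000)
    s <- random_series(n, t_max = dur)
    N <- runif(1, 100, dur)
    Q <- sample(1:5, 1)
    ws <- partition_windows(s, khte_params(N = N, Q = Q), duration_ms = dur)
    orc <- oracle_partition(s$t, s$ht, N, Q, dur)
    expect_equal(ws$indices, orc$indices)
    expect_equal(ws$windows, orc$windows)
  }
})

test_that("histogram columns are normalized with an overflow last bin", {
  s <- hold_time_series(t = c(1, 2, 3), ht = c(50, 150, 250))
  fit <- khte(s, khte_params(N = 100, Q = 1, k = 3, M = 300),
              duration_ms = 100)
  expect_equal(dim(fit$K), c(3L, 1L))
  expect_equal(fit$K[, 1], rep(1 / 3, 3))

  # observation above M lands in the last bin
  s <- hold_time_series(t = 1, ht = 500)
  fit <- khte(s, khte_params(N = 100, Q = 1, k = 3, M = 300),
              duration_ms = 100)
  expect_equal(fit$K[, 1], c(0, 0, 1))

  # boundary exactly at an internal edge goes to the upper bin
  s <- hold_time_series(t = c(1, 2), ht = c(100, 99.9999))
  fit <- khte(s, khte_params(N = 100, Q = 1, k = 3, M = 300),
              duration_ms = 100)
  expect_equal(fit$K[, 1], c(0.5, 0.5, 0))
})

test_that("matrix entries match a per-sample counting oracle", {
  withr::local_seed(33)
  for (i in 1:60) {
    k <- sample(2:12, 1); M <- runif(1, 100, 600)
    n <- sample(3:40, 1)
    s <- random_series(n, t_max = 900, ht_max = 1.5 * M)
    fit <- khte(s, khte_params(N = 250, Q = 1, k = k, M = M),
                duration_ms = 1000)
    for (j in seq_len(ncol(fit$K))) {
      w_id <- fit$window_indices[j]
      w <- s$ht[floor(s$t / 250) == w_id]
      expect_equal(fit$K[, j], oracle_histogram(w, k, M))
    }
    expect_equal(colSums(fit$K), rep(1, ncol(fit$K)))
  }
})

test_that("columns are scale-invariant and permutation-invariant", {
  withr::local_seed(5)
  w <- runif(20, 10, 450)
  p <- khte_params(N = 100, Q = 1, k = 10, M = 400)
  one <- function(hts) {
    s <- hold_time_series(t = runif(length(hts), 0, 99), ht = hts)
    khte(s, p, duration_ms = 100)$K[, 1]
  }
  base <- one(w)
  expect_equal(one(sample(w)), base)     # permutation within window
  expect_equal(one(c(w, w)), base)       # duplicating every observation
})

test_that("raising Q never increases the number of retained windows", {
  withr::local_seed(9)
  s <- random_series(200, t_max = 5000)
  z <- vapply(1:12, function(Q) {
    ws <- partition_windows(s, khte_params(N = 500, Q = Q),
                            duration_ms = 5000)
    length(ws$windows)
  }, 1L)
  expect_true(all(diff(z) <= 0))
})

test_that("an empty window set is an actionable error", {
  s <- hold_time_series(t = c(1, 2), ht = c(100, 100))
  expect_error(khte(s, khte_params(N = 100, Q = 30), duration_ms = 200),
               "relax Q")
})

test_that("a KHTE fit round-trips through its text serialization", {
  withr::local_seed(2)
  s <- random_series(300, t_max = 3000)
  fit <- khte(s, khte_params(N = 500, Q = 5, k = 8, M = 350, L = 0.4),
              duration_ms = 3000)
  path <- withr::local_tempfile()
  write_khte(fit, path)
  back <- read_khte(path)
  expect_equal(back$K, fit$K)
  expect_equal(back$bin_edges, fit$bin_edges)
  expect_equal(back$window_indices, fit$window_indices)
  expect_equal(unclass(back$params), unclass(fit$params))
  file.remove(paste0(path, ".json"))
})
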