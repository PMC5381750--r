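make_khte <- function(K, k = nrow(K), M = 500, L = 0.5) {
  structure(
    list(K = K, bin_edges = seq(0, M, length.out = k + 1),
         window_indices = seq_len(ncol(K)) - 1L,
         window_sizes = rep(10L, ncol(K)),
         params = khte_params(N = 60000, Q = 1, k = k, M = M, L = L)),
    class = "khte"
  )
}

test_that("the peak is the mean mode bin center, low bin on ties", {
  # every column peaks in [100, 125) with k = 20, M = 500
  K <- matrix(0, 20, 4); K[5, ] <- 1
  expect_equal(khte_peak(make_khte(K)), 112.5)

  # flat column: tie broken toward the lowest bin
  K <- matrix(1 / 3, 3, 1)
  expect_equal(khte_peak(make_khte(K, M = 300)), 50)

  # overflow bin representative is M + M/(2k)
  K <- matrix(c(0, 0, 1), 3, 1)
  expect_equal(khte_peak(make_khte(K, M = 300)), 300 + 50)
})

test_that("the peak matches an exhaustive argmax oracle on random matrices", {
  withr::local_seed(14)
  for (i in 1:100) {
    k <- sample(2:15, 1); z <- sample(1:8, 1); M <- runif(1, 100, 600)
    K <- matrix(runif(k * z), k, z)
    K <- sweep(K, 2, colSums(K), "/")
    expect_equal(khte_peak(make_khte(K, M = M)), oracle_peak(K, k, M))
  }
})

test_that("self-similarity handles the identity and saturation cases", {
  K <- matrix(rep(c(0.2, 0.3, 0.5), 3), 3, 3)
  s <- self_similarity(make_khte(K, M = 300))
  expect_equal(s$raw, matrix(0, 3, 3))
  expect_equal(s$values, matrix(0, 3, 3))
  expect_equal(khte_selfsim(s), 1)

  K <- cbind(c(1, 0), c(0, 1))
  s <- self_similarity(make_khte(K, M = 300, L = 1))
  expect_equal(s$raw[1, 2], sqrt(2))
  expect_equal(s$values[1, 2], 1)  # saturated
  expect_equal(khte_selfsim(s), 0)

  expect_error(self_similarity(make_khte(matrix(1, 2, 1))), "single window")
})

test_that("self-similarity matches a double-loop distance oracle", {
  withr::local_seed(8)
  for (i in 1:60) {
    k <- sample(2:10, 1); z <- sample(2:7, 1)
    L <- runif(1, 0.05, 1.5)
    K <- matrix(runif(k * z), k, z)
    K <- sweep(K, 2, colSums(K), "/")
    s <- self_similarity(make_khte(K, L = L))
    orc <- oracle_selfsim(K, L)
    expect_equal(s$raw, orc$raw)
    expect_equal(s$values, orc$norm)
    expect_true(isSymmetric(s$values))
    expect_equal(diag(s$values), rep(0, z))
    expect_true(all(s$values >= 0 & s$values <= 1))
    expect_equal(khte_selfsim(s), 1 - oracle_offdiag_mean(orc$norm))
  }
})

test_that("connectivity is row-permutation invariant and monotone in L", {
  withr::local_seed(19)
  K <- matrix(runif(40), 8, 5)
  K <- sweep(K, 2, colSums(K), "/")
  base <- khte_selfsim(self_similarity(make_khte(K)))
  perm <- sample(8)
  expect_equal(khte_selfsim(self_similarity(make_khte(K[perm, ]))), base)

  # large L: no saturation, normalized = raw / L exactly
  raw <- self_similarity(make_khte(K), L = 1)$raw
  big <- max(raw) * 3
  s_big <- self_similarity(make_khte(K), L = big)
  expect_equal(s_big$values, raw / big)

  # K^s is monotone non-decreasing in L, and tends to 0 as L -> 0+
  Ls <- c(1e-6, 0.05, 0.2, 0.5, 2, 10)
  ks <- vapply(Ls, function(L)
    khte_selfsim(self_similarity(make_khte(K), L = L)), 1)
  expect_true(all(diff(ks) >= 0))
  expect_lt(ks[1], 1e-3)
})

test_that("a shared mode bin makes the peak exactly that bin center", {
  K <- matrix(runif(60, 0, 0.3), 10, 6)
  K[4, ] <- 2   # dominant shared mode
  K <- sweep(K, 2, colSums(K), "/")
  fit <- make_khte(K, M = 500)  # k = 10, width 50, bin 4 center = 175
  expect_equal(khte_peak(fit), 175)
})

test_that("delta vectors subtract component-wise with polar bookkeeping", {
  v <- c(khte_peak = 100, khte_selfsim = 0.9)
  vp <- c(khte_peak = 140, khte_selfsim = 0.6)
  d <- delta_vector(v, vp)
  expect_equal(d$d_peak, 40)
  expect_equal(d$d_selfsim, -0.3)
  expect_equal(d$magnitude, sqrt(40^2 + 0.3^2))
  expect_equal(d$angle, atan2(-0.3, 40))

  # zero change: magnitude 0, angle flagged undefined
  d0 <- delta_vector(v, v)
  expect_equal(d0$magnitude, 0)
  expect_true(d0$degenerate)
  expect_true(is.na(d0$angle))

  # unit diagonal: angle pi/4
  d1 <- delta_vector(c(khte_peak = 0, khte_selfsim = 0),
                     c(khte_peak = 1, khte_selfsim = 1))
  expect_equal(d1$angle, pi / 4)

  # orientation flip and peak scaling move only the angle
  d2 <- delta_vector(v, vp, selfsim_orientation = -1, angle_peak_scale = 25)
  expect_equal(d2$d_peak, 40)
  expect_equal(d2$magnitude, d$magnitude)
  expect_equal(d2$angle, atan2(0.3, 40 / 25))
})
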