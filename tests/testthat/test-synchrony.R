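test_that("discretize uses half-open lower-inclusive bins", {
  sch <- partitions_from_labels(c(0, 0.1, 5, 5.1), c(1, 1, 2, 2))
  expect_equal(discretize(c(0, 0.1, 5, 5.1), sch), c(1L, 1L, 2L, 2L))
  # boundary hit goes to the upper bin; out-of-range clamps
  expect_equal(discretize(c(sch$boundaries[1], -100, 100), sch),
               c(2L, 1L, 2L))
  one <- partitions_from_labels(1:3, rep(1, 3))
  expect_equal(discretize(c(-1, 0, 7), one), c(1L, 1L, 1L))
})

test_that("estimate_joint tallies exactly", {
  j <- estimate_joint(c(1, 1, 2, 2), c(1, 1, 2, 2), 2, 2)
  expect_equal(j$table, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  j2 <- estimate_joint(c(1, 2), c(1, 1), 2, 2)
  expect_equal(j2$table, matrix(c(0.5, 0.5, 0, 0), 2, 2))
  expect_error(estimate_joint(1:3, 1:2), "length")

  set.seed(9)
  sx <- sample(1:4, 1000, replace = TRUE)
  sy <- sample(1:3, 1000, replace = TRUE)
  j3 <- estimate_joint(sx, sy, 4, 3)
  tally <- matrix(0, 4, 3)
  for (t in 1:1000) tally[sx[t], sy[t]] <- tally[sx[t], sy[t]] + 1
  expect_equal(j3$table, tally / 1000)
  expect_equal(rowSums(j3$table), j3$marginal_x)
  expect_equal(colSums(j3$table), j3$marginal_y)
  expect_equal(sum(j3$table), 1, tolerance = 1e-12)
})

test_that("entropies and mutual information follow the base-2 definitions", {
  ju <- estimate_joint(c(1, 1, 2, 2), c(1, 2, 1, 2), 2, 2)  # uniform
  expect_equal(unname(entropies(ju)), c(1, 1, 2))

  jd <- estimate_joint(1, 1, 1, 1)                          # degenerate
  expect_equal(unname(entropies(jd)), c(0, 0, 0))

  # table [[0.5, 0], [0.25, 0.25]] (rows = x)
  jm <- estimate_joint(c(1, 1, 2, 2), c(1, 1, 1, 2), 2, 2)
  h <- entropies(jm)
  expect_equal(h[["h_x"]], 1)
  expect_equal(h[["h_y"]], 0.811278, tolerance = 1e-6)
  expect_equal(h[["h_xy"]], 1.5)
  expect_equal(mutual_information(jm), 0.311278, tolerance = 1e-6)

  # perfect dependence and independence
  expect_equal(mutual_information(estimate_joint(c(1, 2), c(1, 2), 2, 2)), 1)
  prod <- estimate_joint(rep(1:2, each = 2), rep(1:2, times = 2), 2, 2)
  expect_equal(mutual_information(prod), 0)

  # symmetry under transpose
  set.seed(1)
  sx <- sample(1:3, 200, replace = TRUE)
  sy <- sample(1:4, 200, replace = TRUE)
  expect_equal(mutual_information(estimate_joint(sx, sy, 3, 4)),
               mutual_information(estimate_joint(sy, sx, 4, 3)),
               tolerance = 1e-12)
})

test_that("apcpmi_pair and uniform_mi_pair agree with the brute-force oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(c(60, 120, 250), 1)
    shared <- rnorm(n)
    x <- shared + rnorm(n, sd = 0.5)
    y <- 0.7 * shared + rnorm(n, sd = 0.8)
    sx <- channel_scheme(x)
    sy <- channel_scheme(y)
    got <- apcpmi_pair(x, y, sx, sy)
    eq <- equalize_partition_counts(sx, sy)
    want <- mi_oracle_bits(discretize(x, eq$x), discretize(y, eq$y))
    expect_equal(got, want, tolerance = 1e-12)

    k <- sample(2:6, 1)
    got_u <- uniform_mi_pair(x, y, k)
    want_u <- mi_oracle_bits(discretize(x, uniform_partition(x, k)),
                             discretize(y, uniform_partition(y, k)))
    expect_equal(got_u, want_u, tolerance = 1e-12)
  }
})

test_that("apcpmi_pair behaves at the dependence extremes", {
  set.seed(2)
  x <- rnorm(500)
  sch <- channel_scheme(x)
  # y = x: MI equals the self-entropy under the scheme
  sym <- discretize(x, sch)
  h_self <- -sum((p <- tabulate(sym, sch$count) / 500)[p > 0] *
                   log2(p[p > 0]))
  expect_equal(apcpmi_pair(x, x, sch, sch), h_self, tolerance = 1e-12)

  # balanced bimodal pair: ~1 bit
  m <- rep(c(0, 10), each = 250)
  xb <- m + rnorm(500, sd = 0.01)
  yb <- m + rnorm(500, sd = 0.01)
  sb_x <- channel_scheme(xb); sb_y <- channel_scheme(yb)
  expect_equal(apcpmi_pair(xb, yb, sb_x, sb_y), 1, tolerance = 0.05)

  # independent channels: below the permutation-null ceiling
  y <- rnorm(500)
  sy <- channel_scheme(y)
  mi_obs <- apcpmi_pair(x, y, sch, sy)
  null_mi <- replicate(30, apcpmi_pair(x, sample(y), sch, sy))
  expect_lte(mi_obs, max(null_mi) + 3 * stats::sd(null_mi))

  # uniform baseline: y = x with distinct values, k = 4 -> 2 bits; k = 1 -> 0
  v <- runif(400)
  expect_equal(uniform_mi_pair(v, v, 4), 2, tolerance = 1e-12)
  expect_identical(uniform_mi_pair(v, v, 1), 0)
})

test_that("build_cmapcpmi is symmetric with self-entropy diagonal and MI bounds hold", {
  set.seed(14)
  shared <- rnorm(256)
  w <- rbind(shared + rnorm(256, sd = 0.3),
             shared + rnorm(256, sd = 0.3),
             rnorm(256),
             rep(1, 256))              # constant channel
  sm <- build_cmapcpmi(w)
  expect_s3_class(sm, "sync_matrix")
  expect_equal(sm$n, 4L)
  expect_identical(sm$values, t(sm$values))
  expect_true(all(sm$values >= 0))
  # constant channel: zero entropy, zero MI with everyone
  expect_equal(unname(sm$values[4, ]), rep(0, 4))
  # MI bounded by the smaller self-entropy
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_lte(sm$values[i, j], min(sm$values[i, i], sm$values[j, j]) + 1e-9)
  # coupled pair more synchronous than independent pair
  expect_gt(sm$values[1, 2], sm$values[1, 3])
  # flattening
  expect_length(flatten_sync(sm), 16L)
  expect_equal(flatten_sync(sm)[2], sm$values[1, 2])

  # two identical channels: off-diagonal equals the diagonal
  w2 <- rbind(shared, shared)
  sm2 <- build_cmapcpmi(w2)
  expect_equal(sm2$values[1, 2], sm2$values[1, 1], tolerance = 1e-12)
})

test_that("partition_sweep reports per-k means and nonnegative spread", {
  set.seed(6)
  shared <- rnorm(128)
  windows <- lapply(1:4, function(i) rbind(shared + rnorm(128, sd = 0.2),
                                           shared + rnorm(128, sd = 0.2),
                                           rnorm(128)))
  sw <- partition_sweep(windows, k_list = c(2, 4))
  expect_equal(sw$summary$k, c(2, 4))
  expect_true(all(sw$summary$avg_sd >= 0))
  expect_equal(dim(sw$mean_matrices[[1]]), c(3, 3))

  # identical-channel windows: off-diagonal ~= log2(k) (self-MI of quantile bins)
  v <- runif(200)
  ident <- list(rbind(v, v), rbind(v, v))
  sw2 <- partition_sweep(ident, k_list = c(2, 4))
  expect_equal(sw2$mean_matrices[[1]][1, 2], 1, tolerance = 1e-9)
  expect_equal(sw2$mean_matrices[[2]][1, 2], 2, tolerance = 1e-9)
})
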