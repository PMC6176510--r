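test_that("default architecture reproduces the reference parameter counts", {
  p <- build_model(clfcnn_config())
  expect_equal(n_parameters(p), 55252L)
  counts <- edge_parameter_counts(p)
  # edges in (from, to) order: input->h1, input->h2, input->out,
  # h1->h2, h1->out, h2->out
  expect_equal(counts$n[counts$from == 1 & counts$to == 2], 42400)
  expect_equal(counts$n[counts$from == 1 & counts$to == 3], 10600)
  expect_equal(counts$n[counts$from == 1 & counts$to == 4], 530)
  expect_equal(counts$n[counts$from == 2 & counts$to == 3], 1620)
  expect_equal(counts$n[counts$from == 2 & counts$to == 4], 81)
  expect_equal(counts$n[counts$from == 3 & counts$to == 4], 21)
})

test_that("parameter count matches brute-force summation for arbitrary widths", {
  set.seed(10)
  for (rep in 1:5) {
    widths <- c(sample(3:30, 1), sample(2:20, sample(1:3, 1)))
    cfg <- clfcnn_config(input_dim = widths[1],
                         hidden_widths = widths[-1], seed = rep)
    p <- build_model(cfg)
    brute <- sum(vapply(p$edges, function(e) length(e$w) + length(e$b),
                        numeric(1)))
    expect_equal(n_parameters(p), as.integer(brute))
  }
  # toy arithmetic 4 -> 2 -> 1: 10 + 5 + 3 = 18
  toy <- build_model(clfcnn_config(input_dim = 4, hidden_widths = 2))
  expect_equal(n_parameters(toy), 18L)
  # adjacent-only wiring drops the skip edges
  adj <- build_model(clfcnn_config(input_dim = 4, hidden_widths = 2,
                                   cross_layer = FALSE))
  expect_equal(n_parameters(adj), 13L)   # 10 + 3
})

test_that("forward pass sums per-edge rectified contributions", {
  cfg <- clfcnn_config(input_dim = 2, hidden_widths = 2, dropout_input = 0,
                       standardize = FALSE)
  p <- build_model(cfg)
  # zero weights -> zero output
  p0 <- p
  for (e in seq_along(p0$edges)) {
    p0$edges[[e]]$w[] <- 0
    p0$edges[[e]]$b[] <- 0
  }
  expect_equal(clfcnn_forward(p0, c(3, -1)), 0)

  # hand-set weights, by-hand evaluation of the cross-layer rule
  # edges: (1,2) input->hidden, (1,3) input->out, (2,3) hidden->out
  ph <- p0
  ph$edges[[1]]$w <- matrix(c(1, 0, -1, 1), 2, 2)  # hidden pre-acts
  ph$edges[[1]]$b <- c(0.5, -0.5)
  ph$edges[[2]]$w <- matrix(c(0.2, -0.3), 2, 1)
  ph$edges[[2]]$b <- 0.1
  ph$edges[[3]]$w <- matrix(c(1, 2), 2, 1)
  ph$edges[[3]]$b <- -0.2
  x <- c(1.5, 2)
  h <- pmax(0, c(1.5 * 1 + 2 * 0 + 0.5, 1.5 * -1 + 2 * 1 - 0.5))
  out_edge_input <- max(0, 1.5 * 0.2 + 2 * -0.3 + 0.1)
  out_edge_hidden <- max(0, h[1] * 1 + h[2] * 2 - 0.2)
  expect_equal(clfcnn_forward(ph, x), out_edge_input + out_edge_hidden)
  # output is a sum of rectified terms, hence nonnegative
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  expect_true(all(clfcnn_forward(p, X) >= 0))
  expect_error(clfcnn_forward(p, c(1, 2, 3)), "dimension")
})

test_that("gradients match central finite differences on random toy nets", {
  set.seed(77)
  worst <- 0
  for (rep in 1:20) {
    cfg <- clfcnn_config(input_dim = sample(3:10, 1),
                         hidden_widths = sample(2:6, sample(1:2, 1)),
                         dropout_input = 0, standardize = FALSE, seed = rep)
    p <- build_model(cfg)
    n <- sample(3:6, 1)
    repeat {  # keep the batch away from rectifier kinks for the FD oracle
      X <- matrix(rnorm(n * cfg$input_dim), n, cfg$input_dim)
      if (min_abs_preact(p, X) > 1e-4) break
    }
    y <- sample(0:1, n, replace = TRUE)
    an <- loss_and_gradients(p, X, y)$gradients
    fd <- fd_gradients(p, X, y)
    worst <- max(worst, max_rel_err(an, fd))
  }
  expect_lt(worst, 1e-5)
})

test_that("loss and gradient edge cases behave", {
  cfg <- clfcnn_config(input_dim = 3, hidden_widths = 2, dropout_input = 0,
                       standardize = FALSE)
  p <- build_model(cfg)
  expect_error(loss_and_gradients(p, matrix(0, 0, 3), numeric(0)),
               "empty batch")
  # a dead unit (negative pre-activation over the whole batch) gets zero
  # gradient on its incoming weights
  pd <- p
  pd$edges[[1]]$w[] <- 0
  pd$edges[[1]]$b <- c(-5, 1)    # unit 1 dead, unit 2 alive
  X <- matrix(abs(rnorm(9)), 3, 3)
  g <- loss_and_gradients(pd, X, c(1, 0, 1))$gradients
  expect_equal(g[[1]]$w[, 1], rep(0, 3))
  expect_equal(g[[1]]$b[1], 0)
})

test_that("momentum update follows the exact element-wise rule", {
  cfg <- clfcnn_config(input_dim = 1, hidden_widths = 1,
                       standardize = FALSE)
  # scalar edge-by-edge check via a 1->1->1 net restricted to one weight
  p <- build_model(cfg)
  for (e in seq_along(p$edges)) { p$edges[[e]]$w[] <- 1; p$edges[[e]]$b[] <- 0 }
  zero_g <- lapply(p$edges, function(e)
    list(w = matrix(0, nrow(e$w), ncol(e$w)), b = numeric(length(e$b))))
  st <- sgd_momentum_step(p, NULL, zero_g, cfg)
  # v' = -wd * eps * w = -2e-4 * 0.01 * 1
  expect_equal(st$params$edges[[1]]$w[1, 1], 1 - 2e-6, tolerance = 1e-15)

  # w = 0: plain gradient step
  p0 <- p
  for (e in seq_along(p0$edges)) p0$edges[[e]]$w[] <- 0
  g <- zero_g; g[[1]]$w[1, 1] <- 3
  st0 <- sgd_momentum_step(p0, NULL, g, cfg)
  expect_equal(st0$params$edges[[1]]$w[1, 1], -0.01 * 3)

  # two consecutive steps match the hand-iterated recursion
  w <- 1; v <- 0; g_val <- 0.5
  for (i in 1:2) { v <- 0.9 * v - 2e-4 * 0.01 * w - 0.01 * g_val; w <- w + v }
  p1 <- p
  gg <- zero_g; gg[[1]]$w[1, 1] <- g_val
  s1 <- sgd_momentum_step(p1, NULL, gg, cfg)
  s2 <- sgd_momentum_step(s1$params, s1$state, gg, cfg)
  expect_equal(s2$params$edges[[1]]$w[1, 1], w, tolerance = 1e-12)

  # wd = 0, momentum = 0 reduces to vanilla gradient descent
  cfgv <- clfcnn_config(input_dim = 1, hidden_widths = 1, momentum = 0,
                        weight_decay = 0, standardize = FALSE)
  sv <- sgd_momentum_step(p, NULL, gg, cfgv)
  expect_equal(sv$params$edges[[1]]$w[1, 1], 1 - 0.01 * g_val)
})

test_that("training separates two Gaussian clusters and history is consistent", {
  set.seed(5)
  X <- rbind(matrix(rnorm(100 * 10, mean = 0), 100, 10),
             matrix(rnorm(100 * 10, mean = 3), 100, 10))
  y <- rep(c(0, 1), each = 100)
  cfg <- clfcnn_config(input_dim = 10, hidden_widths = c(8, 4),
                       patience = 300, seed = 3)
  f <- clfcnn_fit(X, y, cfg)
  expect_gte(max(f$history$acc), 0.99)
  expect_lte(nrow(f$history), cfg$max_epochs)
  expect_equal(nrow(f$history), max(f$history$epoch))
  expect_false(anyNA(f$history$acc))
  # first-10-step loss decrease on a fixed batch at a small learning rate
  cfg2 <- clfcnn_config(input_dim = 10, hidden_widths = c(8, 4),
                        learning_rate = 1e-4, momentum = 0,
                        dropout_input = 0, standardize = FALSE, seed = 4)
  p <- build_model(cfg2)
  losses <- numeric(10)
  st <- NULL
  for (i in 1:10) {
    lg <- loss_and_gradients(p, X[96:105, ], y[96:105])
    losses[i] <- lg$loss
    up <- sgd_momentum_step(p, st, lg$gradients, cfg2)
    p <- up$params; st <- up$state
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("prediction respects the threshold and input order", {
  cfg <- clfcnn_config(input_dim = 2, hidden_widths = 2, standardize = FALSE)
  p <- build_model(cfg)
  for (e in seq_along(p$edges)) { p$edges[[e]]$w[] <- 0; p$edges[[e]]$b[] <- 0 }
  expect_equal(clfcnn_predict(p, c(1, 1)), 0L)          # output 0 -> negative
  p$edges[[2]]$b <- 0.7                                  # constant output 0.7
  expect_equal(clfcnn_predict(p, c(1, 1)), 1L)
  X <- matrix(rnorm(10), 5, 2)
  expect_length(clfcnn_predict(p, X), 5L)
})

test_that("split_and_crossvalidate partitions reproducibly in 64/16/20", {
  set.seed(2)
  X <- matrix(rnorm(100 * 4), 100, 4)
  X[51:100, ] <- X[51:100, ] + 3
  y <- rep(c(0, 1), each = 50)
  cfg <- clfcnn_config(input_dim = 4, hidden_widths = c(6, 3),
                       patience = 100, max_epochs = 300, seed = 1)
  cv <- split_and_crossvalidate(X, y, cfg, split_seed = 7)
  expect_length(cv$splits$train, 64)
  expect_length(cv$splits$val, 16)
  expect_length(cv$splits$test, 20)
  expect_length(intersect(cv$splits$train, cv$splits$test), 0)
  pool <- c(cv$splits$train, cv$splits$val)
  expect_setequal(c(pool, cv$splits$test), 1:100)
  cv2 <- split_and_crossvalidate(X, y, cfg, split_seed = 7)
  expect_identical(cv$splits, cv2$splits)
  expect_length(cv$fold_metrics, 5L)
  expect_gte(cv$test_metrics$accuracy, 0.9)
})
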