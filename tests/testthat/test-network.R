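test_that("forward pass honors the activation and gradient factor", {
  cfg <- network_config(3, "logistic", n_in = 3, n_out = 5)
  w0 <- network_weights(W = matrix(0, 3, 3), V = matrix(0, 5, 3),
                        theta_hidden = rep(0, 3), theta_out = rep(0, 5))
  # zero net input -> 0.5 for any input and lambda
  for (lam in c(1, 4, 100)) {
    out <- forward_pass(w0, cfg, c(0.2, 0.5, 0.9), lambda = lam)$output
    expect_equal(unname(out[1, ]), rep(0.5, 5))
  }

  # growing lambda drives a fixed nonzero net input monotonically to 0.5
  cfg1 <- network_config(1, "logistic", n_in = 1, n_out = 1)
  w1 <- network_weights(W = matrix(1), V = matrix(1),
                        theta_hidden = 0, theta_out = 0)
  outs <- vapply(c(1, 2, 4, 8, 16),
                 function(l) forward_pass(w1, cfg1, 2, lambda = l)$output[1],
                 numeric(1))
  expect_true(all(diff(outs) < 0))
  expect_true(all(outs > 0.5))

  # shape mismatch is a structural error
  expect_error(forward_pass(w1, cfg, c(1, 2, 3)), "shape")
})

test_that("per-sample error matches hand-computed example-prediction rows", {
  pe <- prediction_examples()
  actual <- as.matrix(pe[, 1:5])
  expected <- as.matrix(pe[, 6:10])
  # frozen oracle: explicit sums of five squared differences per row
  frozen <- c("1" = 0.01477745, "2" = 0.18993219, "3" = 0.05447459,
              "15" = 0.05229155)
  for (r in names(frozen)) {
    i <- as.integer(r)
    expect_equal(sample_error(expected[i, ], actual[i, ]), frozen[[r]],
                 tolerance = 1e-9)
  }
  expect_equal(sample_error(actual[1, ], actual[1, ]), 0)
  expect_equal(sample_error(c(1, 0, 0, 0, 0), rep(0, 5)), 1)
  expect_error(sample_error(1:3, 1:5), "equal length")
})

test_that("aggregate error squares E_p again in the printed metric", {
  expect_equal(total_mse(c(0.1, 0.3)), (0.01 + 0.09) / 2)
  expect_equal(total_mse(0.2), 0.04)                 # single sample: e^2
  expect_equal(total_mse(c(0, 0, 0)), 0)
  expect_equal(total_mse(c(0.1, 0.3), metric = "mean_ep"), 0.2)
  expect_error(total_mse(numeric(0)), "at least one")
})

test_that("analytic backprop gradient matches central finite differences", {
  for (act in c("logistic", "tangent")) {
    for (lam in c(1, 4)) {
      cfg <- network_config(3, act, n_in = 2, n_out = 2)
      w <- random_weights(cfg, seed = match(act, c("logistic", "tangent")))
      set.seed(99)
      x <- matrix(stats::rnorm(12), 6, 2)
      y <- matrix(stats::runif(12), 6, 2)
      g <- shadematch:::network_gradient(w, cfg, x, y, lambda = lam)
      analytic <- flatten_blocks(g$grad)
      numeric_g <- fd_gradient(w, cfg, x, y, lambda = lam)
      expect_lt(max(abs(analytic - numeric_g) / (abs(numeric_g) + 1e-8)),
                1e-6)
    }
  }
})

test_that("momentum accumulates past adjustments geometrically", {
  # with a constant gradient g and alpha, the recursion
  # delta_t = -eta*g + alpha*delta_{t-1} gives
  # delta_t = -eta*g*(1 + alpha + ... + alpha^(t-1))
  g <- list(W = matrix(2, 1, 1), V = matrix(-1, 1, 1),
            theta_hidden = 3, theta_out = 0.5)
  eta <- 0.1; alpha <- 0.5
  prev <- list(W = matrix(0, 1, 1), V = matrix(0, 1, 1),
               theta_hidden = 0, theta_out = 0)
  for (t in 1:4) {
    prev <- shadematch:::momentum_delta(g, prev, eta, alpha)
    series <- sum(alpha^(0:(t - 1)))
    expect_equal(prev$W[1, 1], -eta * 2 * series)
    expect_equal(prev$theta_hidden, -eta * 3 * series)
  }
  # alpha = 0 reduces to the plain gradient step
  plain <- shadematch:::momentum_delta(g, prev, eta, 0)
  expect_equal(plain$V[1, 1], eta * 1)
})

test_that("invalid adjustments are rolled back and eta shrinks by beta", {
  # force a rollback: targets sit at the logistic midpoint, so the huge
  # first step saturates every output away from them and the error rises
  d <- tiny_dataset()
  cfg <- network_config(3, "logistic")
  nrm <- fit_normalizer(d, 0.1, 0.9)
  x <- normalize_lab(nrm, d$lab)
  y <- matrix(0.5, nrow(x), 5)
  init <- random_weights(cfg, 4)
  ctl <- gd_control(eta0 = 1e6, beta = 0.7, max_epochs = 1L)
  fit <- train_gd(x, y, cfg, ctl, init = init)
  # the oversized step must have been regarded as invalid: weights
  # bit-identical to the initial ones, eta multiplied by beta
  expect_identical(fit$weights$W, init$W)
  expect_identical(fit$weights$theta_out, init$theta_out)
  expect_equal(fit$eta_final, 1e6 * 0.7)

  # valid step: eta grows by theta and weights move
  ctl2 <- gd_control(eta0 = 0.1, theta = 1.05, max_epochs = 1L)
  fit2 <- train_gd(x, y, cfg, ctl2, init = init)
  expect_equal(fit2$eta_final, 0.1 * 1.05)
  expect_false(identical(fit2$weights$W, init$W))

  # eta never exceeds eta0 * theta^epochs (property)
  ctl3 <- gd_control(eta0 = 0.3, max_epochs = 50L)
  fit3 <- train_gd(x, y, cfg, ctl3, init = init)
  expect_lte(fit3$eta_final, 0.3 * 1.05^50 + 1e-12)
})

test_that("flat-area rule boosts lambda only when flat but unconverged", {
  fa <- list(grad_tol = 1e-6, residual_tol = 0.1, lambda_boost = 4)
  expect_equal(flat_area_lambda(1e-8, 0.3, fa), 4)   # flat, residual large
  expect_equal(flat_area_lambda(0.5, 0.3, fa), 1)    # error still moving
  expect_equal(flat_area_lambda(1e-8, 0.01, fa), 1)  # converged, stays 1
})

test_that("training descends, stops at the goal, and is deterministic", {
  # XOR-style 4-point toy problem
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- matrix(c(0.1, 0.9, 0.9, 0.1), 4, 1)
  cfg <- network_config(3, "tangent", n_in = 2, n_out = 1)
  fit <- train_gd(x, y, cfg, gd_control(max_epochs = 300), seed = 8)
  expect_lt(tail(fit$history, 1), fit$history[1])

  # goal above the starting error stops after one epoch
  quick <- train_gd(x, y, cfg, gd_control(goal_error = 1e6, max_epochs = 50),
                    seed = 8)
  expect_equal(quick$epochs, 1L)
  expect_true(quick$converged)

  # identical seeds give bitwise-identical histories
  fit2 <- train_gd(x, y, cfg, gd_control(max_epochs = 300), seed = 8)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
})

test_that("vanilla-mode training follows a textbook gradient-descent oracle", {
  # alpha = 0, adaptive off, lambda = 1 must reproduce plain GD exactly
  x <- rbind(c(0.2, 0.8), c(0.6, 0.4), c(0.9, 0.1))
  y <- matrix(c(0.2, 0.5, 0.7), 3, 1)
  cfg <- network_config(2, "logistic", n_in = 2, n_out = 1)
  init <- random_weights(cfg, 21)
  eta <- 0.3
  fit <- train_gd(x, y, cfg,
                  gd_control(eta0 = eta, alpha = 0, adaptive = FALSE,
                             max_epochs = 5L),
                  init = init)
  # oracle: iterate p <- p - eta * fd_gradient(p) from the same start;
  # train_gd returns the best iterate, so compare against the oracle's best
  p <- encode_weights(init)
  objective <- function(v) {
    mean((y - forward_pass(decode_weights(v, cfg), cfg, x)$output)^2)
  }
  iterates <- vector("list", 5L)
  for (i in 1:5) {
    w <- decode_weights(p, cfg)
    p <- p - eta * fd_gradient(w, cfg, x, y)
    iterates[[i]] <- p
  }
  best <- iterates[[which.min(vapply(iterates, objective, numeric(1)))]]
  expect_equal(encode_weights(fit$weights), best, tolerance = 1e-6)
})
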