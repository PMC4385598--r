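#' Network architecture configuration
#'
#' Describes the three-layer feed-forward network: 3 color inputs, `n_hidden`
#' hidden neurons, 5 powder-fraction outputs. The activation applies to both
#' the hidden and output layers. `lambda` is the gradient factor: the net
#' input of every neuron is divided by `lambda` before the activation, so
#' values above 1 flatten the saturation zones (used to escape error-surface
#' plateaus); during normal operation `lambda = 1`.
#'
#' @param n_hidden Number of hidden-layer neurons.
#' @param activation `"logistic"` (output in (0,1)), `"tangent"`
#'   (tanh, output in (-1,1)), or `"linear"` (identity; a testing hook for
#'   closed-form checks, not used by the shipped training profiles).
#' @param n_in,n_out Input and output widths; 3 and 5 for color matching.
#' @param lambda Gradient factor, >= 1.
#' @return A `ccm_network_config`.
#' @export
network_config <- function(n_hidden, activation = c("logistic", "tangent",
                                                    "linear"),
                           n_in = 3L, n_out = 5L, lambda = 1) {
  activation <- match.arg(activation)
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  n_hidden <- as.integer(n_hidden)
  if (n_in < 1L || n_hidden < 1L || n_out < 1L) {
    stop("all layer widths must be >= 1")
  }
  if (!is.numeric(lambda) || lambda < 1) stop("`lambda` must be >= 1")
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 activation = activation, lambda = as.numeric(lambda)),
            class = "ccm_network_config")
}

#' @export
print.ccm_network_config <- function(x, ...) {
  cat(sprintf("<network %d-%d-%d, %s activation, lambda = %g>\n",
              x$n_in, x$n_hidden, x$n_out, x$activation, x$lambda))
  invisible(x)
}

#' Number of free parameters of a network
#'
#' `n_in * h + h * n_out + h + n_out`: the two weight matrices plus the
#' hidden and output thresholds (113 for the 3-12-5 network).
#'
#' @param cfg A `ccm_network_config`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(cfg) {
  with(cfg, n_in * n_hidden + n_hidden * n_out + n_hidden + n_out)
}

#' Construct or randomly initialize network weights
#'
#' The four parameter blocks: `W` (hidden x in) input-to-hidden weights, `V`
#' (out x hidden) hidden-to-output weights, and the two threshold vectors.
#' Net input convention: `net = weights %*% previous_layer - threshold`.
#'
#' @param W,V Weight matrices with shapes `h x n_in` and `n_out x h`.
#' @param theta_hidden,theta_out Threshold vectors of lengths `h`, `n_out`.
#' @return A `ccm_weights` object.
#' @export
network_weights <- function(W, V, theta_hidden, theta_out) {
  W <- as.matrix(W); V <- as.matrix(V)
  theta_hidden <- as.numeric(theta_hidden)
  theta_out <- as.numeric(theta_out)
  if (nrow(V) < 1L || ncol(V) != nrow(W)) {
    stop("shape mismatch: ncol(V) must equal nrow(W) (hidden width)")
  }
  if (length(theta_hidden) != nrow(W)) {
    stop("theta_hidden length must equal the hidden width")
  }
  if (length(theta_out) != nrow(V)) {
    stop("theta_out length must equal the output width")
  }
  vals <- c(W, V, theta_hidden, theta_out)
  if (!all(is.finite(vals))) stop("all weight entries must be finite")
  structure(list(W = W, V = V, theta_hidden = theta_hidden,
                 theta_out = theta_out),
            class = "ccm_weights")
}

#' @rdname network_weights
#' @param cfg A `ccm_network_config`.
#' @param seed Integer seed for reproducible initialization.
#' @param range Interval for the uniform draw, default `[-0.5, 0.5]`.
#' @export
random_weights <- function(cfg, seed, range = c(-0.5, 0.5)) {
  stopifnot(inherits(cfg, "ccm_network_config"))
  set.seed(as.integer(seed))
  draw <- function(n) stats::runif(n, range[1], range[2])
  network_weights(
    W = matrix(draw(cfg$n_hidden * cfg$n_in), cfg$n_hidden, cfg$n_in),
    V = matrix(draw(cfg$n_out * cfg$n_hidden), cfg$n_out, cfg$n_hidden),
    theta_hidden = draw(cfg$n_hidden),
    theta_out = draw(cfg$n_out)
  )
}

check_shapes <- function(w, cfg) {
  if (nrow(w$W) != cfg$n_hidden || ncol(w$W) != cfg$n_in ||
      nrow(w$V) != cfg$n_out || ncol(w$V) != cfg$n_hidden) {
    stop("weight shapes do not match the network configuration")
  }
  invisible(TRUE)
}

activate <- function(net, activation, lambda) {
  z <- net / lambda
  switch(activation,
         logistic = 1 / (1 + exp(-z)),
         tangent = tanh(z),
         linear = z)
}

# derivative d o / d net expressed through the activation output o
# (preserves the shape of o)
activate_deriv <- function(o, activation, lambda) {
  switch(activation,
         logistic = o * (1 - o) / lambda,
         tangent = (1 - o^2) / lambda,
         linear = (o * 0 + 1) / lambda)
}

#' Forward pass through the network
#'
#' Computes `o_k = f(net_k / lambda)` layer by layer with
#' `net = weights %*% input - threshold`. Accepts a single 3-vector or an
#' n x 3 matrix of (normalized) inputs and returns the intermediates needed
#' for backpropagation.
#'
#' @param w A `ccm_weights`.
#' @param cfg A `ccm_network_config`.
#' @param x Input vector of length `n_in` or matrix with `n_in` columns.
#' @param lambda Optional gradient-factor override (defaults to
#'   `cfg$lambda`).
#' @return List with `output` (n x n_out), `hidden` (n x h), and the raw net
#'   inputs `net_hidden`, `net_out`.
#' @export
forward_pass <- function(w, cfg, x, lambda = cfg$lambda) {
  stopifnot(inherits(w, "ccm_weights"), inherits(cfg, "ccm_network_config"))
  check_shapes(w, cfg)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != cfg$n_in) {
    stop("input has ", ncol(x), " columns; network expects ", cfg$n_in)
  }
  net_h <- sweep(x %*% t(w$W), 2, w$theta_hidden)
  hidden <- activate(net_h, cfg$activation, lambda)
  net_o <- sweep(hidden %*% t(w$V), 2, w$theta_out)
  output <- activate(net_o, cfg$activation, lambda)
  list(output = output, hidden = hidden, net_hidden = net_h, net_out = net_o)
}

#' Per-sample prediction error
#'
#' The error of one sample is the sum of squared differences between the
#' expected and actual output vectors:
#' `E_p = sum_k (d_k - o_k)^2`.
#'
#' @param expected,actual Numeric vectors of equal length (expected = target
#'   recipe, actual = network output).
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @export
sample_error <- function(expected, actual) {
  if (length(expected) != length(actual)) {
    stop("expected and actual outputs must have equal length")
  }
  sum((expected - actual)^2)
}

#' Aggregate error over a set of samples
#'
#' The headline metric squares each per-sample error again before averaging:
#' `E_MSE = mean(E_p^2)` (`metric = "printed"`, the default). The
#' conventional mean of the per-sample errors is available with
#' `metric = "mean_ep"`.
#'
#' @param errors Numeric vector of per-sample errors `E_p` (see
#'   [sample_error()]).
#' @param metric `"printed"` (mean of squared `E_p`) or `"mean_ep"`.
#' @return Scalar aggregate error.
#' @export
total_mse <- function(errors, metric = c("printed", "mean_ep")) {
  metric <- match.arg(metric)
  if (length(errors) < 1L) stop("`errors` must contain at least one value")
  if (metric == "printed") mean(errors^2) else mean(errors)
}

#' Per-sample errors of a prediction matrix
#'
#' @param expected,actual n x m matrices of targets and outputs.
#' @return Numeric n-vector of `E_p` values.
#' @export
sample_errors <- function(expected, actual) {
  expected <- as.matrix(expected); actual <- as.matrix(actual)
  if (!all(dim(expected) == dim(actual))) {
    stop("expected and actual matrices must have identical shapes")
  }
  rowSums((expected - actual)^2)
}

# Training objective: mean squared error over samples x outputs,
# J = sum((d - o)^2) / (n * m). Scale-free in the problem size so the same
# learning-rate defaults work for any batch.
mse_objective <- function(output, target) {
  mean((target - output)^2)
}

# Full-batch gradient of the training objective with respect to all four
# parameter blocks. Returns the gradient blocks, the objective value, and
# the output matrix (residuals are reused by the flat-area rule).
network_gradient <- function(w, cfg, x, target, lambda = cfg$lambda) {
  fp <- forward_pass(w, cfg, x, lambda = lambda)
  n <- nrow(x); m <- cfg$n_out
  resid <- fp$output - target                       # n x m
  d_out <- 2 * resid / (n * m)                      # dJ/dO
  s_out <- activate_deriv(fp$output, cfg$activation, lambda)
  delta_out <- d_out * s_out                        # dJ/dnet_out, n x m
  s_hid <- activate_deriv(fp$hidden, cfg$activation, lambda)
  delta_hid <- (delta_out %*% w$V) * s_hid          # n x h
  list(
    grad = list(W = t(delta_hid) %*% x,
                V = t(delta_out) %*% fp$hidden,
                theta_hidden = -colSums(delta_hid),
                theta_out = -colSums(delta_out)),
    value = mean(resid^2),
    output = fp$output
  )
}

# elementwise arithmetic over the four parameter blocks
blocks_map <- function(f, ...) {
  args <- list(...)
  out <- lapply(c("W", "V", "theta_hidden", "theta_out"), function(nm) {
    do.call(f, lapply(args, `[[`, nm))
  })
  names(out) <- c("W", "V", "theta_hidden", "theta_out")
  out
}

zero_blocks <- function(w) {
  blocks_map(function(b) b * 0, w)
}

apply_delta <- function(w, delta) {
  network_weights(W = w$W + delta$W, V = w$V + delta$V,
                  theta_hidden = w$theta_hidden + delta$theta_hidden,
                  theta_out = w$theta_out + delta$theta_out)
}
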