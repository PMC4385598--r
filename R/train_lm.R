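#' Levenberg-Marquardt control parameters
#'
#' Classic Marquardt damping schedule: start at `mu0`, multiply by
#' `mu_up` on a rejected step, divide by `mu_down` on an accepted one; stop
#' on `max_iter`, on a gradient infinity-norm below `grad_tol`, or when
#' `mu` overflows `mu_max`.
#'
#' @param mu0 Initial damping.
#' @param mu_up,mu_down Damping multipliers (reject / accept).
#' @param mu_max Damping ceiling; exceeding it stops the run.
#' @param max_iter Maximum accepted-or-rejected iterations.
#' @param grad_tol Stop when `max(abs(J' r))` falls below this.
#' @return A `ccm_lm_control` list.
#' @export
lm_control <- function(mu0 = 1e-3, mu_up = 10, mu_down = 10, mu_max = 1e10,
                       max_iter = 100L, grad_tol = 1e-10) {
  stopifnot(mu0 > 0, mu_up > 1, mu_down > 1, mu_max > mu0, max_iter >= 1)
  structure(list(mu0 = mu0, mu_up = mu_up, mu_down = mu_down,
                 mu_max = mu_max, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol),
            class = "ccm_lm_control")
}

# Flatten the four parameter blocks to the canonical vector:
# W row-major, V row-major, theta_hidden, theta_out.
flatten_weights <- function(w) {
  c(as.vector(t(w$W)), as.vector(t(w$V)), w$theta_hidden, w$theta_out)
}

unflatten_weights <- function(v, cfg) {
  h <- cfg$n_hidden; ni <- cfg$n_in; no <- cfg$n_out
  sizes <- c(h * ni, no * h, h, no)
  if (length(v) != sum(sizes)) {
    stop("parameter vector has length ", length(v), "; network needs ",
         sum(sizes))
  }
  ends <- cumsum(sizes)
  network_weights(
    W = matrix(v[seq_len(ends[1])], h, ni, byrow = TRUE),
    V = matrix(v[(ends[1] + 1):ends[2]], no, h, byrow = TRUE),
    theta_hidden = v[(ends[2] + 1):ends[3]],
    theta_out = v[(ends[3] + 1):ends[4]]
  )
}

# Residual vector r = d - o stacked sample-major (all outputs of sample 1,
# then sample 2, ...), and its analytic Jacobian with respect to the
# flattened parameters. dr/dp = -do/dp.
lm_residual_jacobian <- function(w, cfg, x, y, lambda = cfg$lambda) {
  fp <- forward_pass(w, cfg, x, lambda = lambda)
  n <- nrow(x); h <- cfg$n_hidden; ni <- cfg$n_in; no <- cfg$n_out
  npar <- ni * h + h * no + h + no
  s_out <- activate_deriv(fp$output, cfg$activation, lambda)  # n x no
  s_hid <- activate_deriv(fp$hidden, cfg$activation, lambda)  # n x h
  J <- matrix(0, n * no, npar)
  iW <- seq_len(h * ni)
  iV <- h * ni + seq_len(no * h)
  ith <- h * ni + no * h + seq_len(h)
  ito <- h * ni + no * h + h + seq_len(no)
  for (p in seq_len(n)) {
    rows <- (p - 1L) * no + seq_len(no)
    # do_k/dy_j = s_out_k * V[k, j]; dy_j/dW[j, i] = s_hid_j * x_i
    A <- s_out[p, ] * w$V                       # no x h
    B <- A * rep(s_hid[p, ], each = no)         # no x h: do_k/dnet_hid_j
    # W block, row-major: index (j - 1) * ni + i
    for (j in seq_len(h)) {
      J[rows, (j - 1L) * ni + seq_len(ni)] <- -outer(B[, j], x[p, ])
    }
    # V block, row-major: index (k - 1) * h + j -> do_k/dV[k, j] = s_out_k * y_j
    for (k in seq_len(no)) {
      J[rows[k], iV[(k - 1L) * h + seq_len(h)]] <-
        -s_out[p, k] * fp$hidden[p, ]
    }
    J[rows, ith] <- B          # do_k/dtheta_h_j = -B => dr = +B
    J[rows, ito] <- diag(s_out[p, ], no, no)  # dr/dtheta_o_k = +s_out_k
  }
  list(r = as.vector(t(y - fp$output)), J = J, output = fp$output)
}

#' Train a network by damped Gauss-Newton (Levenberg-Marquardt)
#'
#' Minimizes the sum of squared residuals over all samples and outputs by
#' solving `(J'J + mu I) step = J' r` with the analytic residual Jacobian.
#' A step is accepted (and `mu` decreased) only if it lowers the SSE, so
#' the accepted-step error sequence is strictly decreasing.
#'
#' @param x n x n_in matrix of normalized inputs.
#' @param y n x n_out matrix of targets.
#' @param cfg A `ccm_network_config`.
#' @param init Initial `ccm_weights`.
#' @param control An [lm_control()].
#' @return List with `weights`, `history` (SSE after each accepted step,
#'   starting from the initial SSE), `iterations`, and `converged`.
#' @export
train_lm <- function(x, y, cfg, init, control = lm_control()) {
  stopifnot(inherits(cfg, "ccm_network_config"),
            inherits(init, "ccm_weights"),
            inherits(control, "ccm_lm_control"))
  x <- as.matrix(x); y <- as.matrix(y)
  check_shapes(init, cfg)
  w <- init
  p <- flatten_weights(w)
  mu <- control$mu0
  rj <- lm_residual_jacobian(w, cfg, x, y)
  sse <- sum(rj$r^2)
  history <- sse
  converged <- FALSE

  for (iter in seq_len(control$max_iter)) {
    g <- crossprod(rj$J, rj$r)
    if (max(abs(g)) < control$grad_tol) { converged <- TRUE; break }
    JtJ <- crossprod(rj$J)
    step <- tryCatch(
      solve(JtJ + mu * diag(nrow(JtJ)), g),
      error = function(e) NULL
    )
    if (is.null(step)) {
      if (mu >= control$mu_max) {
        stop("singular normal equations at the damping ceiling")
      }
      mu <- mu * control$mu_up
      next
    }
    p_new <- p - as.vector(step)  # descent: J here is dr/dp
    w_new <- unflatten_weights(p_new, cfg)
    r_new <- as.vector(t(y - forward_pass(w_new, cfg, x)$output))
    sse_new <- sum(r_new^2)
    if (is.finite(sse_new) && sse_new < sse) {
      p <- p_new; w <- w_new; sse <- sse_new
      history <- c(history, sse)
      mu <- mu / control$mu_down
      rj <- lm_residual_jacobian(w, cfg, x, y)
    } else {
      mu <- mu * control$mu_up
      if (mu > control$mu_max) break
    }
  }

  list(weights = w, history = history, iterations = length(history) - 1L,
       converged = converged, sse = sse)
}
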