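#' Gradient-descent training control parameters
#'
#' Governs the improved backpropagation loop: momentum, the adaptive
#' learning-efficiency schedule, and the flat-area gradient factor.
#'
#' Momentum adds a fraction `alpha` of the previous adjustment to the
#' current one: `delta_t = eta * (-gradient) + alpha * delta_{t-1}`. The
#' adaptive schedule watches the total error after each full-batch step: if
#' it rose, the step is regarded as invalid — the weights are rolled back
#' and `eta` shrinks by `beta`; if it fell, the step stands and `eta` grows
#' by `theta`. The flat-area rule raises the gradient factor `lambda` above
#' 1 when the error change is nearly zero while residuals are still large
#' (a plateau, not convergence), and resets it to 1 once the error moves
#' again.
#'
#' @param eta0 Initial learning efficiency, > 0.
#' @param alpha Momentum coefficient in (0, 1); 0 disables momentum.
#' @param beta Learning-rate decrease factor in (0, 1).
#' @param theta Learning-rate increase factor, > 1.
#' @param adaptive Logical; enable the error-watching schedule (with step
#'   rollback). When `FALSE`, `eta` stays at `eta0` and every step stands.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param goal_error Stop once the total training error (sum of the
#'   per-sample errors `E_p` over the batch, at the operational
#'   gradient factor `lambda = 1`) falls to this value or below.
#' @param flat_area List with `enabled`, `grad_tol` (error-change threshold
#'   below which the surface counts as flat), `residual_tol` (a residual
#'   above this means training has not converged), and `lambda_boost`
#'   (gradient factor applied while trapped in the flat area).
#' @return A `ccm_gd_control` list.
#' @export
gd_control <- function(eta0 = 0.5, alpha = 0.9, beta = 0.7, theta = 1.05,
                       adaptive = TRUE, max_epochs = 500L, goal_error = 0,
                       flat_area = list(enabled = FALSE, grad_tol = 1e-6,
                                        residual_tol = 0.1,
                                        lambda_boost = 4)) {
  stopifnot(eta0 > 0, alpha >= 0, alpha < 1, beta > 0, beta < 1, theta > 1,
            max_epochs >= 1, goal_error >= 0)
  fa <- utils::modifyList(list(enabled = FALSE, grad_tol = 1e-6,
                               residual_tol = 0.1, lambda_boost = 4),
                          flat_area)
  stopifnot(fa$lambda_boost > 1, fa$grad_tol > 0, fa$residual_tol > 0)
  structure(list(eta0 = eta0, alpha = alpha, beta = beta, theta = theta,
                 adaptive = adaptive, max_epochs = as.integer(max_epochs),
                 goal_error = goal_error, flat_area = fa),
            class = "ccm_gd_control")
}

#' Named training profiles
#'
#' Two presets bundle an activation with a training control:
#' * `"bp_improved"` — tangent activation, momentum plus adaptive learning
#'   efficiency (the improved plain-BP configuration).
#' * `"gabp_paper"` — logistic activation, momentum, adaptive learning
#'   efficiency and the flat-area gradient factor; intended to be paired
#'   with GA-optimized initial weights.
#'
#' @param profile Profile name.
#' @param ... Overrides passed to [gd_control()].
#' @return List with `activation` and `control`.
#' @export
training_profile <- function(profile = c("bp_improved", "gabp_paper"), ...) {
  profile <- match.arg(profile)
  overrides <- list(...)
  base <- switch(profile,
    bp_improved = list(activation = "tangent",
                       control = list(adaptive = TRUE)),
    gabp_paper = list(activation = "logistic",
                      control = list(adaptive = TRUE,
                                     flat_area = list(enabled = TRUE)))
  )
  ctl_args <- utils::modifyList(base$control, overrides)
  list(profile = profile, activation = base$activation,
       control = do.call(gd_control, ctl_args))
}

# One momentum step: delta_t = eta * (-grad) + alpha * delta_{t-1}
momentum_delta <- function(grad, prev_delta, eta, alpha) {
  blocks_map(function(g, p) -eta * g + alpha * p, grad, prev_delta)
}

#' Train a network by improved full-batch backpropagation
#'
#' Runs the momentum + adaptive-learning-efficiency + flat-area loop on a
#' full batch of (normalized input, target recipe) pairs until `max_epochs`
#' or `goal_error` is reached. Fully deterministic given the initial
#' weights and data order. Returns the best weights seen (lowest training
#' objective), not necessarily the final ones.
#'
#' @param x n x n_in matrix of normalized inputs.
#' @param y n x n_out matrix of targets (raw mass fractions).
#' @param cfg A `ccm_network_config`.
#' @param control A [gd_control()].
#' @param init Initial `ccm_weights` (e.g. GA-optimized), or `NULL` to draw
#'   random weights from `seed`.
#' @param seed Integer seed used only when `init` is `NULL`.
#' @return A `ccm_gd_fit`: list with `weights` (best-so-far), `history`
#'   (total training error per epoch, after any rollback), `eta_final`,
#'   `epochs`, `lambda_trace`, `best_error` (total error of the returned
#'   weights at `lambda = 1`), and `converged`.
#' @export
train_gd <- function(x, y, cfg, control = gd_control(), init = NULL,
                     seed = NULL) {
  stopifnot(inherits(cfg, "ccm_network_config"),
            inherits(control, "ccm_gd_control"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < 1L) stop("training batch is empty")
  if (is.null(init)) {
    if (is.null(seed)) stop("provide `init` weights or a `seed`")
    init <- random_weights(cfg, seed)
  }
  check_shapes(init, cfg)
  w <- init
  eta <- control$eta0
  prev_delta <- zero_blocks(w)
  lambda <- cfg$lambda
  fa <- control$flat_area
  history <- numeric(control$max_epochs)
  lambda_trace <- numeric(control$max_epochs)
  # The error watched by the adaptive and flat-area rules is the total
  # error: the sum of the per-sample errors E_p over the batch. The
  # gradient step itself uses the mean-scaled objective (same direction),
  # which keeps the learning-rate defaults independent of the batch size.
  scale <- nrow(x) * cfg$n_out
  err_cur <- network_gradient(w, cfg, x, y, lambda = lambda)$value * scale
  best_w <- w; best_err <- err_cur
  epochs_run <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    g <- network_gradient(w, cfg, x, y, lambda = lambda)
    if (!all(vapply(g$grad, function(b) all(is.finite(b)), logical(1)))) {
      stop(sprintf("non-finite gradient at epoch %d (training diverged)",
                   epoch))
    }
    delta <- momentum_delta(g$grad, prev_delta, eta, control$alpha)
    w_new <- apply_delta(w, delta)
    err_new <- network_gradient(w_new, cfg, x, y,
                                lambda = lambda)$value * scale
    err_prev <- err_cur

    accepted <- !(control$adaptive && err_new > err_cur)
    if (!accepted) {
      # invalid adjustment: roll back, shrink eta, drop momentum memory
      eta <- control$beta * eta
      prev_delta <- zero_blocks(w)
    } else {
      w <- w_new
      err_cur <- err_new
      prev_delta <- delta
      if (control$adaptive) eta <- control$theta * eta
    }

    # the model of record operates at lambda = 1; judge best-so-far there
    err_op <- if (lambda == 1) {
      err_cur
    } else {
      mse_objective(forward_pass(w, cfg, x, lambda = 1)$output, y) * scale
    }
    if (err_op < best_err) {
      best_err <- err_op
      best_w <- w
    }
    history[epoch] <- err_cur
    lambda_trace[epoch] <- lambda
    epochs_run <- epoch

    if (fa$enabled && accepted) {
      # a rejected, rolled-back step says nothing about surface flatness,
      # so the flat-area rule only looks at accepted epochs
      resid <- abs(y - forward_pass(w, cfg, x, lambda = lambda)$output)
      lambda_new <- flat_area_lambda(err_prev - err_cur, max(resid), fa)
      if (lambda_new != lambda) {
        lambda <- lambda_new
        # error surface changed with lambda; re-anchor the adaptive rule
        err_cur <- network_gradient(w, cfg, x, y,
                                    lambda = lambda)$value * scale
      }
    }
    if (err_op <= control$goal_error) break
  }

  structure(list(weights = best_w,
                 history = history[seq_len(epochs_run)],
                 lambda_trace = lambda_trace[seq_len(epochs_run)],
                 eta_final = eta, epochs = epochs_run,
                 best_error = best_err,
                 converged = best_err <= control$goal_error),
            class = "ccm_gd_fit")
}

#' Flat-area gradient factor rule
#'
#' Detects the flat-area condition — the error change per epoch is nearly
#' zero while some residual is still large — and returns the gradient
#' factor to use next: `lambda_boost` while trapped, 1 otherwise (including
#' when residuals are small, i.e. genuine convergence).
#'
#' @param delta_e Change in total error over the last epoch.
#' @param max_residual Largest absolute output residual `|d_k - o_k|`.
#' @param fa Flat-area settings (see [gd_control()]).
#' @return The gradient factor for the next epoch.
#' @export
flat_area_lambda <- function(delta_e, max_residual, fa) {
  if (abs(delta_e) < fa$grad_tol && max_residual > fa$residual_tol) {
    fa$lambda_boost
  } else {
    1
  }
}

#' @export
print.ccm_gd_fit <- function(x, ...) {
  cat(sprintf(
    "<gd fit: %d epochs, best objective %.6g, final eta %.4g%s>\n",
    x$epochs, x$best_error, x$eta_final,
    if (x$converged) ", reached goal" else ""))
  invisible(x)
}
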