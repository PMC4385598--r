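#' Train a color-matching model
#'
#' High-level pipeline: fits the input normalizer on the training data
#' (target interval chosen by the activation), normalizes the CIELAB
#' inputs, obtains initial weights (random, or GA-optimized for
#' `method = "gabp"`), and runs the improved gradient-descent trainer.
#'
#' @param train A `ccm_dataset` of training samples.
#' @param method `"bp"` (random initial weights) or `"gabp"`
#'   (genetic-algorithm-optimized initial weights).
#' @param h Hidden-node count.
#' @param profile A profile list from [training_profile()], or a profile
#'   name; defaults to `"bp_improved"` for BP and `"gabp_paper"` for GA+BP.
#' @param gacfg [ga_config()] used when `method = "gabp"`.
#' @param control Optional [gd_control()] overriding the profile's.
#' @param seed Integer seed covering initialization (and the GA).
#' @return A `ccm_model`: list with `weights`, `config`, `normalizer`,
#'   `profile`, `method`, `fit` (the `ccm_gd_fit`), and `ga_log` (GA+BP
#'   only).
#' @export
train_ccm <- function(train, method = c("bp", "gabp"), h = 12L,
                      profile = NULL, gacfg = ga_config(), control = NULL,
                      seed) {
  method <- match.arg(method)
  stopifnot(inherits(train, "ccm_dataset"))
  if (n_samples(train) < 1L) stop("training dataset is empty")
  if (is.null(profile)) {
    profile <- training_profile(
      if (method == "bp") "bp_improved" else "gabp_paper")
  } else if (is.character(profile)) {
    profile <- training_profile(profile)
  }
  if (!is.null(control)) profile$control <- control
  cfg <- network_config(h, activation = profile$activation)
  interval <- normalizer_for_activation(profile$activation)
  nrm <- fit_normalizer(train, interval[1], interval[2])
  x <- normalize_lab(nrm, train$lab)
  y <- train$recipe
  ga_log <- NULL
  if (method == "gabp") {
    ga <- ga_evolve(x, y, cfg, gacfg, seed = seed)
    init <- ga$weights
    ga_log <- ga$log
    fit <- train_gd(x, y, cfg, profile$control, init = init)
  } else {
    fit <- train_gd(x, y, cfg, profile$control, seed = seed)
  }
  structure(list(weights = fit$weights, config = cfg, normalizer = nrm,
                 profile = profile$profile, method = method, fit = fit,
                 ga_log = ga_log, seed = seed),
            class = "ccm_model")
}

#' @export
print.ccm_model <- function(x, ...) {
  cat(sprintf("<ccm_model: %s, %d-%d-%d %s net, training objective %.6g>\n",
              toupper(x$method), x$config$n_in, x$config$n_hidden,
              x$config$n_out, x$config$activation, x$fit$best_error))
  invisible(x)
}

#' Predict powder recipes from CIELAB colors
#'
#' Normalizes the inputs with the model's fitted normalizer and runs the
#' forward pass. By default the raw network outputs are returned — they
#' need not lie on the recipe grid nor sum to 0.40, matching how prediction
#' quality is scored. With `clip = TRUE` outputs are clamped at zero and
#' rescaled to sum to exactly 0.40 (a dispensable post-processing step for
#' producing a mixable recipe).
#'
#' @param object A `ccm_model`.
#' @param lab CIELAB 3-vector or n x 3 matrix.
#' @param clip Clamp at zero and renormalize the sum to 0.40.
#' @param ... Unused.
#' @return n x 5 matrix of powder mass fractions.
#' @export
predict.ccm_model <- function(object, lab, clip = FALSE, ...) {
  x <- normalize_lab(object$normalizer, lab)
  out <- forward_pass(object$weights, object$config, x)$output
  colnames(out) <- POWDER_COLS
  if (clip) {
    out <- pmax(out, 0)
    sums <- rowSums(out)
    sums[sums == 0] <- 1
    out <- out / sums * RECIPE_TOTAL
  }
  out
}

#' Evaluate a model on a dataset
#'
#' Computes the per-sample errors `E_p` and both aggregate metrics.
#'
#' @param model A `ccm_model`.
#' @param d A `ccm_dataset`.
#' @return List with `per_sample` (vector of `E_p`), `mse_printed`
#'   (mean of squared `E_p`) and `mse_mean_ep` (mean of `E_p`).
#' @export
evaluate_model <- function(model, d) {
  stopifnot(inherits(model, "ccm_model"), inherits(d, "ccm_dataset"))
  pred <- predict(model, d$lab)
  ep <- sample_errors(d$recipe, pred)
  list(per_sample = ep,
       mse_printed = total_mse(ep, "printed"),
       mse_mean_ep = total_mse(ep, "mean_ep"))
}

#' Save / load a model as JSON
#'
#' The model file records the architecture, the four weight blocks
#' (row-major), the input normalizer, and the training profile, so a saved
#' model reproduces predictions exactly.
#'
#' @param model A `ccm_model`.
#' @param path Output path.
#' @return `save_model`: `path`, invisibly. `load_model`: a `ccm_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ccm_model"))
  obj <- list(
    package = "shadematch",
    method = model$method,
    profile = model$profile,
    config = list(n_in = model$config$n_in,
                  n_hidden = model$config$n_hidden,
                  n_out = model$config$n_out,
                  activation = model$config$activation,
                  lambda = model$config$lambda),
    weights = list(W = unname(apply(model$weights$W, 1, c, simplify = FALSE)),
                   V = unname(apply(model$weights$V, 1, c, simplify = FALSE)),
                   theta_hidden = model$weights$theta_hidden,
                   theta_out = model$weights$theta_out),
    normalizer = list(min = unname(model$normalizer$min),
                      max = unname(model$normalizer$max),
                      lo = model$normalizer$lo, hi = model$normalizer$hi),
    seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(obj$config$n_hidden,
                        activation = obj$config$activation,
                        n_in = obj$config$n_in, n_out = obj$config$n_out,
                        lambda = obj$config$lambda)
  to_mat <- function(x) {
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  w <- network_weights(W = to_mat(obj$weights$W), V = to_mat(obj$weights$V),
                       theta_hidden = unlist(obj$weights$theta_hidden),
                       theta_out = unlist(obj$weights$theta_out))
  nrm <- structure(list(min = stats::setNames(obj$normalizer$min, LAB_COLS),
                        max = stats::setNames(obj$normalizer$max, LAB_COLS),
                        lo = obj$normalizer$lo, hi = obj$normalizer$hi),
                   class = "ccm_normalizer")
  structure(list(weights = w, config = cfg, normalizer = nrm,
                 profile = obj$profile, method = obj$method,
                 fit = list(best_error = NA_real_), ga_log = NULL,
                 seed = obj$seed),
            class = "ccm_model")
}
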