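# Shared fixtures, all built in code.

# Tiny 4-sample dataset on the recipe grid with a deterministic linear map
# to color space; handy for fast pipeline tests.
tiny_dataset <- function() {
  recipes <- rbind(
    c(0.40, 0, 0, 0, 0),
    c(0, 0.40, 0, 0, 0),
    c(0.16, 0.08, 0.08, 0, 0.08),
    c(0.08, 0, 0.16, 0.16, 0)
  )
  lab <- recipe_to_lab(recipes, synthetic_params(curvature = 0,
                                                 noise_sd = c(0, 0, 0)))
  ccm_dataset(lab, recipes, name = "tiny")
}

# Example specimen rows shipped with the package (CSV fixture).
specimen_examples_path <- function() {
  system.file("extdata", "specimen_examples.csv", package = "shadematch")
}

prediction_examples <- function() {
  utils::read.csv(system.file("extdata", "prediction_examples.csv",
                              package = "shadematch"))
}

# Flatten a gradient/weight block list in the canonical chromosome order.
flatten_blocks <- function(b) {
  c(as.vector(t(b$W)), as.vector(t(b$V)), b$theta_hidden, b$theta_out)
}

# Central finite-difference gradient of the training objective; the
# independent oracle for the analytic backprop gradient.
fd_gradient <- function(w, cfg, x, y, lambda = cfg$lambda, eps = 1e-5) {
  p <- encode_weights(w)
  f <- function(v) {
    o <- forward_pass(decode_weights(v, cfg), cfg, x, lambda = lambda)$output
    mean((y - o)^2)
  }
  vapply(seq_along(p), function(i) {
    up <- p; up[i] <- up[i] + eps
    dn <- p; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
}
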