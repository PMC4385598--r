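# Default pure-component colors (L*, a*, b*) of the five fired dentin
# powders used by the synthetic forward model. Chosen as fixed constants
# whose convex hull brackets the color ranges observed in fired-specimen
# measurements (L* roughly 64-72.5, a* -1.3-1.8, b* 14.5-21.5). These are
# synthetic stand-ins, not measured optical constants.
PURE_COMPONENT_LAB <- matrix(
  c(73.0, -1.5, 14.2,   # A1: lightest, least chromatic
    66.0,  1.6, 20.5,   # A4
    65.0,  1.2, 21.9,   # B4: most yellow
    63.5,  2.0, 19.5,   # C4: darkest, most red
    66.5,  0.3, 18.5),  # D4
  nrow = 5, byrow = TRUE,
  dimnames = list(c("A1", "A4", "B4", "C4", "D4"), c("L", "a", "b")))

# Fixed quadratic interaction coefficients (one 5 x 5 symmetric matrix per
# color channel), deterministic constants generated from a sine grid so the
# nonlinearity is smooth, reproducible, and of order 0.1 per unit curvature.
interaction_matrices <- function() {
  lapply(1:3, function(ch) {
    M <- outer(1:5, 1:5, function(i, j) sin(ch * i + j))
    (M + t(M)) / 2
  })
}

#' Parameters of the synthetic porcelain-mixing forward model
#'
#' The generator maps a powder recipe `r` (5 mass fractions summing to
#' 0.40) to a CIELAB triple by
#' `lab = offset + t(basis) %*% r + curvature * g(r) + noise`,
#' where `basis` holds each powder's color contribution per unit mass
#' fraction, `g` is a fixed smooth quadratic interaction term emulating
#' non-additive optical mixing, and the noise is independent Gaussian per
#' channel (instrument repeatability scale).
#'
#' Because every recipe sums to the same total, an additive offset is
#' indistinguishable from a uniform shift of the basis columns; the default
#' therefore uses a zero offset with the baseline folded into the basis
#' (each basis row is a pure-component color divided by 0.40).
#'
#' @param basis 5 x 3 matrix of per-powder color directions.
#' @param offset Baseline CIELAB 3-vector.
#' @param curvature Non-negative strength of the quadratic interaction.
#' @param noise_sd Per-channel measurement noise standard deviations
#'   (CIELAB units). Default 0.3, a typical intra-instrument repeatability.
#' @return A `ccm_synth_params`.
#' @export
synthetic_params <- function(basis = PURE_COMPONENT_LAB / RECIPE_TOTAL,
                             offset = c(0, 0, 0), curvature = 5,
                             noise_sd = c(0.3, 0.3, 0.3)) {
  basis <- as.matrix(basis)
  stopifnot(nrow(basis) == 5L, ncol(basis) == 3L, length(offset) == 3L,
            curvature >= 0, length(noise_sd) == 3L, all(noise_sd >= 0))
  structure(list(basis = basis, offset = as.numeric(offset),
                 curvature = as.numeric(curvature),
                 noise_sd = as.numeric(noise_sd)),
            class = "ccm_synth_params")
}

#' Enumerate all valid recipes
#'
#' Every specimen recipe distributes 5 grid units of 0.08 over the five
#' powders: the weak compositions of 5 into 5 parts, `choose(9, 4) = 126`
#' possibilities.
#'
#' @return 126 x 5 matrix of recipes (rows sum to 0.40).
#' @export
enumerate_recipes <- function() {
  units <- expand.grid(a = 0:5, b = 0:5, c = 0:5, d = 0:5)
  units <- units[rowSums(units) <= 5L, ]
  grid <- cbind(as.matrix(units), e = 5L - rowSums(units))
  recipes <- grid * RECIPE_STEP
  dimnames(recipes) <- list(NULL, POWDER_COLS)
  recipes[order(recipes[, 1], recipes[, 2], recipes[, 3], recipes[, 4]), ]
}

#' Draw recipes uniformly from the composition grid
#'
#' Samples uniformly among the 126 valid recipes. Uses the current R
#' random stream; seed upstream (see [generate_dataset()]).
#'
#' @param n Number of recipes.
#' @return n x 5 matrix of recipes.
#' @export
sample_recipes <- function(n) {
  grid <- enumerate_recipes()
  grid[sample.int(nrow(grid), n, replace = TRUE), , drop = FALSE]
}

#' Forward mixing model: recipe to CIELAB color
#'
#' @param recipe 5-vector or n x 5 matrix of recipes.
#' @param params A [synthetic_params()].
#' @param noise If `TRUE`, adds Gaussian measurement noise using the
#'   current R random stream; if `FALSE` the map is deterministic.
#' @return n x 3 matrix of CIELAB values.
#' @export
recipe_to_lab <- function(recipe, params = synthetic_params(),
                          noise = FALSE) {
  stopifnot(inherits(params, "ccm_synth_params"))
  if (is.null(dim(recipe))) recipe <- matrix(recipe, nrow = 1L)
  recipe <- as.matrix(recipe)
  lab <- recipe %*% params$basis
  lab <- sweep(lab, 2, params$offset, "+")
  if (params$curvature > 0) {
    Qs <- interaction_matrices()
    quad <- vapply(Qs, function(Q) {
      rowSums((recipe %*% Q) * recipe)
    }, numeric(nrow(recipe)))
    quad <- matrix(quad, nrow = nrow(recipe))
    lab <- lab + params$curvature * quad
  }
  if (noise) {
    lab <- lab + matrix(stats::rnorm(length(lab)), nrow(lab), 3L,
                        byrow = FALSE) %*% diag(params$noise_sd)
  }
  colnames(lab) <- LAB_COLS
  lab
}

#' Generate a synthetic specimen dataset
#'
#' Draws `n` recipes uniformly from the 126-member composition grid, maps
#' each through the forward mixing model with measurement noise, and
#' returns the standard dataset. Deterministic given `seed`. The default
#' `n = 119` matches the size of the fired-specimen database.
#'
#' @param n Number of samples, >= 1.
#' @param params A [synthetic_params()].
#' @param seed Integer seed for recipes and noise.
#' @param name Dataset label.
#' @return A [ccm_dataset()].
#' @export
generate_dataset <- function(n = 119L, params = synthetic_params(), seed,
                             name = "synthetic") {
  if (n < 1L) stop("`n` must be >= 1")
  set.seed(as.integer(seed))
  recipes <- sample_recipes(n)
  lab <- recipe_to_lab(recipes, params, noise = any(params$noise_sd > 0))
  ccm_dataset(lab, recipes, name = name)
}

#' Recover the linear mixing map from noiseless data
#'
#' Least-squares fit of the no-intercept linear map from recipes to colors.
#' On data generated with zero curvature and zero noise this recovers the
#' generator's `basis` exactly (and the zero offset it uses: with all
#' recipes summing to 0.40 an intercept would be collinear with the basis,
#' so the generator folds any baseline into the basis and the fit omits
#' the intercept).
#'
#' @param d A `ccm_dataset` with at least 5 samples spanning the
#'   composition space.
#' @return List with `basis` (5 x 3) and `offset` (zero 3-vector).
#' @export
fit_linear_mixing <- function(d) {
  stopifnot(inherits(d, "ccm_dataset"))
  if (n_samples(d) < 5L) stop("need at least 5 samples to fit the basis")
  basis <- qr.solve(d$recipe, d$lab)
  dimnames(basis) <- list(POWDER_COLS, LAB_COLS)
  list(basis = basis, offset = c(0, 0, 0))
}
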