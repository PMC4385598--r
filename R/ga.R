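#' Genetic-algorithm configuration
#'
#' Parameters of the real-coded GA that searches initial weights and
#' thresholds for the network. Each chromosome is the flattened parameter
#' vector in four contiguous segments: input-to-hidden weights (row-major),
#' hidden-to-output weights (row-major), hidden thresholds, output
#' thresholds.
#'
#' @param pop_size Population size N >= 2.
#' @param max_generations Number of generations to evolve.
#' @param crossover_prob Probability that a selected pair exchanges a
#'   contiguous gene range (single-point crossover).
#' @param mutation_prob Per-gene probability of uniform resampling from
#'   `gene_range`.
#' @param gene_range Interval for initialization and mutation resampling.
#' @param fitness_mode `"static_error"` scores the decoded, untrained
#'   network; `"trained_error"` first applies the inner trainer.
#' @param inner_trainer `"none"`, `"gd_k_epochs"` or `"lm_k_iters"`; the
#'   short training applied before scoring when
#'   `fitness_mode = "trained_error"`.
#' @param inner_k Epochs / iterations for the inner trainer.
#' @param fitness_eps Small positive constant: fitness is
#'   `1 / (error + fitness_eps)`, so a zero-error network gets the maximum
#'   finite fitness.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (default 1, which makes per-generation best fitness
#'   monotone non-decreasing).
#' @param target_fitness Optional early-stopping fitness.
#' @param segment_crossover If `TRUE`, the crossover cut point is restricted
#'   to the four segment boundaries instead of any gene position.
#' @param mutation_kind `"uniform"` resampling (default) or `"gaussian"`
#'   perturbation with sd one tenth of the gene-range width.
#' @return A `ccm_ga_config`.
#' @export
ga_config <- function(pop_size = 40L, max_generations = 50L,
                      crossover_prob = 0.7, mutation_prob = 0.05,
                      gene_range = c(-1, 1),
                      fitness_mode = c("static_error", "trained_error"),
                      inner_trainer = c("none", "gd_k_epochs", "lm_k_iters"),
                      inner_k = 5L, fitness_eps = 1e-6, elitism = 1L,
                      target_fitness = NULL, segment_crossover = FALSE,
                      mutation_kind = c("uniform", "gaussian")) {
  fitness_mode <- match.arg(fitness_mode)
  inner_trainer <- match.arg(inner_trainer)
  mutation_kind <- match.arg(mutation_kind)
  stopifnot(pop_size >= 2, max_generations >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            length(gene_range) == 2L, gene_range[2] > gene_range[1],
            inner_k >= 0, fitness_eps > 0, elitism >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 gene_range = as.numeric(gene_range),
                 fitness_mode = fitness_mode,
                 inner_trainer = inner_trainer, inner_k = as.integer(inner_k),
                 fitness_eps = fitness_eps, elitism = as.integer(elitism),
                 target_fitness = target_fitness,
                 segment_crossover = segment_crossover,
                 mutation_kind = mutation_kind),
            class = "ccm_ga_config")
}

#' Encode network weights as a chromosome / decode a chromosome
#'
#' The encoding is a bijection between the four parameter blocks and a flat
#' real vector of length `n_in*h + h*n_out + h + n_out`, segment order:
#' W (row-major), V (row-major), hidden thresholds, output thresholds.
#'
#' @param w A `ccm_weights`.
#' @return `encode_weights`: numeric gene vector. `decode_weights`: a
#'   `ccm_weights`.
#' @export
encode_weights <- function(w) {
  stopifnot(inherits(w, "ccm_weights"))
  flatten_weights(w)
}

#' @rdname encode_weights
#' @param genes Numeric gene vector of the correct length.
#' @param cfg A `ccm_network_config`.
#' @export
decode_weights <- function(genes, cfg) {
  stopifnot(inherits(cfg, "ccm_network_config"))
  unflatten_weights(genes, cfg)
}

#' Fitness of a chromosome on a training set
#'
#' Decodes the chromosome, optionally applies the configured inner trainer
#' (a few gradient-descent epochs or Levenberg-Marquardt iterations), then
#' scores the aggregate training error `E_MSE` (printed metric) and returns
#' `1 / (error + fitness_eps)`: small error means high fitness. A
#' non-finite error is scored with the worst fitness, `fitness_eps`.
#'
#' @param genes Gene vector.
#' @param x,y Normalized training inputs and raw targets.
#' @param cfg A `ccm_network_config`.
#' @param gacfg A [ga_config()].
#' @return Strictly positive scalar fitness.
#' @export
chromosome_fitness <- function(genes, x, y, cfg, gacfg) {
  w <- decode_weights(genes, cfg)
  if (gacfg$fitness_mode == "trained_error" && gacfg$inner_k > 0L) {
    w <- switch(gacfg$inner_trainer,
      none = w,
      gd_k_epochs = train_gd(x, y, cfg,
                             gd_control(max_epochs = gacfg$inner_k),
                             init = w)$weights,
      lm_k_iters = train_lm(x, y, cfg, w,
                            lm_control(max_iter = gacfg$inner_k))$weights
    )
  }
  out <- forward_pass(w, cfg, x)$output
  err <- total_mse(sample_errors(y, out), metric = "printed")
  if (!is.finite(err)) return(gacfg$fitness_eps)
  1 / (err + gacfg$fitness_eps)
}

#' Roulette-wheel selection
#'
#' Draws one population index with probability proportional to fitness:
#' `p_i = f_i / sum(f)`. Uses the current R random stream.
#'
#' @param fitness Vector of positive fitness values.
#' @return Selected index in `seq_along(fitness)`.
#' @export
roulette_select <- function(fitness) {
  if (!length(fitness) || any(fitness < 0) || sum(fitness) <= 0) {
    stop("roulette selection needs positive total fitness")
  }
  wheel <- cumsum(fitness) / sum(fitness)
  findInterval(stats::runif(1), wheel) + 1L
}

#' Single-point crossover of two chromosomes
#'
#' With probability `crossover_prob` a cut point is chosen uniformly and the
#' gene tail beyond it is exchanged between the parents; otherwise the
#' children are copies. Each child position always comes from exactly one
#' parent, so `child1 + child2 = parent1 + parent2` positionwise.
#'
#' @param a,b Parent gene vectors of equal length.
#' @param gacfg A [ga_config()]; `segment_crossover = TRUE` restricts the
#'   cut to the four segment boundaries (requires `cfg`).
#' @param cfg Network configuration, needed for segment-aligned cuts.
#' @return List of two children gene vectors.
#' @export
ga_crossover <- function(a, b, gacfg, cfg = NULL) {
  if (length(a) != length(b)) stop("parent chromosomes differ in length")
  if (stats::runif(1) >= gacfg$crossover_prob || length(a) < 2L) {
    return(list(a, b))
  }
  if (isTRUE(gacfg$segment_crossover)) {
    if (is.null(cfg)) stop("segment crossover needs the network config")
    h <- cfg$n_hidden
    bounds <- cumsum(c(cfg$n_in * h, h * cfg$n_out, h))
    cut <- bounds[sample.int(length(bounds), 1L)]
  } else {
    cut <- sample.int(length(a) - 1L, 1L)
  }
  tail_idx <- (cut + 1L):length(a)
  c1 <- a; c2 <- b
  c1[tail_idx] <- b[tail_idx]
  c2[tail_idx] <- a[tail_idx]
  list(c1, c2)
}

#' Mutate a chromosome
#'
#' Each gene is independently replaced with probability `mutation_prob`:
#' uniform resampling from `gene_range` (default) or a Gaussian perturbation
#' clamped to the range.
#'
#' @param genes Gene vector.
#' @param gacfg A [ga_config()].
#' @return Mutated gene vector.
#' @export
ga_mutate <- function(genes, gacfg) {
  mask <- stats::runif(length(genes)) < gacfg$mutation_prob
  if (!any(mask)) return(genes)
  lo <- gacfg$gene_range[1]; hi <- gacfg$gene_range[2]
  k <- sum(mask)
  if (gacfg$mutation_kind == "uniform") {
    genes[mask] <- stats::runif(k, lo, hi)
  } else {
    genes[mask] <- pmin(hi, pmax(lo, genes[mask] +
                                   stats::rnorm(k, 0, (hi - lo) / 10)))
  }
  genes
}

#' Evolve initial network weights by genetic algorithm
#'
#' Initializes `pop_size` random chromosomes, then iterates
#' roulette-wheel selection, single-point crossover, per-gene mutation and
#' elitist carry-over for `max_generations` generations (or until
#' `target_fitness`). Returns the best-ever individual, decoded to network
#' weights, together with a per-generation log. Deterministic given `seed`.
#'
#' @param x,y Normalized training inputs and raw targets.
#' @param cfg A `ccm_network_config`.
#' @param gacfg A [ga_config()].
#' @param seed Integer seed for all GA randomness.
#' @return A `ccm_ga_result`: list with `weights` (decoded best), `genes`,
#'   `fitness`, `error` (training E_MSE of the best individual), and `log`
#'   (data.frame: generation, best_fitness, mean_fitness, best_error).
#' @export
ga_evolve <- function(x, y, cfg, gacfg = ga_config(), seed) {
  stopifnot(inherits(cfg, "ccm_network_config"),
            inherits(gacfg, "ccm_ga_config"))
  x <- as.matrix(x); y <- as.matrix(y)
  set.seed(as.integer(seed))
  len <- n_parameters(cfg)
  N <- gacfg$pop_size
  pop <- matrix(stats::runif(N * len, gacfg$gene_range[1],
                             gacfg$gene_range[2]), N, len)
  fit <- apply(pop, 1, chromosome_fitness, x = x, y = y, cfg = cfg,
               gacfg = gacfg)
  best_i <- which.max(fit)
  best_genes <- pop[best_i, ]
  best_fit <- fit[best_i]
  log <- data.frame(generation = 0L, best_fitness = max(fit),
                    mean_fitness = mean(fit),
                    best_error = 1 / max(fit) - gacfg$fitness_eps)

  gen <- 0L
  while (gen < gacfg$max_generations &&
         (is.null(gacfg$target_fitness) ||
          best_fit < gacfg$target_fitness)) {
    gen <- gen + 1L
    new_pop <- matrix(0, N, len)
    n_elite <- min(gacfg$elitism, N)
    if (n_elite > 0L) {
      ord <- order(fit, decreasing = TRUE)[seq_len(n_elite)]
      new_pop[seq_len(n_elite), ] <- pop[ord, , drop = FALSE]
    }
    filled <- n_elite
    while (filled < N) {
      i <- roulette_select(fit)
      j <- roulette_select(fit)
      kids <- ga_crossover(pop[i, ], pop[j, ], gacfg, cfg)
      for (child in kids) {
        if (filled >= N) break
        filled <- filled + 1L
        new_pop[filled, ] <- ga_mutate(child, gacfg)
      }
    }
    pop <- new_pop
    fit <- apply(pop, 1, chromosome_fitness, x = x, y = y, cfg = cfg,
                 gacfg = gacfg)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_genes <- pop[which.max(fit), ]
    }
    log <- rbind(log, data.frame(
      generation = gen, best_fitness = max(fit), mean_fitness = mean(fit),
      best_error = 1 / max(fit) - gacfg$fitness_eps))
  }

  structure(list(weights = decode_weights(best_genes, cfg),
                 genes = best_genes, fitness = best_fit,
                 error = 1 / best_fit - gacfg$fitness_eps, log = log),
            class = "ccm_ga_result")
}

#' @export
print.ccm_ga_result <- function(x, ...) {
  cat(sprintf(
    "<GA result: %d generations, best fitness %.4g (error %.6g)>\n",
    max(x$log$generation), x$fitness, x$error))
  invisible(x)
}
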