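test_that("chromosome encoding is a length-correct bijection", {
  cfg225 <- network_config(2, "logistic", n_in = 2, n_out = 1)
  expect_equal(n_parameters(cfg225), 2 * 2 + 2 * 1 + 2 + 1)  # 9

  cfg <- network_config(12, "logistic")
  expect_equal(n_parameters(cfg), 113L)                       # 36+60+12+5

  w <- random_weights(cfg, 3)
  genes <- encode_weights(w)
  expect_length(genes, 113L)
  back <- decode_weights(genes, cfg)
  expect_identical(back$W, w$W)
  expect_identical(back$V, w$V)
  expect_identical(back$theta_hidden, w$theta_hidden)
  expect_identical(back$theta_out, w$theta_out)
  # segment order: W row-major first
  expect_identical(genes[1:3], w$W[1, ])
  expect_error(decode_weights(genes[-1], cfg), "length")
})

test_that("fitness decreases in error and honors the inner-trainer modes", {
  d <- tiny_dataset()
  cfg <- network_config(3, "logistic")
  nrm <- fit_normalizer(d, 0.1, 0.9)
  x <- normalize_lab(nrm, d$lab); y <- d$recipe
  gacfg <- ga_config()
  set.seed(1)
  g1 <- stats::runif(n_parameters(cfg), -1, 1)
  g2 <- stats::runif(n_parameters(cfg), -1, 1)
  f <- function(g, gc = gacfg) chromosome_fitness(g, x, y, cfg, gc)
  e <- function(g) {
    out <- forward_pass(decode_weights(g, cfg), cfg, x)$output
    total_mse(sample_errors(y, out))
  }
  # fitness = 1/(E + eps): monotone, and exact at the definition
  expect_equal(f(g1), 1 / (e(g1) + gacfg$fitness_eps))
  expect_equal(f(g1) > f(g2), e(g1) < e(g2))

  # trained_error with k = 0 reduces exactly to static_error
  gc0 <- ga_config(fitness_mode = "trained_error",
                   inner_trainer = "gd_k_epochs", inner_k = 0L)
  expect_equal(f(g1, gc0), f(g1))

  # inner training can only improve (or preserve) the scored error
  gc_lm <- ga_config(fitness_mode = "trained_error",
                     inner_trainer = "lm_k_iters", inner_k = 5L)
  expect_gte(f(g1, gc_lm), f(g1) * 0.999999)
})

test_that("roulette frequencies follow fitness-proportional probabilities", {
  set.seed(42)
  draws <- vapply(1:20000, function(i) roulette_select(c(3, 1)), integer(1))
  p_hat <- mean(draws == 1)
  # binomial 3-sigma band around p = 0.75
  sigma <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(p_hat - 0.75), 3 * sigma)

  set.seed(7)
  uni <- vapply(1:8000, function(i) roulette_select(rep(1, 4)), integer(1))
  expect_gt(stats::chisq.test(table(factor(uni, levels = 1:4)))$p.value,
            0.001)
  expect_error(roulette_select(numeric(0)), "positive")
})

test_that("crossover exchanges a tail and conserves positionwise sums", {
  gacfg <- ga_config(crossover_prob = 1)
  a <- c(1, 1, 1, 1); b <- c(2, 2, 2, 2)
  set.seed(3)
  kids <- ga_crossover(a, b, gacfg)
  expect_equal(kids[[1]] + kids[[2]], a + b)
  # exactly one contiguous tail swapped
  flips <- which(kids[[1]] != a)
  expect_equal(flips, seq.int(min(flips), 4L))

  # probability 0: identical copies
  none <- ga_crossover(a, b, ga_config(crossover_prob = 0))
  expect_identical(none[[1]], a)
  expect_identical(none[[2]], b)

  # conservation holds across random parents (property)
  set.seed(9)
  for (i in 1:20) {
    pa <- stats::rnorm(11); pb <- stats::rnorm(11)
    ks <- ga_crossover(pa, pb, gacfg)
    expect_equal(ks[[1]] + ks[[2]], pa + pb)
  }
})

test_that("mutation resamples the expected number of genes within range", {
  gacfg <- ga_config(mutation_prob = 0)
  g <- stats::rnorm(113)
  expect_identical(ga_mutate(g, gacfg), g)

  all_mut <- ga_mutate(g, ga_config(mutation_prob = 1))
  expect_true(all(all_mut >= -1 & all_mut <= 1))

  # binomial oracle: mean mutated count ~ Binomial(113, 0.05)
  set.seed(11)
  gc <- ga_config(mutation_prob = 0.05)
  counts <- vapply(1:2000, function(i) sum(ga_mutate(g, gc) != g),
                   numeric(1))
  expected <- 113 * 0.05
  sigma <- sqrt(113 * 0.05 * 0.95 / 2000)
  expect_lt(abs(mean(counts) - expected), 3 * sigma)
})

test_that("evolution is elitist-monotone, seeded, and returns the best", {
  d <- tiny_dataset()
  cfg <- network_config(3, "logistic")
  nrm <- fit_normalizer(d, 0.1, 0.9)
  x <- normalize_lab(nrm, d$lab); y <- d$recipe

  # zero generations: best of the random initial population
  gacfg0 <- ga_config(pop_size = 10, max_generations = 0)
  res0 <- ga_evolve(x, y, cfg, gacfg0, seed = 5)
  expect_equal(nrow(res0$log), 1L)
  expect_equal(res0$fitness, res0$log$best_fitness[1])

  gacfg <- ga_config(pop_size = 12, max_generations = 15, elitism = 1)
  res <- ga_evolve(x, y, cfg, gacfg, seed = 5)
  expect_true(all(diff(res$log$best_fitness) >= 0))
  expect_equal(max(res$log$best_fitness), res$fitness)

  res2 <- ga_evolve(x, y, cfg, gacfg, seed = 5)
  expect_identical(res$log, res2$log)
  expect_identical(res$genes, res2$genes)
})
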