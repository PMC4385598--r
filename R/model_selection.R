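#' Hidden-layer size range from the square-root rule
#'
#' The customary estimate for the hidden-node count of a three-layer
#' network is `h = sqrt(n + m) + a` with `a` an integer constant in
#' `[1, 10]`; sweeping `a` gives a candidate range. Rounding is
#' half-up to the nearest integer. For the 3-input, 5-output color-matching
#' network this yields candidates 4 through 13.
#'
#' @param n Input-layer nodes.
#' @param m Output-layer nodes.
#' @param a_min,a_max Integer bounds for the additive constant, within
#'   `[1, 10]`.
#' @return A `ccm_hidden_range`: list with `h_min`, `h_max`, and the
#'   arguments.
#' @export
hidden_range <- function(n, m, a_min = 1L, a_max = 10L) {
  stopifnot(n >= 1, m >= 1)
  if (!(a_min >= 1 && a_min <= a_max && a_max <= 10)) {
    stop("`a_min`/`a_max` must satisfy 1 <= a_min <= a_max <= 10")
  }
  half_up <- function(x) floor(x + 0.5)
  structure(list(n = as.integer(n), m = as.integer(m),
                 a_min = as.integer(a_min), a_max = as.integer(a_max),
                 h_min = as.integer(half_up(sqrt(n + m) + a_min)),
                 h_max = as.integer(half_up(sqrt(n + m) + a_max))),
            class = "ccm_hidden_range")
}

#' @export
print.ccm_hidden_range <- function(x, ...) {
  cat(sprintf("<hidden-node range: %d..%d (n=%d, m=%d, a in [%d,%d])>\n",
              x$h_min, x$h_max, x$n, x$m, x$a_min, x$a_max))
  invisible(x)
}

#' Choose the hidden-node count by trial and error
#'
#' For every candidate `h` in the range, trains `reps` independently seeded
#' networks with otherwise identical parameters and records the aggregate
#' test error of each; the chosen `h` minimizes the mean test error, ties
#' broken toward the smaller (cheaper) network. A repetition that diverges
#' is recorded with an infinite error and flagged, which removes its `h`
#' from contention.
#'
#' @param train,test `ccm_dataset`s (test held out from training).
#' @param hrange A [hidden_range()] or integer vector of candidate `h`.
#' @param reps Trainings per candidate.
#' @param profile Training profile name (see [training_profile()]).
#' @param control Optional [gd_control()] override.
#' @param metric Aggregate error metric, see [total_mse()].
#' @param seed Integer seed; repetition seeds are derived from it.
#' @return A `ccm_hidden_selection`: list with `best_h`, `trials`
#'   (data.frame: h, rep, error, diverged) and `summary` (data.frame: h,
#'   mean_error, sd_error).
#' @export
select_hidden_nodes <- function(train, test, hrange, reps = 20L,
                                profile = "bp_improved", control = NULL,
                                metric = "printed", seed) {
  stopifnot(inherits(train, "ccm_dataset"), inherits(test, "ccm_dataset"))
  hs <- if (inherits(hrange, "ccm_hidden_range")) {
    seq.int(hrange$h_min, hrange$h_max)
  } else {
    as.integer(hrange)
  }
  if (!length(hs)) stop("empty hidden-node range")
  if (reps < 1L) stop("`reps` must be >= 1")
  prof <- training_profile(profile)
  if (!is.null(control)) prof$control <- control
  seeds <- derive_seeds(seed, length(hs) * reps)
  rows <- vector("list", length(hs) * reps)
  k <- 0L
  for (h in hs) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      err <- tryCatch({
        model <- train_ccm(train, method = "bp", h = h,
                           profile = prof, seed = seeds[k])
        evaluate_model(model, test)[[paste0("mse_", metric)]]
      }, error = function(e) Inf)
      rows[[k]] <- data.frame(h = h, rep = r, error = err,
                              diverged = !is.finite(err))
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$h), function(tr) {
    data.frame(h = tr$h[1], mean_error = mean(tr$error),
               sd_error = stats::sd(tr$error))
  }))
  summary <- summary[order(summary$h), ]
  rownames(summary) <- NULL
  best_h <- summary$h[which.min(summary$mean_error)]  # which.min: first min
  structure(list(best_h = as.integer(best_h), trials = trials,
                 summary = summary, metric = metric),
            class = "ccm_hidden_selection")
}

#' @export
print.ccm_hidden_selection <- function(x, ...) {
  cat(sprintf("<hidden-node selection: best h = %d>\n", x$best_h))
  print(x$summary)
  invisible(x)
}

#' Compare plain BP against GA+BP
#'
#' Runs `n_trials` independently seeded trainings for each arm and reports
#' the per-trial aggregate test errors with their means and variances:
#' * BP arm: random initial weights, `bp_improved` profile (momentum +
#'   adaptive learning efficiency, tangent activation).
#' * GA+BP arm: genetic-algorithm-optimized initial weights, `gabp_paper`
#'   profile (momentum + adaptive learning efficiency + flat-area gradient
#'   factor, logistic activation).
#'
#' @param train,test `ccm_dataset`s.
#' @param h Hidden-node count (default 12, the trial-and-error optimum for
#'   the 3-input 5-output problem).
#' @param n_trials Trainings per arm, >= 2.
#' @param gacfg A [ga_config()] for the GA arm.
#' @param bp_control,gabp_control Optional [gd_control()] overrides.
#' @param metric Aggregate error metric, see [total_mse()].
#' @param seed Integer seed; all trial seeds derive from it.
#' @return A `ccm_comparison`: list with `bp_errors`, `gabp_errors`
#'   (length `n_trials` each), `summary` (data.frame: method, mean_mse,
#'   var_mse), `metric`, and `trials` (long data.frame).
#' @export
compare_bp_gabp <- function(train, test, h = 12L, n_trials = 10L,
                            gacfg = ga_config(), bp_control = NULL,
                            gabp_control = NULL, metric = "printed", seed) {
  stopifnot(inherits(train, "ccm_dataset"), inherits(test, "ccm_dataset"))
  if (n_trials < 2L) stop("`n_trials` must be >= 2")
  seeds <- derive_seeds(seed, 2L * n_trials)
  run_arm <- function(method, arm_seeds, control) {
    vapply(arm_seeds, function(s) {
      prof <- training_profile(
        if (method == "bp") "bp_improved" else "gabp_paper")
      if (!is.null(control)) prof$control <- control
      model <- train_ccm(train, method = method, h = h, profile = prof,
                         gacfg = gacfg, seed = s)
      evaluate_model(model, test)[[paste0("mse_", metric)]]
    }, numeric(1))
  }
  bp <- run_arm("bp", seeds[seq_len(n_trials)], bp_control)
  gabp <- run_arm("gabp", seeds[n_trials + seq_len(n_trials)], gabp_control)
  summary <- data.frame(
    method = c("bp", "gabp"),
    mean_mse = c(mean(bp), mean(gabp)),
    var_mse = c(stats::var(bp), stats::var(gabp))
  )
  trials <- data.frame(
    method = rep(c("bp", "gabp"), each = n_trials),
    trial = rep(seq_len(n_trials), 2L),
    mse = c(bp, gabp)
  )
  structure(list(bp_errors = bp, gabp_errors = gabp, summary = summary,
                 trials = trials, metric = metric, h = h, seed = seed),
            class = "ccm_comparison")
}

#' @export
print.ccm_comparison <- function(x, ...) {
  cat(sprintf("<BP vs GA+BP comparison: %d trials/arm, h = %d, %s metric>\n",
              length(x$bp_errors), x$h, x$metric))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
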