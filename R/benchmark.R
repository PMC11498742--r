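# Desk-scale analogue of the evaluation protocol: log-uniform parameter
# sampling within bounds, per-pair failure-rate tabulation, pairwise
# gradient-agreement statistics, and equilibration-vs-total timing
# decomposition.

#' Sample parameter vectors within bounds
#'
#' Each coordinate is drawn uniformly on the parameter's declared scale
#' (uniform in log10 for `log10`-scaled parameters) within its bounds,
#' reproducibly for a given seed.
#'
#' @param model an [ode_model()].
#' @param n number of vectors.
#' @param seed RNG seed.
#' @return list of named parameter vectors (linear scale).
#' @export
sample_parameters <- function(model, n, seed = 1L) {
  if (any(model$scale == "log10" & model$lower <= 0))
    stop("log10-scaled parameters need positive lower bounds")
  set.seed(seed)
  lapply(seq_len(n), function(i) sample_theta_once(model))
}

#' Classify a simulation or gradient outcome
#'
#' A parameter vector counts as failed if any of its conditions'
#' simulations failed; the first failing category is reported.
#'
#' @param result a `simulation_result`, `gradient_result`, or a list of
#'   them (one per condition).
#' @return `"ok"` or a failure category string.
#' @export
classify_outcome <- function(result) {
  if (inherits(result, c("simulation_result", "gradient_result")))
    return(result$status)
  for (r in result) if (r$status != "ok") return(r$status)
  "ok"
}

#' Pairwise gradient agreement statistics
#'
#' For each pair of gradient collections restricted to mutually successful
#' samples: the Pearson correlation of pooled gradient entries after a
#' log10 transform of absolute values (entries below the floor in either
#' set are excluded), the untransformed Pearson correlation, the number of
#' sign mismatches, and the maximum and median elementwise relative
#' deviations \eqn{|g_1-g_2| / \max(|g_1|, |g_2|, \mathrm{floor})}.
#'
#' @param grad_sets named list; each element a list of gradient vectors
#'   (or `NULL` for failed samples), all of equal length.
#' @param floor magnitude floor for the log transform and the deviation
#'   denominator.
#' @return data.frame with one row per unordered pair of sets; pairs with
#'   fewer than two mutually successful samples are marked undefined
#'   (`NA` statistics, `defined = FALSE`).
#' @export
compare_gradients <- function(grad_sets, floor = 1e-12) {
  nms <- names(grad_sets)
  empty <- data.frame(pair_a = character(0), pair_b = character(0),
                      n_common = integer(0), defined = logical(0),
                      pearson_log10 = numeric(0), pearson = numeric(0),
                      sign_mismatches = integer(0),
                      max_rel_dev = numeric(0), median_rel_dev = numeric(0))
  if (length(grad_sets) < 2) return(empty)
  out <- list()
  for (a in seq_along(nms)) for (b in seq_along(nms)) {
    if (b <= a) next
    ga <- grad_sets[[a]]; gb <- grad_sets[[b]]
    common <- which(!vapply(ga, is.null, logical(1)) &
                      !vapply(gb, is.null, logical(1)))
    row <- list(pair_a = nms[a], pair_b = nms[b],
                n_common = length(common), defined = length(common) >= 2,
                pearson_log10 = NA_real_, pearson = NA_real_,
                sign_mismatches = NA_integer_,
                max_rel_dev = NA_real_, median_rel_dev = NA_real_)
    if (length(common) >= 2) {
      va <- unlist(ga[common]); vb <- unlist(gb[common])
      keep <- abs(va) > floor & abs(vb) > floor
      row$pearson_log10 <- if (sum(keep) >= 2 &&
                               stats::sd(log10(abs(va[keep]))) > 0 &&
                               stats::sd(log10(abs(vb[keep]))) > 0)
        stats::cor(log10(abs(va[keep])), log10(abs(vb[keep]))) else NA_real_
      row$pearson <- if (stats::sd(va) > 0 && stats::sd(vb) > 0)
        stats::cor(va, vb) else NA_real_
      row$sign_mismatches <- sum(sign(va[keep]) != sign(vb[keep]))
      rel <- abs(va - vb) / pmax(abs(va), abs(vb), floor)
      row$max_rel_dev <- max(rel)
      row$median_rel_dev <- stats::median(rel)
    }
    out[[length(out) + 1]] <- as.data.frame(row)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Run the method-pair benchmark on one problem
#'
#' For each sampled parameter vector and each method pair, computes the
#' objective gradient, tabulates failure categories, pairwise gradient
#' agreement over mutually successful samples, and per-phase timings.
#' Deterministic for a given seed up to the wall-clock fields.
#'
#' @param model,deriv model and derivatives.
#' @param data an [dataset()].
#' @param pairs list of [method_pair()] objects (default: all six).
#' @param n number of parameter samples.
#' @param seed sampling seed.
#' @param config an [eqsens_config()].
#' @param collect_timings also run a plain (gradient-free) simulation per
#'   successful sample to record the equilibration/dynamic/overhead wall
#'   -clock split; disable to halve the cost when only failure rates and
#'   gradient agreement are needed.
#' @return a list of class `benchmark_report` with `failures` (per-pair
#'   category counts), `failure_rates` (percent), `agreement`
#'   (from [compare_gradients()]), `timings`, `gradients`, `n_samples`,
#'   `seed`.
#' @export
run_benchmark <- function(model, deriv, data, pairs = all_method_pairs(),
                          n = 100, seed = 1L, config = eqsens_config(),
                          collect_timings = TRUE) {
  thetas <- sample_parameters(model, n, seed)
  categories <- c("ok", "numerical_error", "negative_state",
                  "no_steady_state", "newton_nonconverged",
                  "tailored_method_inapplicable")
  pair_names <- vapply(pairs, function(p) p$name, character(1))
  names(pairs) <- pair_names
  counts <- matrix(0L, length(pairs), length(categories),
                   dimnames = list(pair_names, categories))
  grads <- stats::setNames(
    lapply(pairs, function(p) vector("list", n)), pair_names)
  timings <- stats::setNames(
    lapply(pairs, function(p)
      data.frame(total = rep(NA_real_, n), equilibration = NA_real_,
                 dynamic = NA_real_, gradient_total = NA_real_)),
    pair_names)
  objective <- matrix(NA_real_, n, length(pairs),
                      dimnames = list(NULL, pair_names))
  for (s in seq_len(n)) {
    for (pn in pair_names) {
      gres <- objective_gradient(model, deriv, thetas[[s]], data,
                                 pairs[[pn]], config)
      cat_s <- if (gres$status %in% categories) gres$status else
        "numerical_error"
      counts[pn, cat_s] <- counts[pn, cat_s] + 1L
      if (gres$status == "ok") {
        grads[[pn]][[s]] <- gres$gradient
        objective[s, pn] <- gres$objective_value
      }
      if (gres$status == "ok" && collect_timings) {
        ids <- unique(data$measurements$simulationConditionId)
        tms <- vapply(ids, function(id)
          simulate_condition(model, deriv, thetas[[s]],
                             data$conditions[[id]], data, pairs[[pn]],
                             config)$timings, numeric(3))
        timings[[pn]]$equilibration[s] <- sum(tms["equilibration", ])
        timings[[pn]]$dynamic[s] <- sum(tms["dynamic", ])
        timings[[pn]]$total[s] <- sum(tms)
      }
      timings[[pn]]$gradient_total[s] <- gres$timings[["total"]]
    }
  }
  failure_rates <- 100 * (1 - counts[, "ok"] / n)
  structure(list(
    failures = counts,
    failure_rates = failure_rates,
    agreement = compare_gradients(grads),
    gradients = grads,
    objective = objective,
    timings = timings,
    n_samples = n, seed = seed), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report:", x$n_samples, "samples (seed", x$seed, ")\n")
  cat("failure rates (%):\n")
  print(round(x$failure_rates, 2))
  if (!is.null(x$agreement) && nrow(x$agreement)) {
    cat("gradient agreement (mutually successful samples):\n")
    print(x$agreement[, c("pair_a", "pair_b", "n_common", "pearson_log10",
                          "max_rel_dev", "median_rel_dev")], digits = 4)
  }
  invisible(x)
}
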