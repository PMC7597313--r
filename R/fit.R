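#' Exact outcome probabilities of the two-condition paradigm
#'
#' For a model and a [paradigm_design()], computes the exact probability of
#' every observable outcome in each condition: the choice-confidence
#' condition has one cell per (choice, confidence) pair (unnormalised
#' Lueders joint probabilities — they sum to one because both stages are
#' complete partitions and the flow preserves the trace), and the
#' confidence-alone condition one cell per confidence outcome.
#'
#' @inheritParams interference_statistic
#' @return A tibble with columns `condition`, `choice` (`NA` in the
#'   confidence-alone condition), `confidence`, `prob`.
#' @export
paradigm_probabilities <- function(model, state0, design,
                                   method = c("expm", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "paradigm_design"))
  joint <- make_joint_fn(model, state0, method)
  cc <- tidyr::expand_grid(ci = seq_along(design$choice),
                           fi = seq_along(design$confidence))
  cc <- dplyr::mutate(
    cc,
    condition = "choice_confidence",
    choice = vapply(.data$ci, function(i) design$choice[[i]]$label, character(1)),
    confidence = vapply(.data$fi, function(i) design$confidence[[i]]$label,
                        character(1)),
    prob = purrr::map2_dbl(.data$ci, .data$fi, function(i, j)
      joint(list(design$choice[[i]], design$confidence[[j]]),
            c(design$t1, design$t2)))
  )
  ca <- tibble::tibble(
    condition = "confidence_alone",
    choice = NA_character_,
    confidence = vapply(design$confidence, function(m) m$label, character(1)),
    prob = vapply(design$confidence, function(mc)
      joint(list(mc), design$t2), numeric(1))
  )
  out <- dplyr::bind_rows(dplyr::select(cc, "condition", "choice",
                                        "confidence", "prob"), ca)
  tot <- dplyr::summarise(dplyr::group_by(out, .data$condition),
                          s = sum(.data$prob))
  if (max(abs(tot$s - 1)) > 1e-8)
    ow_numerical_error("outcome probabilities do not sum to 1 per condition")
  out
}

make_joint_fn <- function(model, state0, method) {
  if (inherits(model, "markov_generator")) {
    stopifnot(inherits(state0, "probability_state"))
    return(function(projs, times)
      joint_response_probability(model, state0, projs, times))
  }
  if (inherits(state0, "amplitude_state")) state0 <- pure_density(state0)
  stopifnot(inherits(state0, "density_state"))
  if (inherits(model, "hamiltonian"))
    return(function(projs, times)
      joint_response_probability_quantum(model, state0, projs, times))
  stopifnot(inherits(model, "open_system"))
  function(projs, times)
    joint_response_probability_open(model, state0, projs, times,
                                    method = method)
}

#' Sample a synthetic choice-confidence dataset
#'
#' Draws trial counts from the exact outcome probabilities of the paradigm
#' (multinomial sampling), reproducibly under a fixed seed. Either condition
#' or both can be sampled.
#'
#' @inheritParams paradigm_probabilities
#' @param n_trials Trials per condition (>= 1).
#' @param condition `"both"` (default), `"choice_confidence"`, or
#'   `"confidence_alone"`.
#' @param seed Integer RNG seed.
#' @return A tibble (class `paradigm_sample`) with columns `condition`,
#'   `choice`, `confidence`, `prob`, `count`; attributes `seed` and
#'   `n_trials`.
#' @export
simulate_paradigm <- function(model, state0, design, n_trials,
                              condition = c("both", "choice_confidence",
                                            "confidence_alone"),
                              seed = 1L, method = c("expm", "ode")) {
  condition <- match.arg(condition)
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  probs <- paradigm_probabilities(model, state0, design, method)
  if (condition != "both")
    probs <- dplyr::filter(probs, .data$condition == !!condition)
  set.seed(seed)
  out <- probs |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(count = as.integer(rmultinom(1, n_trials, .data$prob))) |>
    dplyr::ungroup()
  structure(out, class = c("paradigm_sample", class(out)),
            seed = seed, n_trials = n_trials)
}

#' Maximum-likelihood recovery of the mixing weight
#'
#' Fits the weight `w` of an open-system model family to paradigm count
#' data by multinomial maximum likelihood: for each candidate `w` the exact
#' outcome probabilities of `open_system(H, G, w)` are computed (no
#' simulation, so the likelihood is deterministic given the data) and the
#' log likelihood `sum(count * log(prob))` accumulated over both conditions.
#' A dense profile over `grid` is refined by golden-section search around
#' the grid optimum. A flat profile (all candidates within `1e-6` of the
#' maximum) is reported rather than resolved arbitrarily.
#'
#' @param data A `paradigm_sample` or any tibble with columns `condition`,
#'   `choice`, `confidence`, `count`.
#' @param H The family's [hamiltonian_walk()].
#' @param G The family's [lindblad_coupling].
#' @param state0 Initial `density_state` (or `amplitude_state`).
#' @param design The [paradigm_design()] used to collect `data`.
#' @param grid Candidate weights in `[0, 1]` (default: step 0.01).
#' @param method Propagation route.
#' @return An object of class `weight_fit`: list with `w_hat`, `loglik`,
#'   `profile` (tibble: w, loglik), `flat`, `n_trials` per condition.
#' @export
fit_weight <- function(data, H, G, state0, design,
                       grid = seq(0, 1, by = 0.01),
                       method = c("expm", "ode")) {
  method <- match.arg(method)
  needed <- c("condition", "choice", "confidence", "count")
  if (!all(needed %in% names(data)))
    abort("`data` must contain condition, choice, confidence, count.")
  if (inherits(state0, "amplitude_state")) state0 <- pure_density(state0)

  counts <- dplyr::summarise(
    dplyr::group_by(data, .data$condition, .data$choice, .data$confidence),
    count = sum(.data$count), .groups = "drop")

  loglik_at <- function(w) {
    probs <- paradigm_probabilities(open_system(H, G, w), state0, design,
                                    method)
    joined <- dplyr::left_join(counts, probs,
                               by = c("condition", "choice", "confidence"))
    if (anyNA(joined$prob))
      abort("data contain outcomes not generated by the design")
    with(joined, sum(ifelse(count > 0, count * log(prob), 0)))
  }

  prof <- tibble::tibble(w = grid,
                         loglik = vapply(grid, loglik_at, numeric(1)))
  flat <- (max(prof$loglik) - min(prof$loglik)) < 1e-6
  i <- which.max(prof$loglik)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (!flat && hi > lo) {
    opt <- optimize(loglik_at, c(lo, hi), maximum = TRUE, tol = 1e-6)
    w_hat <- opt$maximum
    ll_hat <- opt$objective
    if (ll_hat < prof$loglik[i]) { w_hat <- grid[i]; ll_hat <- prof$loglik[i] }
  } else {
    w_hat <- grid[i]
    ll_hat <- prof$loglik[i]
    if (flat) warning("log-likelihood profile is flat in w; w_hat is arbitrary",
                      call. = FALSE)
  }
  n_tab <- dplyr::summarise(dplyr::group_by(counts, .data$condition),
                            n = sum(.data$count))
  structure(
    list(w_hat = w_hat, loglik = ll_hat, profile = prof, flat = flat,
         n_trials = setNames(n_tab$n, n_tab$condition)),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("<weight_fit> w_hat = ", format(x$w_hat, digits = 4),
      ", log-likelihood = ", format(x$loglik, digits = 8),
      if (x$flat) "  [flat profile]", "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_weight Tidy the likelihood profile (one row per candidate
#'   weight).
#' @param x A `weight_fit`.
#' @param ... Unused.
#' @export
tidy.weight_fit <- function(x, ...) x$profile

#' @describeIn fit_weight One-row model summary (estimate, log-likelihood,
#'   trial counts, flat-profile flag).
#' @export
glance.weight_fit <- function(x, ...) {
  tibble::tibble(
    w_hat = x$w_hat, loglik = x$loglik, flat = x$flat,
    n_choice_confidence = unname(x$n_trials["choice_confidence"]) %|NA|% 0L,
    n_confidence_alone = unname(x$n_trials["confidence_alone"]) %|NA|% 0L
  )
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
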