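## ---------------------------------------------------------------------------
## Decision Field Theory-Planning: R-facing wrappers around the C++ core.
## ---------------------------------------------------------------------------

#' DFT accumulator parameters
#'
#' @param theta_plan evidence threshold (points of accumulated valence) for
#'   first-stage deliberation and for simulated second-stage decisions;
#'   must be positive.
#' @param theta_final threshold for final second-stage and single-stage
#'   choices; defaults to `theta_plan` (the single-threshold model).
#' @param phi probability that the higher-magnitude outcome is sampled at a
#'   two-outcome terminal chance node while planning (`0.5` = unbiased).
#' @param delta probability a mental simulation is replaced by a daydream:
#'   a uniform draw over `daydream_range`.
#' @param switch_point integer 0--4: the block after which planning starts
#'   (0 = always plans, 4 = never plans); used by the switch variant.
#' @param daydream_range `(n, m)`: minimum and maximum outcome values
#'   across all trials in the experiment.
#' @param max_steps deliberation cap; if reached, choice is forced by the
#'   sign of the preference state (ties by fair coin).
#' @return object of class `dft_params`.
#' @export
dft_params <- function(theta_plan, theta_final = theta_plan, phi = 0.5,
                       delta = 0, switch_point = 0L,
                       daydream_range = c(0, 120), max_steps = 10000L) {
  stopifnot(theta_plan > 0, theta_final > 0,
            phi >= 0, phi <= 1, delta >= 0, delta <= 1,
            switch_point %in% 0:4,
            length(daydream_range) == 2L,
            daydream_range[1] <= daydream_range[2])
  structure(list(theta_plan = theta_plan, theta_final = theta_final,
                 phi = phi, delta = delta,
                 switch_point = as.integer(switch_point),
                 daydream_range = as.numeric(daydream_range),
                 max_steps = as.integer(max_steps)),
            class = "dft_params")
}

#' @export
print.dft_params <- function(x, ...) {
  cat(sprintf(
    "<dft_params> theta_plan=%g theta_final=%g phi=%.2f delta=%.2f sp=%d\n",
    x$theta_plan, x$theta_final, x$phi, x$delta, x$switch_point))
  invisible(x)
}

#' DFT model variants
#'
#' * `DFT2`: separate planning and final thresholds; simulates future
#'   second-stage decisions while deliberating at the first stage.
#' * `DFT1`: as `DFT2` but one threshold (`theta_plan = theta_final`).
#' * `DFT2_no_plan`, `DFT1_no_plan`: future decision nodes are treated as
#'   fair coin flips instead of simulated decisions.
#' * `DFT2_switch`: `DFT2` that starts out non-planning and begins planning
#'   after the block given by `switch_point` (a change in the other
#'   direction is not considered).
#'
#' @param variant one of the five variant names.
#' @return object of class `dft_model_spec` with fields `variant`,
#'   `tie_thresholds`, `plans` (`TRUE`, `FALSE` or `"switch"`), and
#'   `free` (names of free parameters).
#' @export
model_spec <- function(variant = c("DFT2", "DFT1", "DFT2_no_plan",
                                   "DFT1_no_plan", "DFT2_switch")) {
  variant <- match.arg(variant)
  tie <- variant %in% c("DFT1", "DFT1_no_plan")
  plans <- if (variant %in% c("DFT1", "DFT2")) TRUE
           else if (variant == "DFT2_switch") "switch" else FALSE
  free <- c(if (tie) "theta" else c("theta_plan", "theta_final"),
            "phi", "delta",
            if (identical(plans, "switch")) "switch_point")
  structure(list(variant = variant, tie_thresholds = tie, plans = plans,
                 free = free, n_free = length(free)),
            class = "dft_model_spec")
}

#' @export
print.dft_model_spec <- function(x, ...) {
  cat(sprintf("<dft_model_spec> %s (%d free parameters)\n",
              x$variant, x$n_free))
  invisible(x)
}

## Does the variant simulate second-stage decisions while planning at DN1
## in the given block?
dft_plans_dn2 <- function(spec, block, params = NULL) {
  if (identical(spec$plans, "switch")) {
    sp <- if (is.null(params)) 0L else params$switch_point
    block > sp
  } else isTRUE(spec$plans)
}

## Enforce a spec's parameter-tying rules on a dft_params object.
apply_spec <- function(spec, params) {
  if (spec$tie_thresholds) params$theta_final <- params$theta_plan
  if (!identical(spec$plans, "switch"))
    params$switch_point <- if (isTRUE(spec$plans)) 0L else 4L
  params
}

## Flatten a decision_tree into the arrays the C++ core consumes.
## Memoized: encoding is pure in the tree's structure, and the fitting
## loops hit the same handful of template trees thousands of times.
.tree_enc_cache <- new.env(parent = emptyenv())

encode_tree <- function(tree) {
  key <- paste(tree$kind, tree$template_id,
               paste(names(tree$nodes), collapse = ","),
               paste(unlist(lapply(tree$nodes, function(n)
                 c(n$children, n$value))), collapse = ","),
               paste(as.integer(tree$scramble_map), collapse = ""),
               sep = "#")
  hit <- get0(key, envir = .tree_enc_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  enc <- encode_tree_impl(tree)
  assign(key, enc, envir = .tree_enc_cache)
  enc
}

encode_tree_impl <- function(tree) {
  ids <- names(tree$nodes)
  idx <- setNames(seq_along(ids) - 1L, ids)
  type <- vapply(tree$nodes, function(n)
    switch(n$role, ON = 0L, CN = 1L, DN = 2L), 0L)
  value <- vapply(tree$nodes, function(n)
    if (is.na(n$value)) 0 else n$value, 0)
  kids <- integer(); probs <- numeric()
  ks <- integer(length(ids)); kn <- integer(length(ids))
  for (i in seq_along(ids)) {
    nd <- tree$nodes[[i]]
    ks[i] <- length(kids)
    kn[i] <- length(nd$children)
    kids <- c(kids, unname(idx[nd$children]))
    probs <- c(probs, if (nd$role == "CN") nd$probs
               else rep(NA_real_, length(nd$children)))
  }
  list(type = unname(type), value = unname(value), ks = ks, kn = kn,
       kids = kids, probs = probs, idx = idx, ids = ids)
}

#' Mentally simulate the outcome of an alternative
#'
#' Draws `n` independent mental simulations of the eventual outcome of
#' taking `node`: daydreams with probability `delta`, otherwise traces a
#' path through the (sub)tree, resolving chance nodes by their
#' probabilities (with magnitude bias `phi` at two-outcome terminal chance
#' nodes during planning) and future decision nodes by a simulated
#' decision at `theta_plan` (or a coin flip when `plan_dn2 = FALSE`).
#'
#' @param tree a `decision_tree`.
#' @param node node id to simulate.
#' @param mode `"planning"` or `"final"`.
#' @param params a [dft_params()] object.
#' @param n number of simulations.
#' @param plan_dn2 whether future DNs are simulated decisions (`TRUE`) or
#'   coin flips (`FALSE`).
#' @param seed optional integer seed (uses the current RNG state if
#'   `NULL`).
#' @return numeric vector of `n` simulated outcome values.
#' @export
simulate_outcome <- function(tree, node, mode = c("planning", "final"),
                             params, n = 1L, plan_dn2 = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  enc <- encode_tree(tree)
  if (!node %in% enc$ids) stop("unreachable node '", node, "'")
  run <- function() cpp_sim_outcomes(enc$type, enc$value, enc$ks, enc$kn,
                                     enc$kids, enc$probs, enc$idx[[node]],
                                     mode == "planning", plan_dn2,
                                     unclass(params), n)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Run one or more accumulation-to-threshold decisions
#'
#' Iterates valences `V = nu_i - nu_j` (one simulated outcome per
#' alternative per step) onto the preference state until `|P|` reaches the
#' mode's threshold (`theta_plan` when planning, `theta_final` for final
#' choices); the sign determines the choice.
#'
#' @inheritParams simulate_outcome
#' @param dn id of a binary decision node.
#' @return list with `choice` (character vector of chosen child ids),
#'   `steps` (integer vector), and `forced` (count of max-step forced
#'   choices).
#' @export
simulate_decision <- function(tree, dn, mode = c("planning", "final"),
                              params, n = 1L, plan_dn2 = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  nd <- tree$nodes[[dn]]
  if (is.null(nd) || nd$role != "DN") stop("'", dn, "' is not a decision node")
  if (length(nd$children) != 2L) stop("simulate_decision requires a binary DN")
  enc <- encode_tree(tree)
  run <- function() cpp_sim_decisions(enc$type, enc$value, enc$ks, enc$kn,
                                      enc$kids, enc$probs, enc$idx[[dn]],
                                      mode == "planning", plan_dn2,
                                      unclass(params), n)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  list(choice = nd$children[res$choice + 1L], steps = res$steps,
       forced = res$forced)
}

## Single choice using the current RNG state (for trial simulation).
dft_choose <- function(tree, dn, mode, params, plan_dn2 = TRUE) {
  simulate_decision(tree, dn, mode, params, n = 1L, plan_dn2 = plan_dn2)$choice
}

clip_prob <- function(p, n_sims) {
  lo <- 1 / (2 * n_sims)
  pmin(pmax(p, lo), 1 - lo)
}

## Probability of choosing the *canonically first* child of `dn`,
## estimated from n_sims simulated decisions, clipped away from 0/1.
dft_choice_prob <- function(tree, dn, mode, params, n_sims, plan_dn2, seed) {
  res <- simulate_decision(tree, dn, mode, params, n = n_sims,
                           plan_dn2 = plan_dn2, seed = seed)
  first <- canonical_children(tree, dn)[1]
  clip_prob(mean(res$choice == first), n_sims)
}

#' Predicted choice probabilities for one trial
#'
#' First-stage probabilities come from `n_sims` planning-mode decisions
#' (with the second-stage policy -- simulate vs. coin flip -- determined by
#' the variant and, for the switch variant, by whether the trial's block
#' falls after `switch_point`).  Second-stage probabilities come from
#' `n_sims` final-mode decisions at the realized DN2.  Single-stage trials
#' use final mode.  Probabilities are clipped to
#' `[1/(2 n_sims), 1 - 1/(2 n_sims)]`.
#'
#' @param trial one trial-record row (needs `condition`, `block`,
#'   `template_id`, and `dn2_node` when a second stage was reached).
#' @param trees a template set from [build_template_set()].
#' @param spec a [model_spec()].
#' @param params a [dft_params()]; tying rules of `spec` are applied.
#' @param n_sims simulations per probability estimate (default 300).
#' @param seed integer seed.
#' @return list with `dn1` (named probabilities of the canonical left and
#'   right first-stage choices) and `dn2` (same for the realized DN2, or
#'   `NULL` for single-stage trials).
#' @export
predict_trial <- function(trial, trees, spec, params, n_sims = 300L,
                          seed = 1L) {
  params <- apply_spec(spec, params)
  tree <- trees[[trial$condition]][[trial$template_id]]
  if (trial$condition == "single_stage") {
    p1 <- dft_choice_prob(tree, tree$root, "final", params, n_sims,
                          plan_dn2 = TRUE,
                          seed = substream_seed(seed, trial$condition,
                                                trial$template_id, "DN1"))
    return(list(dn1 = c(left = p1, right = 1 - p1), dn2 = NULL))
  }
  plan <- dft_plans_dn2(spec, trial$block, params)
  p1 <- dft_choice_prob(tree, tree$root, "planning", params, n_sims,
                        plan_dn2 = plan,
                        seed = substream_seed(seed, trial$condition,
                                              trial$template_id, "DN1", plan))
  p2 <- dft_choice_prob(tree, trial$dn2_node, "final", params, n_sims,
                        plan_dn2 = TRUE,
                        seed = substream_seed(seed, trial$condition,
                                              trial$template_id,
                                              trial$dn2_node))
  list(dn1 = c(left = p1, right = 1 - p1),
       dn2 = c(left = p2, right = 1 - p2))
}

#' Exact absorption probability of a discrete random walk
#'
#' Independent oracle for the accumulator: for a walk started at 0 with
#' i.i.d. increments `values` (probabilities `probs`), absorbed when the
#' running sum reaches `+theta` (success) or `-theta` (failure), computes
#' the exact success probability by enumerating the reachable lattice of
#' interior states and solving the linear first-step equations.  Feasible
#' whenever the increment set is small (the intended use: increments taking
#' at most three distinct values).
#'
#' @param values distinct increment values (at least one positive and one
#'   negative, else the walk never splits).
#' @param probs increment probabilities (sum to 1).
#' @param theta absorbing threshold (> 0).
#' @param max_states safety cap on the enumerated interior states.
#' @return probability of hitting `+theta` before `-theta`.
#' @export
rw_absorption_prob <- function(values, probs, theta, max_states = 20000L) {
  stopifnot(length(values) == length(probs), theta > 0,
            abs(sum(probs) - 1) < 1e-9, all(probs >= 0))
  if (all(values >= 0)) return(1)
  if (all(values <= 0)) return(0)
  key <- function(s) sprintf("%.9f", s)
  states <- new.env(parent = emptyenv())
  frontier <- 0
  assign(key(0), 0, envir = states)
  while (length(frontier)) {
    nxt <- numeric(0)
    for (s in frontier) {
      for (v in values) {
        t <- s + v
        if (abs(t) < theta - 1e-12 &&
            !exists(key(t), envir = states, inherits = FALSE)) {
          assign(key(t), t, envir = states)
          nxt <- c(nxt, t)
        }
      }
    }
    if (length(ls(states)) > max_states)
      stop("rw_absorption_prob: state space exceeds max_states")
    frontier <- nxt
  }
  st <- sort(unlist(as.list(states)))
  n <- length(st)
  idx <- setNames(seq_len(n), vapply(st, key, ""))
  A <- diag(n); b <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_along(values)) {
      t <- st[i] + values[k]
      if (t >= theta - 1e-12) b[i] <- b[i] + probs[k]
      else if (t > -theta + 1e-12) {
        j <- idx[[key(t)]]
        A[i, j] <- A[i, j] - probs[k]
      }
    }
  }
  p <- solve(A, b)
  unname(p[idx[[key(0)]]])
}

#' Trace one deliberation step by step
#'
#' Debugging interface: runs a single accumulation-to-threshold decision
#' and records the simulated outcomes, valence, and preference state at
#' every step.
#'
#' @inheritParams simulate_decision
#' @param path optional CSV path; when given, the trace is written with
#'   columns `step, nu_i, nu_j, V, P`.
#' @return list with `choice` (child id) and `trace` (data frame).
#' @export
simulate_decision_trace <- function(tree, dn, mode = c("planning", "final"),
                                    params, plan_dn2 = TRUE, seed = NULL,
                                    path = NULL) {
  mode <- match.arg(mode)
  nd <- tree$nodes[[dn]]
  if (is.null(nd) || nd$role != "DN" || length(nd$children) != 2L)
    stop("simulate_decision_trace requires a binary DN")
  enc <- encode_tree(tree)
  run <- function() cpp_sim_decision_trace(enc$type, enc$value, enc$ks,
                                           enc$kn, enc$kids, enc$probs,
                                           enc$idx[[dn]], mode == "planning",
                                           plan_dn2, unclass(params))
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  trace <- data.frame(step = seq_along(res$P), nu_i = res$nu_i,
                      nu_j = res$nu_j, V = res$V, P = res$P)
  if (!is.null(path)) write.csv(trace, path, row.names = FALSE)
  list(choice = nd$children[res$choice + 1L], trace = trace)
}
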