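## ---------------------------------------------------------------------------
## Simulation-based likelihood, grid-search fitting, four-fold
## cross-validation, and behavioral maximization rates.
## ---------------------------------------------------------------------------

## Build the table of distinct predictions a set of trials needs:
## one first-stage entry per (condition, template, plan-policy) and one
## second-stage entry per realized (condition, template, DN2).  Trials of
## the same template share these probabilities, which makes the simulated
## likelihood dramatically cheaper than predicting trial by trial.
plan_policy <- function(trials, spec, params) {
  plan <- if (identical(spec$plans, "switch"))
    vapply(trials$block, function(b) dft_plans_dn2(spec, b, params), TRUE)
  else rep(isTRUE(spec$plans), nrow(trials))
  ifelse(trials$condition == "single_stage", NA, plan)
}

prediction_keys <- function(trials, spec, params) {
  k1 <- unique(data.frame(
    condition = trials$condition, template_id = trials$template_id,
    node = "DN1",
    plan = plan_policy(trials, spec, params),
    stringsAsFactors = FALSE))
  two <- trials[trials$condition != "single_stage", ]
  k2 <- unique(data.frame(
    condition = two$condition, template_id = two$template_id,
    node = two$dn2_node, plan = rep(NA, nrow(two)),
    stringsAsFactors = FALSE))
  rbind(k1, k2)
}

## Probability of the canonical-left choice for every key row.
## Common random numbers: the seed of each entry depends only on the key
## (never on the parameters), so grid evaluations are comparable and
## repeated evaluations deterministic.
predict_table <- function(keys, trees, spec, params, n_sims, seed) {
  params <- apply_spec(spec, params)
  p <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    tree <- trees[[k$condition]][[k$template_id]]
    sseed <- substream_seed(seed, k$condition, k$template_id, k$node,
                            isTRUE(k$plan))
    p[i] <- if (k$node == "DN1") {
      if (k$condition == "single_stage")
        dft_choice_prob(tree, tree$root, "final", params, n_sims,
                        plan_dn2 = TRUE, seed = sseed)
      else
        dft_choice_prob(tree, tree$root, "planning", params, n_sims,
                        plan_dn2 = isTRUE(k$plan), seed = sseed)
    } else {
      dft_choice_prob(tree, k$node, "final", params, n_sims,
                      plan_dn2 = TRUE, seed = sseed)
    }
  }
  keys$p_left <- p
  keys
}

key_id <- function(df)
  paste(df$condition, df$template_id, df$node, df$plan, sep = "|")

## Per-choice predicted probabilities of the *observed* choices: one per
## first-stage choice, plus one per realized second-stage choice.
## `include` allows ablating either stage from the likelihood.
observed_choice_probs <- function(trials, tab, spec, params,
                                  include = c("DN1", "DN2")) {
  tid <- key_id(tab)
  pr1 <- pr2 <- numeric(0)
  if ("DN1" %in% include) {
    plan <- plan_policy(trials, spec, params)
    k1 <- paste(trials$condition, trials$template_id, "DN1", plan, sep = "|")
    p1 <- tab$p_left[match(k1, tid)]
    pr1 <- ifelse(trials$dn1_choice == "left", p1, 1 - p1)
  }
  if ("DN2" %in% include) {
    two <- trials$condition != "single_stage"
    k2 <- paste(trials$condition[two], trials$template_id[two],
                trials$dn2_node[two], NA, sep = "|")
    p2 <- tab$p_left[match(k2, tid)]
    pr2 <- ifelse(trials$dn2_choice[two] == "left", p2, 1 - p2)
  }
  c(pr1, pr2)
}

#' Simulated binomial log-likelihood of observed choices
#'
#' Sums the log of the model's predicted (clipped) probability of every
#' observed choice: the first-stage choice on every trial plus the realized
#' second-stage choice on two-stage trials.  Predictions are estimated from
#' `n_sims` simulations per distinct (template, node, policy) combination
#' with common random numbers, so the function is deterministic given
#' `seed` and comparable across parameter values.
#'
#' @param trials trial-record data frame (or `dyn_cohort`).
#' @param trees template set (taken from the cohort when omitted).
#' @param spec a [model_spec()].
#' @param params a [dft_params()].
#' @param n_sims simulations per predicted probability.
#' @param seed integer seed for the common random numbers.
#' @param include which observed choices enter the likelihood: `"DN1"`
#'   (first-stage and single-stage) and/or `"DN2"` (realized second
#'   stage); both by default, matching a model of all choice trials
#'   simultaneously.
#' @return log-likelihood (scalar, `<= 0`), with attribute `n_choices`.
#' @export
loglik_dft <- function(trials, trees = NULL, spec, params, n_sims = 300L,
                       seed = 1L, include = c("DN1", "DN2")) {
  if (inherits(trials, "dyn_cohort")) {
    if (is.null(trees)) trees <- trials$trees
    trials <- trials$trials
  }
  stopifnot(nrow(trials) > 0)
  params <- apply_spec(spec, params)
  keys <- prediction_keys(trials, spec, params)
  tab <- predict_table(keys, trees, spec, params, n_sims, seed)
  probs <- observed_choice_probs(trials, tab, spec, params, include)
  ll <- sum(log(probs))
  attr(ll, "n_choices") <- length(probs)
  ll
}

#' Search configuration for DFT fitting
#'
#' Coarse-to-fine grid search.  Thresholds are log-spaced; by default the
#' sampling-bias grid covers `[0.5, 1]` (bias toward the higher magnitude)
#' and daydreaming `[0, 0.5]`; pass wider bounds to explore the full
#' ranges.
#'
#' @param grid_points grid resolution per free continuous dimension.
#' @param theta_bounds,phi_bounds,delta_bounds search bounds.
#' @param n_sims simulations per predicted probability.
#' @param refine number of refinement passes around the incumbent.
#' @param refine_points grid resolution of refinement passes (defaults to
#'   `grid_points`; smaller values trade precision for speed).
#' @return a list of class `dft_search_config`.
#' @export
dft_search_config <- function(grid_points = 8L, theta_bounds = c(1, 200),
                              phi_bounds = c(0.5, 1),
                              delta_bounds = c(0, 0.5),
                              n_sims = 300L, refine = 1L,
                              refine_points = grid_points) {
  stopifnot(grid_points >= 2L, theta_bounds[1] > 0)
  structure(list(grid_points = as.integer(grid_points),
                 theta_bounds = theta_bounds, phi_bounds = phi_bounds,
                 delta_bounds = delta_bounds, n_sims = as.integer(n_sims),
                 refine = as.integer(refine),
                 refine_points = as.integer(refine_points)),
            class = "dft_search_config")
}

## Per-parameter grid values within bounds.
param_grid <- function(name, bounds, k) {
  if (grepl("^theta", name)) exp(seq(log(bounds[1]), log(bounds[2]),
                                     length.out = k))
  else seq(bounds[1], bounds[2], length.out = k)
}

free_bounds <- function(name, search) {
  if (grepl("^theta", name)) search$theta_bounds
  else if (name == "phi") search$phi_bounds
  else search$delta_bounds
}

grid_to_params <- function(row, spec, daydream_range) {
  if (spec$tie_thresholds) {
    dft_params(theta_plan = row[["theta"]], phi = row[["phi"]],
               delta = row[["delta"]],
               switch_point = as.integer(row[["switch_point"]] %||% 0L),
               daydream_range = daydream_range)
  } else {
    dft_params(theta_plan = row[["theta_plan"]],
               theta_final = row[["theta_final"]], phi = row[["phi"]],
               delta = row[["delta"]],
               switch_point = as.integer(row[["switch_point"]] %||% 0L),
               daydream_range = daydream_range)
  }
}

#' Fit a DFT variant by coarse-to-fine grid search
#'
#' Maximizes [loglik_dft()] over the spec's free parameters on a full
#' factorial grid, then refines once (by default) on a finer grid bracketed
#' by the incumbent's neighbors.  The simulated likelihood is non-smooth,
#' so a derivative-free search with common random numbers is used rather
#' than gradient methods.  For the switch variant the switch point is
#' enumerated exhaustively (0--4) with the continuous parameters refit for
#' each value.
#'
#' @param trials one participant's trial records (or a `dyn_cohort` whose
#'   trials all belong to the fit).
#' @param trees template set.
#' @param spec a [model_spec()].
#' @param search a [dft_search_config()].
#' @param seed integer seed (common random numbers).
#' @param daydream_range outcome range for daydream draws; computed from
#'   the trees when `NULL`.
#' @return object of class `dft_fit`: `spec`, `params`, `loglik`,
#'   `n_choices`, `trace` (best point per pass).
#' @export
fit_dft <- function(trials, trees = NULL, spec,
                    search = dft_search_config(), seed = 1L,
                    daydream_range = NULL) {
  if (inherits(trials, "dyn_cohort")) {
    if (is.null(trees)) trees <- trials$trees
    trials <- trials$trials
  }
  if (is.null(daydream_range)) daydream_range <- tree_value_range(trees)
  cont <- setdiff(spec$free, "switch_point")
  sps <- if ("switch_point" %in% spec$free) 0:4 else 0L
  trace <- list(); best <- NULL
  for (sp in sps) {
    grids <- lapply(cont, function(nm)
      param_grid(nm, free_bounds(nm, search), search$grid_points))
    names(grids) <- cont
    for (pass in 0:search$refine) {
      grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
      grid$switch_point <- sp
      for (r in seq_len(nrow(grid))) {
        par <- grid_to_params(grid[r, ], spec, daydream_range)
        ll <- loglik_dft(trials, trees, spec, par,
                         n_sims = search$n_sims, seed = seed)
        if (is.null(best) || ll > best$loglik) {
          best <- list(params = par, loglik = as.numeric(ll),
                       n_choices = attr(ll, "n_choices"))
        }
        if (is.null(trace$incumbent) || ll > trace$incumbent)
          trace$incumbent <- as.numeric(ll)
      }
      if (pass < search$refine) {
        ## bracket the incumbent between its grid neighbors
        inc <- best$params
        grids <- lapply(cont, function(nm) {
          g <- grids[[nm]]
          v <- if (nm == "theta") inc$theta_plan else inc[[nm]]
          i <- which.min(abs(g - v))
          lo <- g[max(1L, i - 1L)]; hi <- g[min(length(g), i + 1L)]
          param_grid(nm, c(lo, hi), search$refine_points)
        })
        names(grids) <- cont
      }
    }
  }
  structure(list(spec = spec, params = apply_spec(spec, best$params),
                 loglik = best$loglik, n_choices = best$n_choices,
                 search = search, seed = seed, trace = trace),
            class = "dft_fit")
}

#' @export
print.dft_fit <- function(x, ...) {
  cat(sprintf("<dft_fit> %s  loglik=%.2f over %d choices\n",
              x$spec$variant, x$loglik, x$n_choices))
  print(x$params)
  invisible(x)
}

tree_value_range <- function(trees) {
  range(unlist(lapply(unlist(trees, recursive = FALSE), outcome_values)))
}

#' Four-fold cross-validated model selection for one participant
#'
#' Trials are randomly allocated to four training sets such that 25% of
#' each condition's trials fall in each (and only one) training set; the
#' complementary 75% form the validation set.  Each spec is fit on each
#' training set and scored on its validation set; the primary accuracy
#' measure is the mean predicted probability assigned to observed
#' validation choices (a binary hit rate with a .5 threshold is reported
#' alongside).  The winner is the spec with the highest mean accuracy
#' across folds, ties going to fewer free parameters and then input order.
#'
#' @param trials one participant's trial records.
#' @param trees template set.
#' @param specs list of [model_spec()] objects.
#' @param seed integer seed (fold assignment and common random numbers).
#' @param search a [dft_search_config()].
#' @return object of class `dft_cv`: `folds` (per-trial assignment),
#'   `accuracy` (spec x fold matrix), `hit_rate`, `mean_accuracy`,
#'   `winner`, `fits` (per spec, per fold).
#' @export
crossvalidate <- function(trials, trees, specs, seed = 1L,
                          search = dft_search_config()) {
  if (inherits(trials, "dyn_cohort")) {
    trees <- trials$trees; trials <- trials$trials
  }
  if (length(unique(trials$participant)) != 1L)
    stop("crossvalidate fits one participant at a time; see select_models()")
  conds <- unique(trials$condition)
  folds <- integer(nrow(trials))
  for (cond in conds) {
    i <- which(trials$condition == cond)
    if (length(i) < 4L)
      stop("condition '", cond, "' has fewer than 4 trials")
    folds[i] <- with_seed(substream_seed(seed, "folds", cond),
                          sample(rep(1:4, length.out = length(i))))
  }
  dd <- tree_value_range(trees)
  nspec <- length(specs)
  acc <- matrix(NA_real_, nspec, 4); hit <- matrix(NA_real_, nspec, 4)
  fits <- vector("list", nspec)
  for (s in seq_len(nspec)) {
    fits[[s]] <- vector("list", 4)
    for (f in 1:4) {
      train <- trials[folds == f, ]; valid <- trials[folds != f, ]
      fit <- fit_dft(train, trees, specs[[s]], search = search,
                     seed = substream_seed(seed, "fit", s, f),
                     daydream_range = dd)
      keys <- prediction_keys(valid, specs[[s]], fit$params)
      tab <- predict_table(keys, trees, specs[[s]], fit$params,
                           search$n_sims,
                           seed = substream_seed(seed, "valid", s, f))
      pr <- observed_choice_probs(valid, tab, specs[[s]], fit$params)
      acc[s, f] <- mean(pr)
      hit[s, f] <- mean(pr > 0.5)
      fits[[s]][[f]] <- fit
    }
  }
  mean_acc <- rowMeans(acc)
  nf <- vapply(specs, `[[`, 0L, "n_free")
  ord <- order(-mean_acc, nf, seq_len(nspec))
  winner <- specs[[ord[1]]]$variant
  rownames(acc) <- rownames(hit) <- vapply(specs, `[[`, "", "variant")
  structure(list(folds = folds, accuracy = acc, hit_rate = hit,
                 mean_accuracy = setNames(mean_acc, rownames(acc)),
                 winner = winner, fits = fits),
            class = "dft_cv")
}

#' @export
print.dft_cv <- function(x, ...) {
  cat("<dft_cv> winner:", x$winner, "\n")
  print(round(x$mean_accuracy, 3))
  invisible(x)
}

#' Cross-validated model selection for a whole cohort
#'
#' Runs [crossvalidate()] per participant and tabulates the winning
#' variants.
#'
#' @param cohort a `dyn_cohort` (or trial-record data frame plus `trees`).
#' @param specs list of [model_spec()] objects.
#' @param seed integer seed.
#' @param search a [dft_search_config()].
#' @param trees template set when `cohort` is a plain data frame.
#' @return list with `summary` (one row per participant: winner and mean
#'   accuracies) and `cv` (per-participant `dft_cv` objects).
#' @export
select_models <- function(cohort, specs, seed = 1L,
                          search = dft_search_config(), trees = NULL) {
  if (inherits(cohort, "dyn_cohort")) {
    trees <- cohort$trees; trials <- cohort$trials
  } else trials <- cohort
  ps <- sort(unique(trials$participant))
  cvs <- lapply(ps, function(p)
    crossvalidate(trials[trials$participant == p, ], trees, specs,
                  seed = substream_seed(seed, "cv", p), search = search))
  summary <- do.call(rbind, lapply(seq_along(ps), function(i)
    data.frame(participant = ps[i], winner = cvs[[i]]$winner,
               t(cvs[[i]]$mean_accuracy), check.names = FALSE)))
  list(summary = summary, cv = setNames(cvs, ps))
}

#' Backward-induction maximization rates
#'
#' Proportion of choices matching the backward-induction policy, split by
#' decision stage and condition, with per-participant means and standard
#' errors (SE of the participant means).
#'
#' @param trials trial records or a `dyn_cohort`.
#' @param trees template set (taken from the cohort when omitted).
#' @return data frame with columns `stage` (`DN1`/`DN2`), `condition`,
#'   `rate`, `se`, `n_participants`.
#' @export
maximization_rates <- function(trials, trees = NULL) {
  if (inherits(trials, "dyn_cohort")) {
    if (is.null(trees)) trees <- trials$trees
    trials <- trials$trials
  }
  bi <- list()
  for (cond in names(trees))
    for (tpl in seq_along(trees[[cond]])) {
      tr <- trees[[cond]][[tpl]]
      pol <- backward_induction(tr)
      sides <- vapply(names(pol$choice_at), function(dn)
        canonical_side(tr, dn, pol$choice_at[[dn]]), "")
      bi[[paste(cond, tpl)]] <- sides
    }
  match_dn1 <- vapply(seq_len(nrow(trials)), function(i) {
    s <- bi[[paste(trials$condition[i], trials$template_id[i])]]
    trials$dn1_choice[i] == s[["DN1"]]
  }, TRUE)
  two <- trials$condition != "single_stage"
  match_dn2 <- rep(NA, nrow(trials))
  match_dn2[two] <- vapply(which(two), function(i) {
    s <- bi[[paste(trials$condition[i], trials$template_id[i])]]
    trials$dn2_choice[i] == s[[trials$dn2_node[i]]]
  }, TRUE)
  out <- list()
  for (cond in unique(trials$condition)) {
    sel <- trials$condition == cond
    pm <- tapply(match_dn1[sel], trials$participant[sel], mean)
    out[[length(out) + 1L]] <- data.frame(
      stage = "DN1", condition = cond, rate = mean(pm),
      se = sd(pm) / sqrt(length(pm)), n_participants = length(pm))
    if (cond != "single_stage") {
      pm2 <- tapply(match_dn2[sel], trials$participant[sel], mean)
      out[[length(out) + 1L]] <- data.frame(
        stage = "DN2", condition = cond, rate = mean(pm2),
        se = sd(pm2) / sqrt(length(pm2)), n_participants = length(pm2))
    }
  }
  do.call(rbind, out)
}
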