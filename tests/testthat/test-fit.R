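# A deterministic one-choice world: the left gamble pays 100 on all eight
# outcomes, the right pays 0, so every simulated final choice goes left.
deterministic_single_trees <- function() {
  full <- full_tree(list(
    list(c(100, 100), c(100, 100)), list(c(100, 100), c(100, 100)),
    list(c(0, 0), c(0, 0)), list(c(0, 0), c(0, 0))))
  list(single_stage = list(derive_single_stage(full)))
}

test_that("loglik contributions hit the clip floor and add exactly", {
  trees <- deterministic_single_trees()
  spec <- model_spec("DFT2")
  par <- dft_params(50, delta = 0)
  trial <- data.frame(participant = 1L, block = 5L, trial = 1L,
                      condition = "single_stage", template_id = 1L,
                      dn1_choice = "right", dn2_node = NA_character_,
                      dn2_choice = NA_character_, stringsAsFactors = FALSE)
  ll <- loglik_dft(trial, trees, spec, par, n_sims = 300, seed = 1)
  expect_equal(as.numeric(ll), log(1 / 600))    # clip floor at n_sims = 300
  expect_equal(attr(ll, "n_choices"), 1L)

  # duplicating every trial doubles the log-likelihood exactly
  ll2 <- loglik_dft(rbind(trial, trial), trees, spec, par, n_sims = 300,
                    seed = 1)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll))
  expect_equal(attr(ll2, "n_choices"), 2L)
})

test_that("likelihood prefers generating parameters over distant ones", {
  trees <- build_template_set()
  vals <- dynchoice:::tree_value_range(trees)
  g <- dft_generator(model_spec("DFT2"),
                     dft_params(5, 25, phi = .8, delta = .1,
                                daydream_range = vals))
  wins <- 0L
  for (r in 1:10) {
    tr <- participant_trials(trees, g, ss(700, r), n_designs = 2L)
    ll_true <- loglik_dft(tr, trees, model_spec("DFT2"),
                          dft_params(5, 25, phi = .8, delta = .1,
                                     daydream_range = vals),
                          n_sims = 200, seed = r)
    ll_far <- loglik_dft(tr, trees, model_spec("DFT2"),
                         dft_params(1, 1, phi = .5, delta = .5,
                                    daydream_range = vals),
                         n_sims = 200, seed = r)
    wins <- wins + (ll_true >= ll_far)
  }
  expect_gte(wins, 9L)
})

test_that("grid search respects tying rules and is deterministic", {
  trees <- build_template_set()
  g <- dft_generator(model_spec("DFT1"), dft_params(20, phi = .7))
  tr <- participant_trials(trees, g, 51, n_designs = 1L)
  search <- dft_search_config(grid_points = 2L, refine = 0L, n_sims = 50L)
  f1 <- fit_dft(tr, trees, model_spec("DFT1"), search = search, seed = 3)
  expect_equal(f1$params$theta_plan, f1$params$theta_final)
  expect_lte(f1$loglik, 0)
  f2 <- fit_dft(tr, trees, model_spec("DFT1"), search = search, seed = 3)
  expect_equal(f1$params, f2$params)
  expect_equal(f1$loglik, f2$loglik)
})

test_that("cross-validation folds are exact within conditions", {
  trees <- build_template_set()
  g <- te_generator(.5, .9, .7, .1, .1)
  tr <- participant_trials(trees, g, 77, n_designs = 1L)
  search <- dft_search_config(grid_points = 2L, refine = 0L, n_sims = 50L)
  cv <- crossvalidate(tr, trees, list(model_spec("DFT2_no_plan")),
                      seed = 5, search = search)
  expect_true(all(cv$folds %in% 1:4))
  # 16 full, 16 half, 8 single-stage trials: 4/4/2 per training fold
  tab <- table(tr$condition, cv$folds)
  expect_true(all(tab["full", ] == 4L))
  expect_true(all(tab["half", ] == 4L))
  expect_true(all(tab["single_stage", ] == 2L))
  # every trial is in exactly one training fold, hence in 3 validation sets
  expect_equal(length(cv$folds), nrow(tr))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))

  few <- tr[tr$condition != "single_stage" | tr$trial %in% 33:35, ]
  expect_error(crossvalidate(few, trees, list(model_spec("DFT2")), seed = 1,
                             search = search), "fewer than 4")
})

test_that("winner ties break toward the more parsimonious spec", {
  acc <- matrix(c(.7, .7, .7, .7, .7, .7, .7, .7), nrow = 2, byrow = TRUE)
  # emulate the tie-break rule used by crossvalidate()
  specs <- list(model_spec("DFT2"), model_spec("DFT1"))
  nf <- vapply(specs, `[[`, 0L, "n_free")
  ord <- order(-rowMeans(acc), nf, seq_along(specs))
  expect_equal(specs[[ord[1]]]$variant, "DFT1")
})

test_that("maximization rates separate solvers from coin flippers", {
  trees <- build_template_set()
  co_max <- simulate_cohort(61, 4L, te_generator(1, 1, 1, 0, 0,
                                                 dn2_error = 0))
  mr <- maximization_rates(co_max)
  expect_true(all(mr$rate == 1))

  co_coin <- simulate_cohort(62, 6L, te_generator(.5, .5, .5, .5, .5,
                                                  dn2_error = .5))
  mr2 <- maximization_rates(co_coin)
  expect_true(all(abs(mr2$rate - .5) < .2))
  expect_true(all(mr2$n_participants == 6L))
})
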