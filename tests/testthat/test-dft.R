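test_that("outcome simulation honors certainty, bias, and daydreams", {
  tr <- tfix_tree()
  par0 <- dft_params(10, delta = 0)
  # a certain outcome node always returns its value
  half <- derive_half_tree(tr)
  on <- half$nodes[["DN2c"]]$children[2]
  expect_true(all(simulate_outcome(half, on, "final", par0, n = 200,
                                   seed = 1) == 50))
  # extreme sampling bias: a {101, 0} chance node always yields 101 when
  # planning with phi = 1
  par1 <- dft_params(10, phi = 1, delta = 0)
  expect_true(all(simulate_outcome(tr, "CN7", "planning", par1, n = 500,
                                   seed = 2) == 101))
  # ...but final-mode sampling is unbiased
  v <- simulate_outcome(tr, "CN7", "final", par1, n = 4000, seed = 3)
  expect_equal(mean(v == 101), .5, tolerance = 3 * sqrt(.25 / 4000) / .5)

  # full daydreaming: uniform over the stated range
  par2 <- dft_params(10, delta = 1, daydream_range = c(0, 120))
  d <- simulate_outcome(tr, "CN7", "planning", par2, n = 10000, seed = 4)
  se <- (120 / sqrt(12)) / sqrt(10000)
  expect_equal(mean(d), 60, tolerance = 3 * se)
  expect_true(all(d >= 0 & d <= 120))

  expect_error(simulate_outcome(tr, "ON99", "final", par0), "unreachable")
})

test_that("decision simulation matches analytic and enumeration oracles", {
  # certain 10 vs {20 w.p. .6, 0 w.p. .4} at theta = 10: every step
  # absorbs, so P(choose certain) = .4 exactly
  tr <- certain_vs_gamble_tree(10, 20, 0, .6)
  par <- dft_params(10, delta = 0)
  res <- simulate_decision(tr, "DN1", "final", par, n = 20000, seed = 5)
  expect_true(all(res$steps == 1))
  p_cert <- mean(res$choice == "ONA")
  expect_equal(p_cert, .4, tolerance = 3 * sqrt(.4 * .6 / 20000) / .4)
  expect_equal(rw_absorption_prob(c(-10, 10), c(.6, .4), 10), .4)

  # certain 12 vs {20, .5; 0, .5}: mean single-step valence = 12 - 10 = 2
  tr2 <- certain_vs_gamble_tree(12, 20, 0, .5)
  va <- simulate_outcome(tr2, "ONA", "final", par, n = 20000, seed = 6)
  vb <- simulate_outcome(tr2, "CNB", "final", par, n = 20000, seed = 7)
  expect_equal(mean(va) - mean(vb), 2, tolerance = 3 * 10 / sqrt(20000))

  # multi-step walk against the exact lattice enumeration
  p_exact <- rw_absorption_prob(c(12, -8), c(.5, .5), 20)
  par20 <- dft_params(20, delta = 0)
  res2 <- simulate_decision(tr2, "DN1", "final", par20, n = 20000, seed = 8)
  p_sim <- mean(res2$choice == "ONA")
  expect_equal(p_sim, p_exact,
               tolerance = 3 * sqrt(p_exact * (1 - p_exact) / 20000) / p_exact)
})

test_that("identical alternatives are chosen equally often", {
  tr <- symmetric_tree()
  for (par in list(dft_params(10), dft_params(40, phi = .9, delta = .2))) {
    res <- simulate_decision(tr, "DN1", "final", par, n = 10000, seed = 9)
    # 99% binomial bounds around .5
    expect_lt(abs(mean(res$choice == "CNA") - .5),
              2.58 * sqrt(.25 / 10000) + .01)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  tr <- tfix_tree()
  par <- dft_params(5, 25, phi = .8, delta = .1)
  a <- simulate_decision(tr, "DN1", "planning", par, n = 50, seed = 42)
  b <- simulate_decision(tr, "DN1", "planning", par, n = 50, seed = 42)
  expect_identical(a, b)
  c <- simulate_decision(tr, "DN1", "planning", par, n = 50, seed = 43)
  expect_false(identical(a$choice, c$choice) && identical(a$steps, c$steps))
})

test_that("max_steps forces a sign-based choice", {
  tr <- symmetric_tree(20, 20)              # V = 0 forever
  par <- dft_params(10, delta = 0, max_steps = 25L)
  res <- simulate_decision(tr, "DN1", "final", par, n = 200, seed = 10)
  expect_equal(res$forced, 200)
  expect_true(all(res$steps == 25L))
})

test_that("variant specs tie parameters and gate planning", {
  s1 <- model_spec("DFT1")
  expect_equal(s1$n_free, 3L)
  p <- dynchoice:::apply_spec(s1, dft_params(5, 25))
  expect_equal(p$theta_final, p$theta_plan)
  expect_equal(model_spec("DFT2")$n_free, 4L)
  expect_equal(model_spec("DFT2_switch")$n_free, 5L)

  sw <- model_spec("DFT2_switch")
  par4 <- dft_params(5, 25, switch_point = 4L)
  expect_false(any(vapply(1:4, function(b)
    dynchoice:::dft_plans_dn2(sw, b, par4), TRUE)))
  par2 <- dft_params(5, 25, switch_point = 2L)
  expect_equal(vapply(1:4, function(b)
    dynchoice:::dft_plans_dn2(sw, b, par2), TRUE),
    c(FALSE, FALSE, TRUE, TRUE))
})

test_that("predict_trial returns clipped complementary probabilities", {
  trees <- build_template_set()
  par <- dft_params(50, delta = 0)
  trial <- data.frame(condition = "full", template_id = 1L, block = 1L,
                      dn2_node = "DN2a", stringsAsFactors = FALSE)
  pr <- predict_trial(trial, trees, model_spec("DFT2"), par, n_sims = 300,
                      seed = 3)
  expect_equal(sum(pr$dn1), 1)
  expect_equal(sum(pr$dn2), 1)
  expect_true(all(pr$dn1 >= 1 / 600 & pr$dn1 <= 1 - 1 / 600))
  # planning at a large threshold heads for the backward-induction side
  expect_gt(pr$dn1[["left"]], .5)
  # DN2a: {100,100} strictly dominates {0,0}; the final choice is certain
  # up to the clip
  expect_equal(pr$dn2[["left"]], 1 - 1 / 600)

  single <- data.frame(condition = "single_stage", template_id = 1L,
                       block = 5L, dn2_node = NA, stringsAsFactors = FALSE)
  ps <- predict_trial(single, trees, model_spec("DFT2_no_plan"), par,
                      n_sims = 300, seed = 4)
  expect_null(ps$dn2)
})

test_that("decision traces record the accumulation path", {
  tr <- certain_vs_gamble_tree(10, 20, 0, .6)
  res <- simulate_decision_trace(tr, "DN1", "final", dft_params(10),
                                 seed = 9, path = path <- tempfile())
  expect_equal(res$trace$V, res$trace$nu_i - res$trace$nu_j)
  expect_equal(res$trace$P, cumsum(res$trace$V))
  last <- nrow(res$trace)
  expect_gte(abs(res$trace$P[last]), 10)
  expect_equal(res$choice,
               if (res$trace$P[last] > 0) "ONA" else "CNB")
  disk <- read.csv(path)
  expect_equal(disk$P, res$trace$P)
})
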