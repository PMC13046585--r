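test_that("designs satisfy all count and adjacency constraints", {
  # property over many seeds
  for (seed in 1:60) {
    des <- generate_design(seed, n_participants = 4L)
    for (d in des) expect_true(design_satisfies_constraints(d))
  }
  # 40 trials, 8 per block, Latin-square cycling of block orders
  des <- generate_design(7, n_participants = 10L)
  expect_equal(vapply(des, `[[`, 0L, "block_order_id"),
               rep(1:4, length.out = 10L))
  all_trials <- unlist(lapply(des[[1]]$blocks, function(b) b$trials$trial))
  expect_equal(sort(all_trials), 1:40)
  expect_error(generate_design(1, n_participants = 3L))
})

test_that("simulated participants are deterministic and well-formed", {
  trees <- build_template_set()
  des <- generate_design(3, 4L)
  g <- te_generator(.5, .9, .7, .1, .1)
  t1 <- simulate_participant(des[[1]], trees, g, seed = 11)
  t2 <- simulate_participant(des[[1]], trees, g, seed = 11)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40L)
  # final outcome is always a reachable outcome value of the trial's tree
  for (i in seq_len(nrow(t1))) {
    tr <- trees[[t1$condition[i]]][[t1$template_id[i]]]
    expect_true(t1$final_outcome[i] %in% dynchoice:::outcome_values(tr))
  }
})

test_that("errorless backward-induction generators choose the BI side", {
  trees <- build_template_set()
  des <- generate_design(5, 4L)
  g <- te_generator(B = 1, s_b = 1, s_f = 1, e12 = 0, e34 = 0, dn2_error = 0)
  tt <- simulate_participant(des[[2]], trees, g, seed = 2)
  two <- tt[tt$condition != "single_stage", ]
  expect_true(all(two$dn1_choice == "left"))
  mr <- maximization_rates(tt, trees)
  expect_true(all(mr$rate == 1))
})

test_that("pattern extraction codes chronology against the BI side", {
  trees <- build_template_set()
  des <- generate_design(9, 4L)
  g <- te_generator(B = 1, s_b = 1, s_f = 1, e12 = 0, e34 = 0)
  trials <- do.call(rbind, lapply(1:4, function(p)
    simulate_participant(des[[p]], trees, g, seed = p)))
  cnt <- extract_patterns(trials, "full", trees)
  expect_equal(sum(cnt), 16L)                      # 4 participants x 4 templates
  expect_equal(unname(cnt[["1111"]]), 16L)         # errorless: all-ones pattern

  # hand-coded check: choices BI, FI, BI, BI for one template -> 1011
  sub <- trials[trials$participant == 1 & trials$condition == "full", ]
  sub <- sub[order(sub$trial), ]
  second <- which(sub$template_id == 2)[2]
  trials$dn1_choice[trials$participant == 1 & trials$condition == "full" &
                    trials$trial == sub$trial[second]] <- "right"
  cnt2 <- extract_patterns(trials, "full", trees)
  expect_equal(unname(cnt2[["1011"]]), 1L)
  expect_equal(unname(cnt2[["1111"]]), 15L)
})

test_that("cohort simulation is reproducible and sized by the design", {
  g <- te_generator(.3, .8, .6, .2, .15)
  co <- simulate_cohort(21, n_participants = 5L, generators = g)
  expect_equal(nrow(co$trials), 200L)
  cnt <- extract_patterns(co, "full")
  expect_equal(sum(cnt), 20L)                      # 5 participants x 4 templates
  co2 <- simulate_cohort(21, n_participants = 5L, generators = g)
  expect_identical(co$trials, co2$trials)

  path <- tempfile(fileext = ".csv")
  write_trials_csv(co, path)
  back <- read_trials_csv(path)
  expect_equal(nrow(back), nrow(co$trials))
  expect_equal(back$final_outcome, co$trials$final_outcome)
})

test_that("TE cohorts reproduce the TE pattern distribution", {
  # moderately sized convergence check (the full-scale one runs in the
  # acceptance suite via the same machinery)
  p <- te_params(.3, .81, .64, .22, .15)
  co <- simulate_cohort(31, n_participants = 200L,
                        generators = te_generator(.3, .81, .64, .22, .15))
  cnt <- extract_patterns(co, "full")
  emp <- cnt / sum(cnt)
  tv <- 0.5 * sum(abs(emp - te_pattern_distribution(p)))
  expect_lt(tv, 0.10)
})

test_that("designs round-trip through JSON", {
  des <- generate_design(13, 4L)
  path <- tempfile(fileext = ".json")
  write_design_json(des, path)
  back <- read_design_json(path)
  expect_equal(length(back), 4L)
  for (p in 1:4) {
    expect_equal(back[[p]]$participant, des[[p]]$participant)
    expect_equal(back[[p]]$block_order_id, des[[p]]$block_order_id)
    for (b in 1:5) {
      expect_equal(back[[p]]$blocks[[b]]$condition,
                   des[[p]]$blocks[[b]]$condition)
      expect_equal(back[[p]]$blocks[[b]]$trials$template_id,
                   des[[p]]$blocks[[b]]$trials$template_id)
      expect_equal(back[[p]]$blocks[[b]]$trials$scramble_seed,
                   des[[p]]$blocks[[b]]$trials$scramble_seed)
    }
  }
})
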