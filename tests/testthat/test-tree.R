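test_that("backward induction solves the fixture and degenerate trees", {
  tr <- tfix_tree()
  pol <- backward_induction(tr)
  expect_equal(pol$value_at[["DN1"]], 100)
  expect_equal(pol$choice_at[["DN1"]], "CN1")
  expect_equal(pol$value_at[["CN2"]], 50.5)
  expect_equal(pol$value_at[["DN2c"]], 50.5)
  # left branch canonical under the dominance-reversal design
  expect_equal(canonical_side(tr, "DN1", pol$choice_at[["DN1"]]), "left")

  # degenerate: every path leads to the same value
  flat <- full_tree(replicate(4, list(c(7, 7), c(7, 7)), simplify = FALSE))
  expect_equal(backward_induction(flat)$value_at[["DN1"]], 7)
})

test_that("backward induction equals brute-force policy maximization", {
  for (tree in list(tfix_tree(), generate_template(5), generate_template(9),
                    derive_half_tree(tfix_tree()))) {
    pol <- backward_induction(tree)
    evs <- vapply(enumerate_policies(tree), function(ch)
      policy_value(tree, ch), 0)
    expect_equal(pol$value_at[[tree$root]], max(evs), tolerance = 1e-12)
    expect_true(all(pol$value_at[[tree$root]] >= evs - 1e-12))
  }
})

test_that("forward evaluation yields the 1/8 union lotteries", {
  tr <- tfix_tree()
  fw <- forward_evaluation(tr)
  # 8 equiprobable outcomes per side (after merging duplicates the
  # probabilities are multiples of 1/8)
  expect_equal(sum(fw$left$probs), 1)
  expect_true(all(abs(fw$left$probs * 8 - round(fw$left$probs * 8)) < 1e-12))
  expect_equal(unname(fw$ev), c(50, 50.25))
  expect_equal(fw$preferred, "right")

  # identical branches: tie
  flat <- full_tree(replicate(4, list(c(10, 2), c(8, 4)), simplify = FALSE))
  expect_equal(forward_evaluation(flat)$preferred, "none")
})

test_that("fosd obeys its defining properties", {
  a <- lottery(c(101, 0), c(.5, .5))
  b <- lottery(c(100, 0), c(.5, .5))
  expect_true(fosd(a, b))
  expect_false(fosd(b, a))                 # asymmetry
  expect_false(fosd(a, a))                 # irreflexive
  expect_false(fosd(lottery(c(10, 0)), lottery(c(20, 0))))
  # dominance implies at least as high EV, over random lottery pairs
  set.seed(41)
  for (i in 1:50) {
    x <- lottery(sample(0:30, 3), c(.2, .3, .5))
    y <- lottery(sample(0:30, 3), c(.4, .4, .2))
    if (fosd(x, y)) expect_gte(lottery_ev(x), lottery_ev(y))
    if (fosd(y, x)) expect_gte(lottery_ev(y), lottery_ev(x))
  }
})

test_that("validate_design passes the fixture and flags violations", {
  expect_true(validate_design(tfix_tree())$ok)

  # raise the dominated CN at DN2a above the dominant one
  bad <- full_tree(list(
    list(c(100, 100), c(150, 150)),
    list(c(100, 100), c(0, 0)),
    list(c(101, 0), c(100, 0)),
    list(c(101, 0), c(100, 0))))
  rep <- validate_design(bad)
  expect_false(rep$ok)

  # identical left/right branches: no reversal
  sym <- full_tree(list(
    list(c(100, 100), c(0, 0)),
    list(c(101, 0), c(100, 0)),
    list(c(100, 100), c(0, 0)),
    list(c(101, 0), c(100, 0))))
  expect_false(validate_design(sym)$checks[["reversal"]])
})

test_that("malformed trees are rejected", {
  tr <- tfix_tree()
  tr$nodes[["CN3"]]$children <- c("ON1", "DN1")  # cycle back to the root
  expect_error(dynchoice:::check_tree(tr), "twice|cycle")
  tr2 <- tfix_tree()
  tr2$nodes[["CN3"]]$children <- c("ON1", "nowhere")
  expect_error(dynchoice:::check_tree(tr2), "dangling")
  tr3 <- tfix_tree()
  tr3$nodes[["CN3"]]$probs <- c(.7, .7)
  expect_error(dynchoice:::check_tree(tr3), "probabilities")
})

test_that("scramble preserves structure, values, and design verdicts", {
  tr <- tfix_tree()
  # identity permutation: all flips FALSE leaves the tree unchanged
  id <- dynchoice:::apply_scramble(tr, setNames(
    rep(FALSE, length(tr$scramble_map)), names(tr$scramble_map)))
  expect_identical(id, tr)

  # a DN1 branch swap flips the physical side but not the canonical one
  sw <- dynchoice:::apply_scramble(tr, c(DN1 = TRUE))
  pol <- backward_induction(sw)
  expect_equal(pol$choice_at[["DN1"]], "CN1")
  expect_equal(canonical_side(sw, "DN1", "CN1"), "left")
  expect_equal(physical_side(sw, "DN1", "CN1"), "right")

  vals <- sort(dynchoice:::outcome_values(tr))
  for (seed in 1:200) {
    s <- scramble(tr, seed)
    expect_true(validate_design(s)$ok)
    expect_equal(sort(dynchoice:::outcome_values(s)), vals)
    expect_equal(backward_induction(s)$value_at[["DN1"]], 100)
  }
  # scrambles compose: map is an xor of flips
  s1 <- scramble(tr, 1); s12 <- scramble(s1, 2)
  expect_true(validate_design(s12)$ok)
})

test_that("trees round-trip through JSON bit-stably", {
  for (tree in list(tfix_tree(), scramble(generate_template(3), 11),
                    derive_half_tree(tfix_tree()),
                    derive_single_stage(tfix_tree()))) {
    path <- withr::local_tempfile(fileext = ".json")
    tree_to_json(tree, path)
    back <- tree_from_json(path)
    expect_equal(back, tree)
    # a second write is byte-identical
    path2 <- withr::local_tempfile(fileext = ".json")
    tree_to_json(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})
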