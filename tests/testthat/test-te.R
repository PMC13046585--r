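test_that("pattern probabilities match the latent-state enumeration oracle", {
  p <- te_params(.30, .81, .64, .22, .15)
  # frozen value computed with te_prob_oracle (enumeration over latent
  # truth x persistence states)
  expect_equal(te_pattern_probability(c(1, 0, 1, 1), p), 0.0633204,
               tolerance = 1e-6)
  set.seed(7)
  for (i in 1:25) {
    q <- te_params(runif(1), runif(1), runif(1), runif(1, 0, .5),
                   runif(1, 0, .5))
    bits <- sample(0:1, 4, replace = TRUE)
    expect_equal(te_pattern_probability(bits, q), te_prob_oracle(bits, q),
                 tolerance = 1e-12)
    d <- te_pattern_distribution(q)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(unname(d[dynchoice:::pattern_index(bits)]),
                 te_pattern_probability(bits, q))
  }
})

test_that("errorless and basic special cases reduce correctly", {
  # errorless backward-induction population: all mass on 1111
  p1 <- te_params(1, 1, 1, 0, 0)
  d <- te_pattern_distribution(p1)
  expect_equal(unname(d[["1111"]]), 1)
  expect_equal(sum(d[setdiff(names(d), "1111")]), 0)

  # extended model with s_b = s_f = 1, e12 = e34 equals the basic TE form
  set.seed(11)
  for (i in 1:10) {
    B <- runif(1); e <- runif(1, 0, .5)
    q <- te_params(B, 1, 1, e, e)
    for (k in 1:16) {
      bits <- dynchoice:::pattern_bits(k)
      expect_equal(te_pattern_probability(bits, q),
                   te_basic_oracle(bits, B, e), tolerance = 1e-12)
    }
  }
})

test_that("likelihood is invariant under profile relabeling", {
  # swapping B <-> 1-B with s_b <-> s_f and complementing all bits is a
  # symmetry of the model
  set.seed(3)
  for (i in 1:20) {
    p <- te_params(runif(1), runif(1), runif(1), runif(1, 0, .5),
                   runif(1, 0, .5))
    q <- te_params(1 - p$B, p$s_f, p$s_b, p$e12, p$e34)
    bits <- sample(0:1, 4, replace = TRUE)
    expect_equal(te_pattern_probability(bits, p),
                 te_pattern_probability(1L - bits, q), tolerance = 1e-12)
  }
})

test_that("second-half prevalence reproduces the reported arithmetic", {
  expect_equal(second_half_prevalence(te_params(.30, .81, .64)), 0.495)
  expect_equal(second_half_prevalence(te_params(.61, 1.00, .78)), 0.6958)
  expect_equal(second_half_prevalence(te_params(1, 1, .3)), 1)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(te_params(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(te_params(.5, 1, 1, e12 = .6), "0.5")
  expect_error(te_pattern_probability(c(1, 0, 1, 1), list(B = .5)))
})

test_that("MLE recovers parameters from noise-free expected counts", {
  p <- te_params(.35, .75, .6, .2, .12)
  counts <- 1e4 * te_pattern_distribution(p)   # expected, not sampled
  fit <- fit_te(counts, n_starts = 10, seed = 4)
  for (nm in c("B", "s_b", "s_f", "e12", "e34"))
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-4)
  expect_lt(fit$G2, 1e-6)
  expect_equal(fit$df, 10L)
})

test_that("restricted fits have the right df and warn on degeneracy", {
  cnt <- simulate_patterns(200, te_params(.3, .8, .6, .2, .15), seed = 5)
  f0 <- fit_te(cnt, n_starts = 6)
  expect_equal(f0$df, 10L)
  fB <- fit_te(cnt, restrictions = "B=1", n_starts = 6)
  expect_equal(fB$df, 11L)
  fb <- fit_te(cnt, restrictions = c("s_b=1", "s_f=1", "e12=e34"),
               n_starts = 6)
  expect_equal(fb$df, 13L)
  expect_error(fit_te(cnt, restrictions = "phi=1"), "unknown restriction")

  degenerate <- setNames(c(rep(0L, 15), 50L), names(cnt))
  expect_warning(fit_te(degenerate, n_starts = 3), "degenerate")
})

test_that("lr_test orders, refuses non-nested fits, and detects misfit", {
  cnt <- simulate_patterns(200, te_params(.3, .81, .64, .22, .15), seed = 9)
  full <- fit_te(cnt, n_starts = 8)
  restr <- fit_te(cnt, restrictions = "B=1", n_starts = 8)
  lt <- lr_test(full, restr)
  expect_gte(lt$delta_G2, 0)
  expect_equal(lt$delta_df, 1L)
  # B = .3 truth against B = 1 restriction: decisive rejection expected
  expect_lt(lt$p_value, 0.001)

  same <- lr_test(full, full0 <- fit_te(cnt, n_starts = 8))
  expect_equal(same$delta_G2, 0, tolerance = 1e-4)

  expect_error(lr_test(restr, full), "nested")
  other <- fit_te(simulate_patterns(100, te_params(.5, 1, 1, .1), 2),
                  n_starts = 4)
  expect_error(lr_test(full, other), "same data")
})

test_that("shared-preference fits nest inside separate fits", {
  pf <- te_params(.30, .81, .64, .22, .15)
  ph <- te_params(.61, 1, .78, .30, .20)
  cf <- simulate_patterns(200, pf, seed = 13)
  ch <- simulate_patterns(200, ph, seed = 14)
  sep <- pool_te_fits(fit_te(cf, n_starts = 8), fit_te(ch, n_starts = 8))
  shared <- fit_te_shared(list(full = cf, half = ch), n_starts = 8)
  expect_equal(shared$df, 23L)          # 30 cells' df - (3 + 2x2) free
  expect_equal(sep$df, 20L)
  lt <- lr_test(sep, shared)
  expect_equal(lt$delta_df, 3L)
  expect_gte(lt$delta_G2, 0)
  # generating preferences differ strongly across conditions
  expect_lt(lt$p_value, 0.05)
})

test_that("pattern counts round-trip through CSV", {
  cnt <- simulate_patterns(120, te_params(.4, .9, .7, .15, .1), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_pattern_counts(cnt, path)
  expect_equal(read_pattern_counts(path), setNames(as.integer(cnt),
                                                   names(cnt)))
})

test_that("parametric-bootstrap p agrees broadly with the chi-square p", {
  cnt <- simulate_patterns(200, te_params(.35, .8, .65, .2, .15), seed = 21)
  fit <- fit_te(cnt, n_starts = 6)
  boot <- te_bootstrap_p(fit, R = 40, seed = 3)
  expect_length(boot$G2_boot, 40)
  expect_true(boot$p_boot >= 0 && boot$p_boot <= 1)
  # a well-fitting model should not be rejected by the bootstrap either
  expect_gt(boot$p_boot, 0.01)
})
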