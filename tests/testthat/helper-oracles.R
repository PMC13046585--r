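# Independent oracles used across test files.  These deliberately avoid the
# package's own computational paths.

# All complete policies of a tree (assignment of one child per DN).
enumerate_policies <- function(tree) {
  roles <- vapply(tree$nodes, `[[`, "", "role")
  dns <- names(tree$nodes)[roles == "DN"]
  kid_lists <- lapply(dns, function(d) tree$nodes[[d]]$children)
  grid <- expand.grid(kid_lists, stringsAsFactors = FALSE)
  names(grid) <- dns
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

# TE pattern probability by explicit enumeration over the latent states
# (2 first-half truths x keep/switch), written independently of the
# vectorized closed form in the package.
te_prob_oracle <- function(bits, p) {
  tot <- 0
  for (truth1 in c(1L, 0L)) for (keep in c(TRUE, FALSE)) {
    w <- if (truth1 == 1L) p$B * (if (keep) p$s_b else 1 - p$s_b)
         else (1 - p$B) * (if (keep) p$s_f else 1 - p$s_f)
    truth2 <- if (keep) truth1 else 1L - truth1
    lik <- prod(ifelse(bits[1:2] == truth1, 1 - p$e12, p$e12)) *
           prod(ifelse(bits[3:4] == truth2, 1 - p$e34, p$e34))
    tot <- tot + w * lik
  }
  tot
}

# Basic (no-switch, single-error) TE closed form, direct.
te_basic_oracle <- function(bits, B, e) {
  B * prod(ifelse(bits == 1, 1 - e, e)) +
    (1 - B) * prod(ifelse(bits == 0, 1 - e, e))
}

# Build a free-standing binary choice problem: a DN offering a certain
# payoff vs a two-outcome gamble (for accumulator oracle checks).
certain_vs_gamble_tree <- function(certain, win, lose, p_win) {
  decision_tree("single_stage", list(
    dynchoice:::tree_node("DN1", "DN", children = c("ONA", "CNB")),
    dynchoice:::tree_node("ONA", "ON", value = certain),
    dynchoice:::tree_node("CNB", "CN", children = c("ONB1", "ONB2"),
                          probs = c(p_win, 1 - p_win)),
    dynchoice:::tree_node("ONB1", "ON", value = win),
    dynchoice:::tree_node("ONB2", "ON", value = lose)))
}

# A symmetric tree: two identical gambles.
symmetric_tree <- function(win = 20, lose = 0) {
  decision_tree("single_stage", list(
    dynchoice:::tree_node("DN1", "DN", children = c("CNA", "CNB")),
    dynchoice:::tree_node("CNA", "CN", children = c("ONA1", "ONA2"),
                          probs = c(.5, .5)),
    dynchoice:::tree_node("ONA1", "ON", value = win),
    dynchoice:::tree_node("ONA2", "ON", value = lose),
    dynchoice:::tree_node("CNB", "CN", children = c("ONB1", "ONB2"),
                          probs = c(.5, .5)),
    dynchoice:::tree_node("ONB1", "ON", value = win),
    dynchoice:::tree_node("ONB2", "ON", value = lose)))
}

ss <- dynchoice:::substream_seed

# One synthetic participant with n_designs * 40 trials (design replicates).
participant_trials <- function(trees, generator, seed, n_designs = 5L) {
  do.call(rbind, lapply(seq_len(n_designs), function(k) {
    des <- generate_design(ss(seed, "design", k), 4L)
    tr <- simulate_participant(des[[1]], trees, generator,
                               ss(seed, "ppt", k))
    tr$trial <- tr$trial + (k - 1L) * 40L
    tr
  }))
}

# Structural check of one participant's experimental design.
design_satisfies_constraints <- function(des) {
  conds <- vapply(des$blocks, `[[`, "", "condition")
  ok <- length(des$blocks) == 5L && conds[5] == "single_stage"
  ok <- ok && all(conds[1:4] %in% c("full", "half")) &&
    all(conds[1:3] != conds[2:4])                 # alternation
  for (b in des$blocks) {
    tpl <- b$trials$template_id
    ok <- ok && nrow(b$trials) == 8L &&
      all(sort(tpl) == rep(1:4, each = 2)) &&     # each template twice
      !any(tpl[-1] == tpl[-8])                    # no back-to-back repeats
  }
  ok
}
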