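#' @useDynLib dynchoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq rbinom runif setNames quantile sd
#' @importFrom utils write.csv read.csv
"_PACKAGE"

## ---------------------------------------------------------------------------
## Decision trees
##
## A tree is a named list of nodes reachable from a root decision node.
## Node roles: "DN" (decision), "CN" (chance), "ON" (outcome/leaf).
## Children are stored in *physical* (on-screen) order; `scramble_map`
## records, per internal node, whether that order is reversed relative to
## the canonical orientation (canonical: the backward-induction-optimal
## first-stage branch is listed first, i.e. "left").
## ---------------------------------------------------------------------------

tree_node <- function(id, role, children = character(), probs = numeric(),
                      value = NA_real_) {
  stopifnot(role %in% c("DN", "CN", "ON"))
  list(id = id, role = role, children = children, probs = probs, value = value)
}

#' Construct a decision tree
#'
#' Low-level constructor used by the template generators.  Most users will
#' call [generate_template()], [derive_half_tree()] or
#' [derive_single_stage()] instead.
#'
#' @param kind one of `"full"`, `"half"`, `"single_stage"`.
#' @param nodes named list of nodes as built by the internal `tree_node()`;
#'   each node has `id`, `role` (`"DN"`, `"CN"`, `"ON"`), `children`
#'   (ordered ids; chance nodes also carry `probs`), and `value`
#'   (outcome nodes only).
#' @param root id of the first-stage decision node.
#' @param template_id integer template identity (1--4).
#' @param scramble_map named logical vector over internal node ids; `TRUE`
#'   means the node's physical child order is reversed relative to canonical.
#' @return an object of class `decision_tree`.
#' @export
decision_tree <- function(kind, nodes, root = "DN1", template_id = 1L,
                          scramble_map = NULL) {
  kind <- match.arg(kind, c("full", "half", "single_stage"))
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  if (is.null(scramble_map)) {
    internal <- names(nodes)[vapply(nodes, function(n) n$role != "ON", TRUE)]
    scramble_map <- setNames(rep(FALSE, length(internal)), internal)
  }
  tr <- structure(
    list(kind = kind, root = root, nodes = nodes,
         template_id = as.integer(template_id), scramble_map = scramble_map),
    class = "decision_tree")
  check_tree(tr)
  tr
}

## Well-formedness: every child exists, the graph reachable from the root is
## a tree (each node one parent, no cycles), CN probabilities sum to 1,
## ON values finite, scramble_map covers the internal nodes bijectively.
check_tree <- function(tree) {
  nodes <- tree$nodes
  if (!tree$root %in% names(nodes))
    stop("malformed tree: root '", tree$root, "' not among nodes")
  seen <- character()
  visit <- function(id) {
    if (id %in% seen) stop("malformed tree: node '", id,
                           "' reached twice (cycle or shared child)")
    seen <<- c(seen, id)
    nd <- nodes[[id]]
    if (is.null(nd)) stop("malformed tree: dangling child '", id, "'")
    if (nd$role == "ON") {
      if (length(nd$children)) stop("malformed tree: ON with children")
      if (!is.finite(nd$value)) stop("malformed tree: non-finite ON value")
    } else {
      if (length(nd$children) < 1L) stop("malformed tree: childless ", nd$role)
      if (nd$role == "CN") {
        if (length(nd$probs) != length(nd$children) ||
            any(nd$probs < 0) || abs(sum(nd$probs) - 1) > 1e-9)
          stop("malformed tree: CN '", id, "' probabilities invalid")
      }
      for (ch in nd$children) visit(ch)
    }
    invisible(NULL)
  }
  visit(tree$root)
  if (length(seen) != length(nodes))
    stop("malformed tree: ", length(nodes) - length(seen),
         " node(s) unreachable from root")
  internal <- names(nodes)[vapply(nodes, function(n) n$role != "ON", TRUE)]
  if (!setequal(names(tree$scramble_map), internal))
    stop("malformed tree: scramble_map does not cover internal nodes")
  invisible(tree)
}

#' @export
print.decision_tree <- function(x, ...) {
  roles <- vapply(x$nodes, `[[`, "", "role")
  cat(sprintf("<decision_tree> kind=%s template=%d  %d DN, %d CN, %d ON\n",
              x$kind, x$template_id, sum(roles == "DN"), sum(roles == "CN"),
              sum(roles == "ON")))
  vals <- outcome_values(x)
  cat(sprintf("  outcomes in [%g, %g]; scrambled: %s\n", min(vals), max(vals),
              if (any(x$scramble_map)) "yes" else "no"))
  invisible(x)
}

## Children of a node in canonical (unscrambled) order.
canonical_children <- function(tree, id) {
  nd <- tree$nodes[[id]]
  if (isTRUE(tree$scramble_map[[id]])) rev(nd$children) else nd$children
}

canonical_probs <- function(tree, id) {
  nd <- tree$nodes[[id]]
  if (isTRUE(tree$scramble_map[[id]])) rev(nd$probs) else nd$probs
}

#' Canonical and physical side of a child
#'
#' The canonical side is invariant under scrambling; the physical side is
#' the on-screen position.
#'
#' @param tree a `decision_tree`.
#' @param dn id of a binary decision node.
#' @param child id of one of its children.
#' @return `"left"` or `"right"`.
#' @export
canonical_side <- function(tree, dn, child) {
  ch <- canonical_children(tree, dn)
  i <- match(child, ch)
  if (is.na(i)) stop("'", child, "' is not a child of '", dn, "'")
  c("left", "right")[i]
}

#' @rdname canonical_side
#' @export
physical_side <- function(tree, dn, child) {
  i <- match(child, tree$nodes[[dn]]$children)
  if (is.na(i)) stop("'", child, "' is not a child of '", dn, "'")
  c("left", "right")[i]
}

outcome_values <- function(tree) {
  unlist(lapply(tree$nodes, function(n) if (n$role == "ON") n$value else NULL))
}

dn2_ids <- function(tree) {
  ids <- names(tree$nodes)
  ids[vapply(tree$nodes, function(n) n$role == "DN", TRUE) & ids != tree$root]
}

## ---------------------------------------------------------------------------
## Solvers
## ---------------------------------------------------------------------------

#' Solve a tree by backward induction
#'
#' Works from the outcome nodes upward: a chance node is worth the
#' probability-weighted value of its children, a decision node is worth its
#' best child (ties break toward the canonically first-listed child).
#'
#' @param tree a `decision_tree`.
#' @param utility optional utility function applied to outcome values;
#'   defaults to identity (values are in points and the benchmark is
#'   expected value).
#' @return an object of class `tree_policy`: list with `choice_at` (named
#'   character, chosen child per DN) and `value_at` (named numeric over all
#'   nodes).
#' @export
backward_induction <- function(tree, utility = identity) {
  choice <- character(); value <- numeric()
  solve <- function(id) {
    nd <- tree$nodes[[id]]
    v <- switch(nd$role,
      ON = utility(nd$value),
      CN = sum(nd$probs * vapply(nd$children, solve, 0)),
      DN = {
        ch <- canonical_children(tree, id)
        cv <- vapply(ch, solve, 0)
        best <- which.max(cv)           # which.max -> first maximum, so ties
        choice[id] <<- ch[best]         # break toward the canonical first child
        cv[best]
      })
    value[id] <<- v
    v
  }
  solve(tree$root)
  structure(list(choice_at = choice, value_at = value), class = "tree_policy")
}

#' Expected value of a fixed policy
#'
#' Evaluates the tree with every decision node forced to the given child.
#' Used as the brute-force oracle against [backward_induction()].
#'
#' @param tree a `decision_tree`.
#' @param choice_at named character vector mapping each DN id to a child id.
#' @return expected value at the root.
#' @export
policy_value <- function(tree, choice_at) {
  ev <- function(id) {
    nd <- tree$nodes[[id]]
    switch(nd$role,
      ON = nd$value,
      CN = sum(nd$probs * vapply(nd$children, ev, 0)),
      DN = ev(choice_at[[id]]))
  }
  ev(tree$root)
}

#' Lotteries over outcomes
#'
#' A lottery is a discrete distribution over outcome values.  Duplicate
#' values are merged and the support is sorted.
#'
#' @param values numeric outcome values.
#' @param probs matching probabilities (must sum to 1).
#' @return object of class `lottery` with fields `values`, `probs`.
#' @export
lottery <- function(values, probs = rep(1 / length(values), length(values))) {
  stopifnot(length(values) == length(probs), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9) stop("lottery probabilities must sum to 1")
  p <- tapply(probs, factor(values, levels = sort(unique(values))), sum)
  structure(list(values = as.numeric(names(p)), probs = as.numeric(p)),
            class = "lottery")
}

#' @rdname lottery
#' @param x a `lottery`.
#' @export
lottery_ev <- function(x) sum(x$values * x$probs)

#' @export
print.lottery <- function(x, ...) {
  cat("<lottery> ", paste0(format(x$values), " (", format(x$probs), ")",
                           collapse = ", "),
      "  EV=", format(lottery_ev(x)), "\n", sep = "")
  invisible(x)
}

## Distribution of terminal outcomes below `id`, optionally treating every
## decision node as an equiprobable chance split (the "forward" view).
node_lottery <- function(tree, id, dn_as_chance = TRUE) {
  walk <- function(id, p) {
    nd <- tree$nodes[[id]]
    switch(nd$role,
      ON = list(v = nd$value, p = p),
      CN = do.call(function(...) list(
             v = unlist(lapply(list(...), `[[`, "v")),
             p = unlist(lapply(list(...), `[[`, "p"))),
             Map(walk, nd$children, p * nd$probs)),
      DN = {
        if (!dn_as_chance)
          stop("node_lottery below a DN requires dn_as_chance = TRUE")
        k <- length(nd$children)
        do.call(function(...) list(
          v = unlist(lapply(list(...), `[[`, "v")),
          p = unlist(lapply(list(...), `[[`, "p"))),
          Map(walk, nd$children, rep(p / k, k)))
      })
  }
  res <- walk(id, 1)
  lottery(res$v, res$p)
}

#' Forward (non-planning) evaluation of the first-stage choice
#'
#' Treats every future decision node as an equiprobable chance event, so
#' each first-stage branch becomes a multiple-outcome lottery (for a full
#' tree: its eight outcome nodes, each with probability 1/8).  Sides refer
#' to the canonical orientation.
#'
#' @param tree a `decision_tree`.
#' @return list with `left`, `right` (lotteries), `ev` (named numeric) and
#'   `preferred` (`"left"`, `"right"` or `"none"` on an EV tie).
#' @export
forward_evaluation <- function(tree) {
  ch <- canonical_children(tree, tree$root)
  if (length(ch) != 2L) stop("first-stage DN must be binary")
  left <- node_lottery(tree, ch[1], dn_as_chance = TRUE)
  right <- node_lottery(tree, ch[2], dn_as_chance = TRUE)
  ev <- c(left = lottery_ev(left), right = lottery_ev(right))
  preferred <- if (abs(ev[1] - ev[2]) < 1e-12) "none" else
    c("left", "right")[which.max(ev)]
  list(left = left, right = right, ev = ev, preferred = unname(preferred))
}

#' First-order stochastic dominance
#'
#' `fosd(a, b)` is `TRUE` iff a's CDF never exceeds b's and is strictly
#' smaller somewhere: any expected-utility maximizer with increasing utility
#' weakly prefers `a`, and strictly so for some such utility.
#'
#' @param a,b lotteries (or objects coercible via [lottery()]).
#' @return logical scalar.
#' @export
fosd <- function(a, b) {
  grid <- sort(unique(c(a$values, b$values)))
  cdf <- function(l) vapply(grid, function(x) sum(l$probs[l$values <= x]), 0)
  Fa <- cdf(a); Fb <- cdf(b)
  all(Fa <= Fb + 1e-12) && any(Fa < Fb - 1e-12)
}

## ---------------------------------------------------------------------------
## Design validation
## ---------------------------------------------------------------------------

#' Check the dominance-reversal design of a full tree
#'
#' Verifies the three structural properties the experimental templates rely
#' on: (i) at each second-stage decision node one chance node
#' stochastically dominates its sibling; (ii) one whole first-stage branch,
#' viewed as an 8-outcome lottery, stochastically dominates the other; and
#' (iii) the backward-induction first-stage choice is the *opposite* side
#' from that forward-dominant branch, so planners and non-planners are
#' predicted to move in different directions.
#'
#' @param tree a full `decision_tree`.
#' @return object of class `design_report`: list with `ok` and a named
#'   logical `checks` (`dn2_dominance`, `forward_dominance`, `reversal`)
#'   plus `detail`.
#' @export
validate_design <- function(tree) {
  if (tree$kind != "full") stop("validate_design expects a full tree")
  checks <- c(dn2_dominance = TRUE, forward_dominance = TRUE, reversal = TRUE)
  detail <- list()

  for (dn in dn2_ids(tree)) {
    ch <- canonical_children(tree, dn)
    la <- node_lottery(tree, ch[1]); lb <- node_lottery(tree, ch[2])
    dom <- c(fosd(la, lb), fosd(lb, la))
    if (sum(dom) != 1L) checks["dn2_dominance"] <- FALSE
    detail[[dn]] <- if (dom[1]) ch[1] else if (dom[2]) ch[2] else NA_character_
  }

  fw <- forward_evaluation(tree)
  fw_dom <- c(left = fosd(fw$left, fw$right), right = fosd(fw$right, fw$left))
  if (sum(fw_dom) != 1L) checks["forward_dominance"] <- FALSE
  fw_side <- if (fw_dom["left"]) "left" else if (fw_dom["right"]) "right"
             else NA_character_
  detail$forward_winner <- fw_side

  pol <- backward_induction(tree)
  bi_side <- canonical_side(tree, tree$root, pol$choice_at[[tree$root]])
  detail$bi_side <- bi_side
  if (is.na(fw_side) || identical(bi_side, fw_side))
    checks["reversal"] <- FALSE

  structure(list(ok = all(checks), checks = checks, detail = detail),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>", if (x$ok) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-18s %s\n", nm, if (x$checks[nm]) "ok" else "VIOLATED"))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Scrambling
## ---------------------------------------------------------------------------

#' Scramble a tree's on-screen layout
#'
#' Randomly composes structure-preserving swaps: the whole first-stage
#' branch swap, within-branch second-stage subtree swaps, within-DN2 sibling
#' swaps, and within-CN outcome swaps.  Each swap reverses one internal
#' node's physical child order; `scramble_map` accumulates the isomorphism
#' (an xor with any existing map), so canonical-side coding and all design
#' verdicts are unchanged.
#'
#' @param tree a `decision_tree`.
#' @param seed integer seed; the identity permutation is produced when every
#'   sampled flip is `FALSE`.
#' @return the scrambled `decision_tree`.
#' @export
scramble <- function(tree, seed) {
  flips <- with_seed(seed, setNames(
    sample(c(TRUE, FALSE), length(tree$scramble_map), replace = TRUE),
    names(tree$scramble_map)))
  apply_scramble(tree, flips)
}

## Apply an explicit flip set (used by scramble() and by tests).
apply_scramble <- function(tree, flips) {
  stopifnot(all(names(flips) %in% names(tree$scramble_map)))
  for (id in names(flips)[flips]) {
    nd <- tree$nodes[[id]]
    tree$nodes[[id]]$children <- rev(nd$children)
    if (nd$role == "CN") tree$nodes[[id]]$probs <- rev(nd$probs)
    tree$scramble_map[[id]] <- xor(tree$scramble_map[[id]], TRUE)
  }
  tree
}

## ---------------------------------------------------------------------------
## JSON serialization
## ---------------------------------------------------------------------------

#' Read and write trees as JSON
#'
#' The schema is a flat node list: `{kind, root, template_id, nodes:
#' [{id, role, children, probs, value}], scramble_map: {id: bool}}`.
#' Round-tripping is exact (values are written at full precision).
#'
#' @param tree a `decision_tree`.
#' @param path file path; for `tree_to_json`, `NULL` returns the JSON string.
#' @return `tree_from_json` returns a `decision_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(
    kind = tree$kind, root = tree$root, template_id = tree$template_id,
    nodes = lapply(unname(tree$nodes), function(n)
      list(id = n$id, role = n$role, children = as.list(n$children),
           probs = as.list(n$probs),
           value = if (is.na(n$value)) NULL else n$value)),
    scramble_map = as.list(tree$scramble_map))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(n)
    tree_node(n$id, n$role, children = unlist(n$children) %||% character(),
              probs = unlist(n$probs) %||% numeric(),
              value = if (is.null(n$value)) NA_real_ else n$value))
  decision_tree(obj$kind, nodes, root = obj$root,
                template_id = obj$template_id,
                scramble_map = unlist(obj$scramble_map))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

## Deterministic substream seeds: fold integers into [0, 2^31 - 2].
## Splits one user seed into independent per-participant / per-trial /
## per-node streams so any unit is reproducible in isolation.
substream_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = ""))
    else as.integer(x)
  })))
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}
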