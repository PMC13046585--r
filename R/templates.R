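## ---------------------------------------------------------------------------
## Template construction
##
## Canonical full-tree skeleton:
##   DN1 -> CN1 (left), CN2 (right); CN1 -> DN2a, DN2b; CN2 -> DN2c, DN2d
##   DN2a -> CN3, CN4 ... DN2d -> CN9, CN10; CNk -> two ONs, each p = .5
## All two-outcome chance nodes are fair (equal red and blue balls).
## ---------------------------------------------------------------------------

#' Build a full tree from second-stage outcome values
#'
#' @param dn2_values list of four length-2 lists (one per DN2, canonical
#'   order a--d); each element is a numeric length-2 vector of outcome
#'   values for that DN2's two chance nodes, dominant-first in canonical
#'   orientation.
#' @param template_id integer 1--4.
#' @return a full `decision_tree` with 5 DNs, 10 CNs, 16 ONs.
#' @export
full_tree <- function(dn2_values, template_id = 1L) {
  stopifnot(length(dn2_values) == 4L)
  dn2 <- c("DN2a", "DN2b", "DN2c", "DN2d")
  nodes <- list(
    tree_node("DN1", "DN", children = c("CN1", "CN2")),
    tree_node("CN1", "CN", children = c("DN2a", "DN2b"), probs = c(.5, .5)),
    tree_node("CN2", "CN", children = c("DN2c", "DN2d"), probs = c(.5, .5)))
  on_i <- 0L
  for (d in seq_len(4L)) {
    cns <- paste0("CN", 2L + 2L * (d - 1L) + 1:2)
    nodes <- c(nodes, list(tree_node(dn2[d], "DN", children = cns)))
    for (c in 1:2) {
      vals <- dn2_values[[d]][[c]]
      stopifnot(length(vals) == 2L)
      ons <- paste0("ON", on_i + 1:2); on_i <- on_i + 2L
      nodes <- c(nodes, list(tree_node(cns[c], "CN", children = ons,
                                       probs = c(.5, .5))))
      nodes <- c(nodes, Map(function(id, v) tree_node(id, "ON", value = v),
                            ons, vals))
    }
  }
  decision_tree("full", nodes, template_id = template_id)
}

#' The validated fixture template
#'
#' A small, hand-checkable full tree: the left branch pairs flat high/low
#' gambles ({100,100} vs {0,0} at DN2a/b), the right branch pairs
#' {101,0} vs {100,0} at DN2c/d.  Backward induction values the left branch
#' at 100 and the right at 50.5, while the right 8-outcome union lottery
#' (EV 50.25) stochastically dominates the left one (EV 50).
#'
#' @param template_id integer 1--4; templates 2--4 add `template_id - 1` to
#'   every outcome value.
#' @return a full `decision_tree` passing [validate_design()].
#' @export
tfix_tree <- function(template_id = 1L) {
  tr <- full_tree(list(
    list(c(100, 100), c(0, 0)),
    list(c(100, 100), c(0, 0)),
    list(c(101, 0), c(100, 0)),
    list(c(101, 0), c(100, 0))), template_id = template_id)
  shift_template(tr, template_id - 1L)
}

#' Shift all outcome values by a constant
#'
#' Derived templates are perceptually distinct but structurally identical:
#' templates 2, 3, 4 add 1, 2, 3 to every outcome of template 1.  Adding a
#' constant preserves all dominance and reversal properties.
#'
#' @param tree a `decision_tree`.
#' @param offset numeric constant added to every ON value.
#' @return the shifted tree (same `template_id` unless updated by caller).
#' @export
shift_template <- function(tree, offset) {
  for (id in names(tree$nodes))
    if (tree$nodes[[id]]$role == "ON")
      tree$nodes[[id]]$value <- tree$nodes[[id]]$value + offset
  tree
}

#' Generate a design-valid full template
#'
#' Constructive scheme with randomized integer values: the left branch
#' carries flat dominant gambles {H_a,H_a}, {H_b,H_b} against flat low
#' gambles {L,L}; the right branch carries {H*+e, L} vs {H*, L} with
#' H* = max(H_a, H_b).  This guarantees (a) per-DN2 dominance, (b) the
#' right union lottery stochastically dominates the left union, and (c)
#' backward induction prefers left (EV (H_a+H_b)/2 > (H*+e+L)/2 whenever
#' H > L + e, enforced by the sampling ranges).  A small integer jitter is
#' then added to all outcomes and the tree re-validated; invalid draws are
#' retried a bounded number of times.
#'
#' @param seed integer seed.
#' @param value_range integer bounds for outcome values (default 0--120).
#' @param template_id integer 1--4.
#' @param max_tries retry bound before failing loudly.
#' @return a full `decision_tree` passing [validate_design()].
#' @export
generate_template <- function(seed, value_range = c(0, 120),
                              template_id = 1L, max_tries = 50L) {
  stopifnot(diff(range(value_range)) >= 30)
  lo <- value_range[1]; hi <- value_range[2]
  ## headroom: +e (3) +jitter (5) +derived-template shift (3)
  h_max <- hi - 11L
  h_min <- max(lo + 12L, ceiling(0.6 * h_max))
  for (try in seq_len(max_tries)) {
    tr <- with_seed(substream_seed(seed, "template", try), {
      L <- lo + sample(0:min(8L, h_min - lo - 4L), 1)
      Ha <- sample(h_min:h_max, 1)
      Hb <- min(Ha + sample(0:5, 1), h_max)
      e <- sample(1:3, 1)
      Hs <- max(Ha, Hb)
      jit <- sample(0:5, 1)   # common offset jitter, validity-preserving
      tr <- full_tree(list(
        list(c(Ha, Ha), c(L, L)),
        list(c(Hb, Hb), c(L, L)),
        list(c(Hs + e, L), c(Hs, L)),
        list(c(Hs + e, L), c(Hs, L))), template_id = template_id)
      shift_template(tr, jit)
    })
    vals <- outcome_values(tr)
    if (min(vals) >= value_range[1] && max(vals) <= value_range[2] &&
        validate_design(tr)$ok)
      return(tr)
  }
  stop("generate_template: no valid tree after ", max_tries, " tries")
}

#' Derive a half tree from a full tree
#'
#' At each second-stage decision node one chance node is replaced by an
#' outcome node equal to that chance node's expected value, so the choice
#' becomes gamble vs. certain payoff.  By default the *dominated* chance
#' node is replaced, which leaves every DN2 backward-induction value (and
#' hence the DN1 solution) unchanged.
#'
#' @param full a valid full `decision_tree`.
#' @param replace `"dominated"` (default) or `"dominant"`: which chance node
#'   of each DN2 becomes the certain payoff.
#' @return a half `decision_tree` with the same `template_id`.
#' @export
derive_half_tree <- function(full, replace = c("dominated", "dominant")) {
  stopifnot(full$kind == "full")
  replace <- match.arg(replace)
  nodes <- full$nodes
  drop <- character()
  for (dn in dn2_ids(full)) {
    ch <- canonical_children(full, dn)
    la <- node_lottery(full, ch[1]); lb <- node_lottery(full, ch[2])
    dominant <- if (fosd(lb, la)) 2L else 1L   # canonical-first tie -> 1
    target <- if (replace == "dominated") ch[3L - dominant] else ch[dominant]
    cn <- nodes[[target]]
    new_on <- sub("CN", "ONc", target)          # certainty ON, e.g. "ONc3"
    nodes[[new_on]] <- tree_node(new_on, "ON",
      value = sum(cn$probs * vapply(cn$children, function(i)
        nodes[[i]]$value, 0)))
    kids <- nodes[[dn]]$children
    nodes[[dn]]$children <- replace(kids, kids == target, new_on)
    drop <- c(drop, target, cn$children)
  }
  nodes[drop] <- NULL
  smap <- full$scramble_map[setdiff(names(full$scramble_map), drop)]
  decision_tree("half", nodes, root = full$root,
                template_id = full$template_id, scramble_map = smap)
}

#' Derive a single-stage tree from a full tree
#'
#' Removes the second decision stage: one decision node offering two
#' 8-outcome gambles, the left holding the full tree's left-branch outcomes
#' (ON1--8) and the right its right-branch outcomes (ON9--16), each
#' equiprobable.  By design one gamble stochastically dominates the other.
#'
#' @param full a valid full `decision_tree`.
#' @return a single-stage `decision_tree`.
#' @export
derive_single_stage <- function(full) {
  stopifnot(full$kind == "full")
  branch_ons <- function(side) {
    lot <- node_lottery(full, canonical_children(full, full$root)[side],
                        dn_as_chance = TRUE)
    ## recover the 8 raw outcome values (lottery() merges duplicates)
    ons <- character()
    walk <- function(id) {
      nd <- full$nodes[[id]]
      if (nd$role == "ON") ons <<- c(ons, id) else lapply(nd$children, walk)
    }
    walk(canonical_children(full, full$root)[side])
    vapply(ons, function(i) full$nodes[[i]]$value, 0)
  }
  lv <- branch_ons(1); rv <- branch_ons(2)
  nodes <- list(
    tree_node("DN1", "DN", children = c("CN1", "CN2")),
    tree_node("CN1", "CN", children = paste0("ON", 1:8),
              probs = rep(1 / 8, 8)),
    tree_node("CN2", "CN", children = paste0("ON", 9:16),
              probs = rep(1 / 8, 8)))
  nodes <- c(nodes,
    Map(function(id, v) tree_node(id, "ON", value = v),
        paste0("ON", 1:16), c(lv, rv)))
  decision_tree("single_stage", nodes, template_id = full$template_id)
}

#' Build the four templates of each condition for one experiment
#'
#' Template 1 is generated (or the fixture is used), templates 2--4 add
#' constants 1--3; half and single-stage trees are derived per template.
#'
#' @param seed integer seed; `NULL` uses the fixture template.
#' @param value_range passed to [generate_template()].
#' @param half_replace passed to [derive_half_tree()].
#' @return nested list: `$full`, `$half`, `$single_stage`, each a list of
#'   four `decision_tree`s indexed by template id.
#' @export
build_template_set <- function(seed = NULL, value_range = c(0, 120),
                               half_replace = "dominated") {
  base <- if (is.null(seed)) tfix_tree(1L)
          else generate_template(seed, value_range, template_id = 1L)
  full <- lapply(1:4, function(k) {
    tr <- shift_template(base, k - 1L)
    tr$template_id <- as.integer(k)
    tr
  })
  list(full = full,
       half = lapply(full, derive_half_tree, replace = half_replace),
       single_stage = lapply(full, derive_single_stage))
}
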