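## ---------------------------------------------------------------------------
## Experimental design: 5 blocks x 8 trials; blocks 1-4 alternate full/half
## trees (Latin-square counterbalanced block orders), block 5 single-stage.
## Each of the 4 templates appears twice per block, never back-to-back.
## ---------------------------------------------------------------------------

## Latin square over the four two-stage block labels (full-1, half-1,
## full-2, half-2); cyclic rotations keep the full/half alternation.
latin_rows <- list(
  c("full", "half", "full", "half"),
  c("half", "full", "half", "full"),
  c("full", "half", "full", "half"),
  c("half", "full", "half", "full"))

## A template order for one block: permutation of {1,1,2,2,3,3,4,4} with no
## adjacent repeats, by rejection sampling.
block_template_order <- function(seed) {
  with_seed(seed, {
    repeat {
      s <- sample(rep(1:4, 2L))
      if (!any(s[-1] == s[-8])) return(s)
    }
  })
}

#' Generate the experimental design for a cohort
#'
#' Participants cycle through the four Latin-square block orders (with 50
#' participants the remainder of 2 means two orders are used one extra
#' time).  Every trial receives its own scramble seed.
#'
#' @param seed integer master seed.
#' @param n_participants cohort size (>= 4 for counterbalancing).
#' @return list of per-participant designs; each is a list with
#'   `participant`, `block_order_id`, and `blocks` -- five blocks each
#'   holding `condition` and a data frame `trials` with `trial`
#'   (1--40), `template_id`, `scramble_seed`.
#' @export
generate_design <- function(seed, n_participants = 50L) {
  stopifnot(n_participants >= 4L)
  lapply(seq_len(n_participants), function(p) {
    row <- (p - 1L) %% 4L + 1L
    conds <- c(latin_rows[[row]], "single_stage")
    blocks <- lapply(1:5, function(b) {
      tpl <- block_template_order(substream_seed(seed, "ord", p, b))
      idx <- (b - 1L) * 8L + 1:8
      list(condition = conds[b],
           trials = data.frame(
             trial = idx, template_id = tpl,
             scramble_seed = vapply(idx, function(i)
               substream_seed(seed, "scr", p, i), 0L)))
    })
    list(participant = p, block_order_id = row, blocks = blocks)
  })
}

## Map each (condition, block) of a design to presentation half 1 or 2:
## the earlier block of a two-stage condition holds presentations 1-2.
condition_half <- function(design_p, block) {
  cond <- vapply(design_p$blocks, `[[`, "", "condition")
  which(which(cond == cond[block]) == block)
}

## ---------------------------------------------------------------------------
## Generators (simulated participants)
## ---------------------------------------------------------------------------

#' Generator specifications for simulated participants
#'
#' `te_generator` emits first-stage choices from the True-and-Error
#' process: a latent true preference (backward- vs forward-consistent) per
#' experiment half, plus independent trembling-hand response errors.
#' Second-stage (and single-stage) choices are EV-maximizing with an
#' independent flip rate `dn2_error` -- a stand-in, since the TE model only
#' describes DN1.  `dft_generator` emits every choice by running the
#' Decision Field Theory-Planning simulator.
#'
#' @param B,s_b,s_f,e12,e34 TE parameters, see [te_params()].
#' @param dn2_error flip rate for EV-maximizing non-DN1 choices.
#' @return a generator list consumed by [simulate_participant()].
#' @export
te_generator <- function(B, s_b, s_f, e12 = 0.05, e34 = 0.05,
                         dn2_error = 0.05) {
  list(type = "te", params = te_params(B, s_b, s_f, e12, e34),
       dn2_error = dn2_error)
}

#' @rdname te_generator
#' @param spec a [model_spec()] (DFT variant).
#' @param params a [dft_params()] object.
#' @export
dft_generator <- function(spec, params) {
  list(type = "dft", spec = spec, params = params)
}

#' Simulate one participant through a design
#'
#' Chance nodes are realized as fair coin draws.  All sides are recorded in
#' canonical coding (invariant to scrambling) alongside the physical
#' on-screen coding induced by the trial's scramble seed.
#'
#' @param design_p one element of [generate_design()]'s output.
#' @param trees a template set from [build_template_set()].
#' @param generator a [te_generator()] or [dft_generator()].
#' @param seed integer seed; fixed seed gives bit-identical records.
#' @return data frame of trial records (one row per trial).
#' @export
simulate_participant <- function(design_p, trees, generator, seed) {
  stopifnot(generator$type %in% c("te", "dft"))
  p <- design_p$participant
  if (generator$type == "te") {
    g <- generator$params
    prefs <- with_seed(substream_seed(seed, "pref", p), {
      bi1 <- runif(1) < g$B
      bi2 <- if (bi1) runif(1) < g$s_b else runif(1) >= g$s_f
      c(bi1, bi2)
    })
  }
  rows <- list()
  for (b in 1:5) {
    blk <- design_p$blocks[[b]]
    for (r in seq_len(nrow(blk$trials))) {
      ti <- blk$trials$trial[r]
      tpl <- blk$trials$template_id[r]
      tree <- trees[[blk$condition]][[tpl]]
      pol <- backward_induction(tree)
      tseed <- substream_seed(seed, "trial", p, ti)
      rec <- with_seed(tseed, {
        root_ch <- canonical_children(tree, tree$root)
        if (generator$type == "te") {
          if (blk$condition == "single_stage") {
            target <- pol$choice_at[[tree$root]]
            err <- generator$dn2_error
          } else {
            half <- condition_half(design_p, b)
            bi <- prefs[half]
            fw <- forward_evaluation(tree)
            bi_choice <- pol$choice_at[[tree$root]]
            fw_choice <- root_ch[match(fw$preferred, c("left", "right"))]
            target <- if (bi) bi_choice else fw_choice
            err <- if (half == 1L) g$e12 else g$e34
          }
          flip <- runif(1) < err
          dn1 <- if (flip) setdiff(root_ch, target) else target
        } else {
          mode <- if (blk$condition == "single_stage") "final" else "planning"
          gpar <- apply_spec(generator$spec, generator$params)
          plan <- dft_plans_dn2(generator$spec, b, gpar)
          dn1 <- dft_choose(tree, tree$root, mode, gpar, plan_dn2 = plan)
        }
        ## first-stage chance realization and second-stage choice
        if (blk$condition == "single_stage") {
          out_node <- sample(tree$nodes[[dn1]]$children, 1,
                             prob = tree$nodes[[dn1]]$probs)
          cn_side <- NA_character_; dn2_node <- NA_character_
          dn2 <- NA_character_; dn2_side <- NA_character_
          outcome <- tree$nodes[[out_node]]$value
        } else {
          branch <- sample(1:2, 1)
          dn2_node <- canonical_children(tree, dn1)[branch]
          cn_side <- c("left", "right")[branch]
          dn2_ch <- canonical_children(tree, dn2_node)
          if (generator$type == "te") {
            best <- pol$choice_at[[dn2_node]]
            dn2 <- if (runif(1) < generator$dn2_error)
              setdiff(dn2_ch, best) else best
          } else {
            dn2 <- dft_choose(tree, dn2_node, "final", gpar, plan_dn2 = TRUE)
          }
          dn2_side <- canonical_side(tree, dn2_node, dn2)
          nd <- tree$nodes[[dn2]]
          outcome <- if (nd$role == "ON") nd$value else
            tree$nodes[[sample(nd$children, 1, prob = nd$probs)]]$value
        }
        str <- scramble(tree, blk$trials$scramble_seed[r])
        data.frame(
          participant = p, block = b, trial = ti,
          condition = blk$condition, template_id = tpl,
          scramble_seed = blk$trials$scramble_seed[r],
          dn1_choice = canonical_side(tree, tree$root, dn1),
          dn1_physical = physical_side(str, tree$root, dn1),
          cn_outcome = cn_side, dn2_node = dn2_node,
          dn2_choice = dn2_side,
          final_outcome = outcome,
          generator = generator$type,
          stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full cohort
#'
#' Builds the template set, design, and trial records for `n_participants`
#' simulated decision makers.
#'
#' @param seed integer master seed (streams into per-participant and
#'   per-trial substreams).
#' @param n_participants cohort size.
#' @param generators either a single generator (recycled) or a list of one
#'   generator per participant.
#' @param trees optional template set; built from `seed` when `NULL`.
#' @param use_fixture if `TRUE` (default) the fixture template set is used;
#'   otherwise templates are generated from `seed`.
#' @return object of class `dyn_cohort`: list with `trees`, `design`,
#'   `trials` (stacked trial records), `generators`.
#' @export
simulate_cohort <- function(seed, n_participants = 50L, generators,
                            trees = NULL, use_fixture = TRUE) {
  if (is.null(trees))
    trees <- build_template_set(seed = if (use_fixture) NULL else
                                substream_seed(seed, "trees"))
  design <- generate_design(seed, n_participants)
  if (!is.null(generators$type)) generators <- list(generators)
  gl <- rep(generators, length.out = n_participants)
  trials <- do.call(rbind, lapply(seq_len(n_participants), function(p)
    simulate_participant(design[[p]], trees, gl[[p]],
                         substream_seed(seed, "participant", p))))
  structure(list(trees = trees, design = design, trials = trials,
                 generators = gl),
            class = "dyn_cohort")
}

#' @export
print.dyn_cohort <- function(x, ...) {
  cat(sprintf("<dyn_cohort> %d participants, %d trials (%s)\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              paste(unique(x$trials$generator), collapse = "/")))
  invisible(x)
}

#' Write and read trial records as CSV
#'
#' One row per trial, with both canonical-side and physical-side coding.
#'
#' @param trials trial-record data frame (or a `dyn_cohort`).
#' @param path file path.
#' @export
write_trials_csv <- function(trials, path) {
  if (inherits(trials, "dyn_cohort")) trials <- trials$trials
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read experimental designs as JSON
#'
#' @param design the list returned by [generate_design()].
#' @param path file path.
#' @return `read_design_json` returns the design list.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(d)
    list(participant = as.integer(d$participant),
         block_order_id = as.integer(d$block_order_id),
         blocks = lapply(d$blocks, function(b)
           list(condition = b$condition,
                trials = data.frame(
                  trial = vapply(b$trials$trial, as.integer, 0L),
                  template_id = vapply(b$trials$template_id, as.integer, 0L),
                  scramble_seed = vapply(b$trials$scramble_seed,
                                         as.integer, 0L))))))
}
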