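## ---------------------------------------------------------------------------
## Orchestration: generate -> simulate -> extract -> fit -> cross-validate
## -> report, as a reproducible, configured pipeline.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param seed master seed; every stage derives substreams from it.
#' @param n_participants cohort size.
#' @param generator_mix list of components, each
#'   `list(weight=, generator=)`; weights must sum to 1.  Participants are
#'   assigned deterministically in proportion to the weights.
#' @param n_sims simulations per predicted probability for DFT stages.
#' @param search a [dft_search_config()].
#' @param specs DFT variants to cross-validate.
#' @param out_dir output directory.
#' @param stages character subset of `c("trees", "simulate", "te", "dft")`.
#' @param use_fixture use the fixture template set (default) or generate
#'   templates from the seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 8L,
                            generator_mix = list(
                              list(weight = 0.5,
                                   generator = te_generator(.5, .9, .7,
                                                            .15, .15)),
                              list(weight = 0.5,
                                   generator = dft_generator(
                                     model_spec("DFT2"),
                                     dft_params(5, 25, phi = .8,
                                                delta = .1)))),
                            n_sims = 300L,
                            search = dft_search_config(grid_points = 4L),
                            specs = list(model_spec("DFT2"),
                                         model_spec("DFT2_no_plan")),
                            out_dir = tempfile("dynchoice_run_"),
                            stages = c("trees", "simulate", "te", "dft"),
                            use_fixture = TRUE) {
  w <- vapply(generator_mix, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("generator mix weights must sum to 1")
  if (n_participants < 1L) stop("cohort size must be positive")
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 generator_mix = generator_mix, n_sims = as.integer(n_sims),
                 search = search, specs = specs, out_dir = out_dir,
                 stages = stages, use_fixture = isTRUE(use_fixture)),
            class = "pipeline_config")
}

## Deterministic proportional assignment of generators to participants.
mix_generators <- function(mix, n) {
  w <- vapply(mix, `[[`, 0, "weight")
  counts <- diff(round(cumsum(c(0, w)) * n))
  idx <- rep(seq_along(mix), counts)
  if (length(idx) < n) idx <- c(idx, rep(length(mix), n - length(idx)))
  lapply(idx[seq_len(n)], function(i) mix[[i]]$generator)
}

#' Run the full analysis pipeline
#'
#' Emits trees (JSON), trial records (CSV), TE pattern counts (CSV) and
#' fits (JSON), DFT cross-validation and maximization-rate tables (CSV),
#' and a manifest (JSON) with seeds, versions, and per-file MD5 checksums.
#' Reruns with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a bundle list with the stage outputs and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(out_dir = config$out_dir, config = config)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  trees <- step("trees", build_template_set(
    seed = if (config$use_fixture) NULL
           else substream_seed(config$seed, "trees")))
  if ("trees" %in% config$stages) {
    for (cond in names(trees))
      for (tpl in seq_along(trees[[cond]]))
        tree_to_json(trees[[cond]][[tpl]],
                     file.path(config$out_dir,
                               sprintf("tree_%s_%d.json", cond, tpl)))
  }
  bundle$trees <- trees

  if (any(c("simulate", "te", "dft") %in% config$stages)) {
    gens <- mix_generators(config$generator_mix, config$n_participants)
    cohort <- step("simulate", simulate_cohort(
      config$seed, config$n_participants, gens, trees = trees))
    write_trials_csv(cohort, file.path(config$out_dir, "trials.csv"))
    bundle$cohort <- cohort
  }

  if ("te" %in% config$stages) {
    te <- step("te", {
      counts <- list(full = extract_patterns(cohort, "full"),
                     half = extract_patterns(cohort, "half"))
      fits <- lapply(counts, fit_te, seed = config$seed)
      for (cond in names(counts))
        write_pattern_counts(counts[[cond]],
                             file.path(config$out_dir,
                                       sprintf("patterns_%s.csv", cond)))
      jsonlite::write_json(
        lapply(fits, function(f) list(
          estimates = unclass(f$params), G2 = f$G2, df = f$df,
          p_value = f$p_value,
          second_half_prevalence = second_half_prevalence(f$params))),
        file.path(config$out_dir, "te_fits.json"),
        auto_unbox = TRUE, digits = NA)
      list(counts = counts, fits = fits)
    })
    bundle$te <- te
  }

  if ("dft" %in% config$stages) {
    dft <- step("dft", {
      sel <- select_models(cohort, config$specs, seed = config$seed,
                           search = config$search)
      maxr <- maximization_rates(cohort)
      write.csv(sel$summary, file.path(config$out_dir, "selection.csv"),
                row.names = FALSE)
      write.csv(maxr, file.path(config$out_dir, "maximization.csv"),
                row.names = FALSE)
      list(selection = sel, maximization = maxr)
    })
    bundle$dft <- dft
  }

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "dynchoice",
    version = as.character(utils::packageVersion("dynchoice")),
    seed = config$seed, n_participants = config$n_participants,
    stages = config$stages,
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Summarize a pipeline bundle
#'
#' Tabulates TE estimates (against generating values where known), DFT
#' model-selection counts by variant, and -- when a switch variant was
#' cross-validated -- the switch-point distribution.  Regeneration from the
#' same bundle is idempotent.
#'
#' @param bundle the return value of [run_pipeline()].
#' @return a `pipeline_report` list with `te`, `selection_counts`,
#'   `switch_points`, `maximization`; printed as tables.
#' @export
pipeline_report <- function(bundle) {
  rep <- list()
  if (!is.null(bundle$te)) {
    rep$te <- do.call(rbind, lapply(names(bundle$te$fits), function(cond) {
      f <- bundle$te$fits[[cond]]
      data.frame(condition = cond, B = f$params$B, s_b = f$params$s_b,
                 s_f = f$params$s_f, e12 = f$params$e12, e34 = f$params$e34,
                 G2 = f$G2, df = f$df, p = f$p_value,
                 second_half = second_half_prevalence(f$params))
    }))
  }
  if (!is.null(bundle$dft)) {
    counts <- table(bundle$dft$selection$summary$winner)
    rep$selection_counts <- as.data.frame(counts,
                                          stringsAsFactors = FALSE)
    names(rep$selection_counts) <- c("variant", "n")
    sps <- unlist(lapply(bundle$dft$selection$cv, function(cv) {
      w <- which(rownames(cv$accuracy) == cv$winner)[1]
      best <- which.max(vapply(cv$fits[[w]], `[[`, 0, "loglik"))
      cv$fits[[w]][[best]]$params$switch_point
    }))
    rep$switch_points <- table(factor(sps, levels = 0:4))
    rep$maximization <- bundle$dft$maximization
  }
  if (is.null(rep$te) && is.null(rep$selection_counts))
    warning("report: no completed model stages in bundle")
  structure(rep, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (!is.null(x$te)) {
    cat("True-and-Error fits:\n")
    print(x$te, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$selection_counts)) {
    cat("\nCross-validated model selection:\n")
    print(x$selection_counts, row.names = FALSE)
    cat("\nSwitch-point distribution of winners:\n")
    print(x$switch_points)
    cat("\nMaximization rates:\n")
    print(x$maximization, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Read a pipeline configuration from JSON
#'
#' A minimal external interface for the command-line driver: recognised
#' fields are `seed`, `n_participants`, `n_sims`, `grid_points`,
#' `out_dir`, `stages`, `use_fixture`; generator mix and specs fall back
#' to the defaults of [pipeline_config()].
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("seed", "n_participants", "n_sims", "out_dir", "use_fixture"))
    if (!is.null(js[[nm]])) args[[nm]] <- js[[nm]]
  if (!is.null(js$stages)) args$stages <- js$stages
  if (!is.null(js$grid_points))
    args$search <- dft_search_config(grid_points = js$grid_points,
                                     n_sims = js$n_sims %||% 300L)
  do.call(pipeline_config, args)
}
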