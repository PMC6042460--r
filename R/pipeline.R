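#' End-to-end pipeline: simulate/load -> estimate -> network -> report
#'
#' @name pipeline
NULL

#' Configure a pipeline run
#'
#' Exactly one of `input` (a cohort CSV readable by
#' [read_qualifier_matrix()]) or `synthetic` (a [synthetic_spec()]) must be
#' given.
#'
#' @param output_dir directory for all artifacts (created if absent).
#' @param input path to a cohort score CSV, or `NULL`.
#' @param synthetic a [synthetic_spec()], or `NULL`.
#' @param schema schema used to validate `input` (defaults to the bundled
#'   CIHD core set; ignored when `synthetic` is given).
#' @param estimation an [estimation_config()].
#' @param zero_tol edge-existence threshold for the graph.
#' @param hi_cutoff,lo_cutoff report cutoffs for the strong (`>=`) and weak
#'   (`<=`, nonzero) coefficient tables.
#' @param max_cycle_len cycle-search length cap.
#' @param cycle_weight_cutoff magnitude cutoff for edges seeding the cycle
#'   search (keeps the enumeration small).
#' @param seed master seed for a synthetic run (overrides the spec's seed
#'   and derives the estimation `cv_seed` as `seed + 2`).
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir, input = NULL, synthetic = NULL,
                       schema = NULL, estimation = estimation_config(),
                       zero_tol = 1e-8, hi_cutoff = 0.75, lo_cutoff = 0.25,
                       max_cycle_len = 5L, cycle_weight_cutoff = 0.25,
                       seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of 'input' and 'synthetic' must be given", call. = FALSE)
  }
  structure(list(output_dir = output_dir, input = input,
                 synthetic = synthetic, schema = schema,
                 estimation = estimation, zero_tol = zero_tol,
                 hi_cutoff = hi_cutoff, lo_cutoff = lo_cutoff,
                 max_cycle_len = as.integer(max_cycle_len),
                 cycle_weight_cutoff = cycle_weight_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: (1) simulate a cohort or load one from CSV; (2) node-wise
#' cross-validated lasso -> dependence matrix; (3) dependency graph and its
#' summaries; (4) reports. Writes, under `output_dir`: `cohort.csv` (if
#' simulated), `dependence_matrix.csv` (dense), `dependence_edges.csv`
#' (sparse), `out_degree.csv`, `strong_edges.csv`, `weak_edges.csv`,
#' `negative_edges.csv`, `bidirectional_pairs.csv`, `loops.json`,
#' `graph.graphml`, `graph.dot` and `manifest.json`. Identical config and
#' seed reproduce byte-identical files.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory results (`cohort`, `D`,
#'   `graph`, `out_degree`, `reports`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[icfnet] ", ...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  # stage 1: cohort
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- config$seed
    say("simulating cohort: ", spec$n_patients, " patients x ",
        nrow(spec$schema), " categories (seed ", spec$seed, ")")
    cohort <- tryCatch(generate_cohort(spec)$matrix,
                       error = function(e) stop("stage 'simulate' failed: ",
                                                conditionMessage(e),
                                                call. = FALSE))
    write_qualifier_matrix(cohort, out("cohort.csv"))
  } else {
    schema <- if (is.null(config$schema)) load_schema("cihd") else config$schema
    say("reading cohort from ", config$input)
    cohort <- tryCatch(read_qualifier_matrix(config$input, schema),
                       error = function(e) stop("stage 'load' failed: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  }

  # stage 2: estimation
  est <- config$estimation
  est$cv_seed <- config$seed + 2L
  say("estimating dependence matrix (", ncol(cohort), " node-wise fits, ",
      est$n_folds, "-fold CV, grid size ", est$lambda_grid_size, ")")
  D <- tryCatch(estimate_dependence_matrix(cohort, est),
                error = function(e) stop("stage 'estimate' failed: ",
                                         conditionMessage(e), call. = FALSE))
  write_dependence_matrix(D, out("dependence_matrix.csv"),
                          out("dependence_edges.csv"), config$zero_tol)

  # stage 3: graph + summaries
  g <- build_graph(D, config$zero_tol)
  deg <- out_degrees(g)
  write.csv(data.frame(code = names(deg), out_degree = deg),
            out("out_degree.csv"), row.names = FALSE, quote = FALSE)
  strong <- threshold_count(D, ">=", config$hi_cutoff, config$zero_tol)
  weak <- threshold_count(D, "<=", config$lo_cutoff, config$zero_tol)
  neg <- negative_edges(D, config$zero_tol)
  bip <- bidirectional_pairs(D, config$zero_tol)
  write.csv(strong$entries, out("strong_edges.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(weak$entries, out("weak_edges.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(neg, out("negative_edges.csv"), row.names = FALSE, quote = FALSE)
  write.csv(bip, out("bidirectional_pairs.csv"), row.names = FALSE,
            quote = FALSE)
  loops <- find_cycles(D, config$zero_tol, config$cycle_weight_cutoff,
                       config$max_cycle_len)
  jsonlite::write_json(loops, out("loops.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  export_graph(g, out("graph.graphml"), "graphml")
  export_graph(g, out("graph.dot"), "dot")
  say(length(g$nodes), " nodes, ", nrow(g$edges), " edges; ",
      strong$count, " coefficients >= ", config$hi_cutoff, ", ",
      weak$count, " nonzero <= ", config$lo_cutoff, ", ",
      nrow(neg), " negative; excluded: ",
      if (length(attr(D, "excluded"))) paste(attr(D, "excluded"),
                                             collapse = ", ") else "none")

  # stage 4: manifest (no timestamps -- reruns must be byte-identical)
  manifest <- list(
    package = "icfnet",
    version = as.character(utils::packageVersion("icfnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    input = if (is.null(config$input)) NULL else config$input,
    synthetic = if (is.null(config$synthetic)) NULL else list(
      n_patients = config$synthetic$n_patients,
      n_categories = nrow(config$synthetic$schema),
      noise_sd = config$synthetic$noise_sd,
      missing_rate_8 = config$synthetic$missing_rate_8,
      missing_rate_9 = config$synthetic$missing_rate_9,
      edges = config$synthetic$edges
    ),
    estimation = unclass(est),
    report = list(zero_tol = config$zero_tol, hi_cutoff = config$hi_cutoff,
                  lo_cutoff = config$lo_cutoff,
                  max_cycle_len = config$max_cycle_len,
                  cycle_weight_cutoff = config$cycle_weight_cutoff),
    excluded_categories = attr(D, "excluded"),
    n_coefficients = length(D)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, D = D, graph = g, out_degree = deg,
                 reports = list(strong = strong, weak = weak, negative = neg,
                                bidirectional = bip, loops = loops),
                 manifest = manifest))
}
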