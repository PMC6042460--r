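#' Synthetic qualifier cohorts with planted dependency structure
#'
#' The generator emulates a functioning-assessment cohort: latent continuous
#' severities follow a linear-Gaussian structural model over a directed
#' acyclic edge set, each latent column is discretised through ordered
#' cut-points into the 0--4 qualifier scale, and "not specified" (8) /
#' "not applicable" (9) codes are injected completely at random. Because the
#' planted edges are the ground truth, the downstream estimator can be
#' scored for structure recovery.
#'
#' @name synthetic-cohorts
NULL

# default cut-points on the standardised latent scale: right-skewed ordinal
# marginals (most mass in 0-2), resembling mildly impaired cohorts
.default_cutpoints <- c(-0.85, 0, 0.85, 1.65)

#' Specify a synthetic cohort
#'
#' @param n_patients number of patients (rows).
#' @param schema an [load_schema()] schema fixing the categories.
#' @param edges data frame with columns `source`, `target`, `weight`: the
#'   planted directed effects, read as a linear structural model
#'   `x[target] <- sum(weight * x[source]) + noise`. Must be acyclic and
#'   self-edge free.
#' @param noise_sd standard deviation of the structural noise (every node).
#' @param thresholds either a single vector of 4 strictly increasing
#'   cut-points used for all categories, or a list of such vectors (one per
#'   category), applied to the standardised latent scale.
#' @param missing_rate_8,missing_rate_9 per-cell probabilities of replacing
#'   a score with 8 resp. 9; their sum must be at most 1.
#' @param seed master seed; all sub-streams derive from it.
#' @return a list of class `synthetic_spec`.
#' @examples
#' sch <- load_schema("cihd")
#' sp <- synthetic_spec(120, sch, cihd_default_edges(), seed = 1)
#' @export
synthetic_spec <- function(n_patients, schema, edges = NULL, noise_sd = 1,
                           thresholds = .default_cutpoints,
                           missing_rate_8 = 0, missing_rate_9 = 0,
                           seed = 1L) {
  stopifnot(n_patients >= 1, noise_sd > 0)
  if (missing_rate_8 < 0 || missing_rate_8 > 1 ||
      missing_rate_9 < 0 || missing_rate_9 > 1 ||
      missing_rate_8 + missing_rate_9 > 1) {
    stop("missing rates must lie in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric())
  }
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  unknown <- setdiff(c(edges$source, edges$target), schema$code)
  if (length(unknown)) {
    stop("edge endpoint(s) not in schema: ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  stopifnot(all(is.finite(edges$weight)))
  thresholds <- .validate_thresholds(thresholds, schema$code)
  structure(list(n_patients = as.integer(n_patients), schema = schema,
                 edges = edges, noise_sd = noise_sd, thresholds = thresholds,
                 missing_rate_8 = missing_rate_8,
                 missing_rate_9 = missing_rate_9, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.validate_thresholds <- function(thresholds, codes) {
  check <- function(v, code) {
    if (length(v) != 4L || any(diff(v) <= 0)) {
      stop("cut-points for '", code,
           "' must be 4 strictly increasing values", call. = FALSE)
    }
    v
  }
  if (!is.list(thresholds)) {
    return(stats::setNames(rep(list(check(thresholds, "all")), length(codes)),
                           codes))
  }
  if (is.null(names(thresholds))) names(thresholds) <- codes
  stopifnot(setequal(names(thresholds), codes))
  mapply(check, thresholds[codes], codes, SIMPLIFY = FALSE)
}

# topological order of schema codes under the planted edges;
# errors with an explicit cycle if one exists (Kahn's algorithm)
.topo_order <- function(edges, codes) {
  indeg <- stats::setNames(integer(length(codes)), codes)
  tab <- table(factor(edges$target, levels = codes))
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- codes[indeg == 0L]
  remaining <- edges
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    out <- remaining$source == v
    for (t in remaining$target[out]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(order) < length(codes)) {
    cyc <- setdiff(codes, order)
    # walk successors among the leftover nodes until a node repeats
    nxt <- function(v) remaining$target[remaining$source == v][1L]
    path <- cyc[1L]
    repeat {
      v <- nxt(path[length(path)])
      if (v %in% path) {
        path <- c(path[which(path == v):length(path)], v)
        break
      }
      path <- c(path, v)
    }
    stop("planted edge set is cyclic: ", paste(path, collapse = " -> "),
         call. = FALSE)
  }
  order
}

#' Draw the latent severity matrix of a synthetic spec
#'
#' Columns are generated in a topological order of the planted edges: root
#' nodes (no parents) are standard normal, and every node with parents is
#' the weighted sum of its parents plus independent `N(0, noise_sd^2)`
#' noise. Edge weights are therefore structural coefficients on a scale
#' where exogenous severities have unit variance: a single edge `A -> B`
#' with weight `w` gives `cor(A, B) = w / sqrt(w^2 + noise_sd^2)`.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric `n_patients` x `p` matrix with category codes as colnames.
#' @export
generate_latent <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  codes <- spec$schema$code
  order <- .topo_order(spec$edges, codes)
  n <- spec$n_patients
  set.seed(spec$seed)
  x <- matrix(0, n, length(codes), dimnames = list(NULL, codes))
  for (v in order) {
    e <- spec$edges[spec$edges$target == v, , drop = FALSE]
    if (nrow(e)) {
      x[, v] <- x[, e$source, drop = FALSE] %*% e$weight +
        rnorm(n, sd = spec$noise_sd)
    } else {
      x[, v] <- rnorm(n)  # exogenous severities are standard normal
    }
  }
  x[, codes, drop = FALSE]
}

#' Discretise latent severities into 0--4 qualifiers
#'
#' Value `k` is assigned where the latent falls in the `k`-th of the five
#' bins delimited by the four cut-points; the map is monotone in the latent.
#'
#' @param latent numeric matrix (columns named by category code) or vector.
#' @param thresholds 4 strictly increasing cut-points, or a named list of
#'   such vectors per category.
#' @return integer matrix (or vector) over `{0..4}`.
#' @examples
#' discretize_latent(c(-2, 0, 2), c(-1.5, -0.5, 0.5, 1.5))
#' @export
discretize_latent <- function(latent, thresholds) {
  if (is.null(dim(latent))) {
    if (length(thresholds) != 4L || any(diff(unlist(thresholds)) <= 0)) {
      stop("cut-points must be 4 strictly increasing values", call. = FALSE)
    }
    return(as.integer(findInterval(latent, unlist(thresholds))))
  }
  codes <- colnames(latent)
  thresholds <- .validate_thresholds(thresholds, codes)
  out <- vapply(codes, function(code) {
    as.integer(findInterval(latent[, code], thresholds[[code]]))
  }, integer(nrow(latent)))
  dimnames(out) <- dimnames(latent)
  out
}

#' Inject "not specified"/"not applicable" codes completely at random
#'
#' Each cell is independently replaced by 8 with probability `rate8`, by 9
#' with probability `rate9`, else kept.
#'
#' @param values integer matrix over `{0..4}`.
#' @param rate8,rate9 probabilities, `rate8 + rate9 <= 1`.
#' @param seed RNG seed for the missingness stream.
#' @return a [qualifier_matrix()].
#' @export
inject_missing <- function(values, rate8, rate9, seed) {
  if (rate8 < 0 || rate8 > 1 || rate9 < 0 || rate9 > 1 || rate8 + rate9 > 1) {
    stop("missing rates must lie in [0,1] and sum to at most 1", call. = FALSE)
  }
  set.seed(seed)
  u <- matrix(runif(length(values)), nrow(values))
  values[u < rate8] <- 8L
  values[u >= rate8 & u < rate8 + rate9] <- 9L
  qualifier_matrix(values)
}

#' Generate a synthetic qualifier cohort
#'
#' Composes [generate_latent()], per-column standardisation of the latent
#' (so the default cut-points act on an approximately standard scale),
#' [discretize_latent()] and [inject_missing()]. Identical spec (including
#' seed) gives bitwise-identical output; the missingness stream uses
#' `seed + 1`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_cohort`: `matrix` (a
#'   [qualifier_matrix()]), `truth` (the spec) and `latent` (kept for
#'   diagnostics).
#' @export
generate_cohort <- function(spec) {
  latent <- generate_latent(spec)
  z <- scale(latent)  # cut-points are defined on the standardised scale
  scores <- discretize_latent(z, spec$thresholds)
  rownames(scores) <- sprintf("P%03d", seq_len(nrow(scores)))
  m <- inject_missing(scores, spec$missing_rate_8, spec$missing_rate_9,
                      seed = spec$seed + 1L)
  structure(list(matrix = m, truth = spec, latent = latent),
            class = "synthetic_cohort")
}

#' Default planted edge set for the 46-category CIHD schema
#'
#' A stand-in dependency structure used by the simulation drivers: a sparse
#' set of plausible directed effects among the bundled categories (cardiac
#' function driving exercise tolerance and mobility, mobility driving
#' domestic life and recreation, and so on). It is a synthetic construct for
#' exercising the pipeline, not an estimate of the published network.
#'
#' @return data frame with columns `source`, `target`, `weight`.
#' @export
cihd_default_edges <- function() {
  data.frame(
    source = c("b410", "b410", "b415", "b455", "b455", "b460", "b740",
               "d450", "d450", "d455", "d640", "b130", "b130", "b134",
               "b152", "d920", "d770", "e575", "e325", "e310"),
    target = c("b455", "b460", "b410", "d450", "b740", "d240", "d430",
               "d455", "d460", "d460", "d630", "d920", "d450", "b130",
               "b134", "d770", "d870", "e570", "e320", "e315"),
    weight = c(0.8, 0.7, 0.6, 0.8, 0.7, 0.6, 0.7,
               0.8, 0.6, 0.5, 0.7, 0.6, 0.5, 0.7,
               0.6, 0.7, 0.8, 0.7, 0.7, 0.6)
  )
}

#' Default synthetic emulation of the CIHD study cohort
#'
#' The study conditions this package emulates: 120 patients scored on the
#' 46-category CIHD core set, a sparse planted dependency structure
#' ([cihd_default_edges()]), structural noise SD 0.8, the default
#' right-skewed cut-points, and sparse "not specified"/"not applicable"
#' codes (3% / 2% of cells).
#'
#' @param n_patients cohort size (the study enrolled 120).
#' @param seed master seed.
#' @return a [synthetic_spec()].
#' @export
cihd_cohort_spec <- function(n_patients = 120L, seed = 1L) {
  synthetic_spec(n_patients, load_schema("cihd"), cihd_default_edges(),
                 noise_sd = 0.8, missing_rate_8 = 0.03,
                 missing_rate_9 = 0.02, seed = seed)
}

#' Write / read a synthetic spec as a YAML config
#'
#' Serialises everything but the schema object itself (the schema is stored
#' by its source name or as inline rows).
#'
#' @param spec a [synthetic_spec()].
#' @param path YAML file path.
#' @param schema schema to attach on read.
#' @return `write_synthetic_spec()` returns `path` invisibly;
#'   `read_synthetic_spec()` returns a [synthetic_spec()].
#' @export
write_synthetic_spec <- function(spec, path) {
  obj <- list(
    n_patients = spec$n_patients,
    noise_sd = spec$noise_sd,
    missing_rate_8 = spec$missing_rate_8,
    missing_rate_9 = spec$missing_rate_9,
    seed = spec$seed,
    thresholds = spec$thresholds,
    edges = lapply(seq_len(nrow(spec$edges)), function(i) {
      as.list(spec$edges[i, c("source", "target", "weight")])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path, schema) {
  obj <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(obj$edges, as.data.frame))
  synthetic_spec(obj$n_patients, schema, edges, noise_sd = obj$noise_sd,
                 thresholds = lapply(obj$thresholds, unlist),
                 missing_rate_8 = obj$missing_rate_8,
                 missing_rate_9 = obj$missing_rate_9, seed = obj$seed)
}
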