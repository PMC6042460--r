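#' Directed dependency graphs and their summaries
#'
#' The dependence-coefficient matrix is read as a directed weighted graph:
#' an edge `j -> i` exists whenever predictor `j` carries a nonzero
#' coefficient in the regression whose response is `i`, with that
#' coefficient as the edge weight. Out-degree of a node then counts how
#' often the category appears as a predictor of others -- the "frequency of
#' appearance" notion used to rank categories by influence.
#'
#' @name dependency-graph
NULL

#' Build the dependency graph of a dependence matrix
#'
#' @param D square numeric matrix, entry `(i, j)` = coefficient of predictor
#'   `j` for response `i` (rows and columns named by category code).
#' @param zero_tol entries with `|value| <= zero_tol` are treated as absent.
#' @param weight_cutoff optional additional magnitude cutoff: keep only
#'   edges with `|weight| >= weight_cutoff` (0 keeps every nonzero edge;
#'   useful for reporting on a thresholded graph).
#' @return list of class `dependency_graph`: `nodes` (all codes, including
#'   isolated ones), `edges` (data frame `source`, `target`, `weight` with
#'   source = predictor, target = response), `zero_tol`.
#' @examples
#' D <- matrix(c(0, 0, 0.5, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' build_graph(D)$edges   # single edge B -> A, weight 0.5
#' @export
build_graph <- function(D, zero_tol = 1e-8, weight_cutoff = 0) {
  stopifnot(nrow(D) == ncol(D))
  keep <- abs(D) > zero_tol & abs(D) >= weight_cutoff
  diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]  # by source code
  edges <- data.frame(source = colnames(D)[idx[, 2L]],
                      target = rownames(D)[idx[, 1L]],
                      weight = D[idx])
  structure(list(nodes = rownames(D), edges = edges, zero_tol = zero_tol),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("dependency graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges\n")
  invisible(x)
}

#' Out-degree of every node
#'
#' @param g a [build_graph()] result.
#' @return named integer vector over all nodes (isolated nodes get 0); its
#'   sum equals the number of edges.
#' @export
out_degrees <- function(g) {
  stopifnot(inherits(g, "dependency_graph"))
  deg <- table(factor(g$edges$source, levels = g$nodes))
  stats::setNames(as.integer(deg), g$nodes)
}

#' Count (and list) entries beyond a cutoff
#'
#' Counts the nonzero entries of a dependence matrix or sparse coefficient
#' table that satisfy `comparator` against `cutoff`, e.g. the published
#' "strong" (`> 0.75`) and "weak" (`< 0.25`) tallies.
#'
#' @param x square matrix (codes as dimnames) or data frame with columns
#'   `response_code`/`response`, `predictor_code`/`predictor`,
#'   `coefficient`.
#' @param comparator one of `">"`, `">="`, `"<"`, `"<="`.
#' @param cutoff numeric threshold.
#' @param zero_tol entries with `|value| <= zero_tol` are ignored.
#' @return list: `count` and `entries` (data frame `response`, `predictor`,
#'   `coefficient`).
#' @export
threshold_count <- function(x, comparator = ">", cutoff = 0.75,
                            zero_tol = 1e-8) {
  cmp <- match.fun(match.arg(comparator, c(">", ">=", "<", "<=")))
  tab <- .as_coef_table(x, zero_tol)
  hit <- cmp(tab$coefficient, cutoff)
  list(count = sum(hit), entries = tab[hit, , drop = FALSE])
}

# normalise matrix / sparse-table input to a response,predictor,coefficient
# data frame of nonzero off-diagonal entries, in row-major order
.as_coef_table <- function(x, zero_tol = 1e-8) {
  if (is.data.frame(x)) {
    nm <- names(x)
    resp <- x[[grep("^response", nm)[1L]]]
    pred <- x[[grep("^predictor", nm)[1L]]]
    tab <- data.frame(response = resp, predictor = pred,
                      coefficient = x$coefficient)
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    idx <- which(row(m) > 0, arr.ind = TRUE)  # all cells, row-major order
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    tab <- data.frame(response = rownames(m)[idx[, 1L]],
                      predictor = colnames(m)[idx[, 2L]],
                      coefficient = m[idx])
    tab <- tab[tab$response != tab$predictor, , drop = FALSE]
  }
  tab <- tab[abs(tab$coefficient) > zero_tol, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Extreme dependence coefficients
#'
#' Global maximum and minimum over the nonzero entries, with their
#' (response, predictor) labels; ties are all reported, first occurrence in
#' row-major order first.
#'
#' @inheritParams threshold_count
#' @return list with elements `max` and `min`, each a list `value` /
#'   `entries` (data frame of the tied cells).
#' @export
matrix_extremes <- function(x, zero_tol = 1e-8) {
  tab <- .as_coef_table(x, zero_tol)
  if (!nrow(tab)) stop("no nonzero entries", call. = FALSE)
  list(max = list(value = max(tab$coefficient),
                  entries = tab[tab$coefficient == max(tab$coefficient), ,
                                drop = FALSE]),
       min = list(value = min(tab$coefficient),
                  entries = tab[tab$coefficient == min(tab$coefficient), ,
                                drop = FALSE]))
}

#' Reciprocated (bidirectional) category pairs
#'
#' All unordered pairs `{a, b}` with both `D[a, b]` and `D[b, a]` nonzero --
#' length-2 bidirectional feedback loops.
#'
#' @param D square dependence matrix (codes as dimnames) or a sparse
#'   coefficient table (see [threshold_count()]).
#' @param zero_tol nonzero threshold.
#' @return data frame: `code_a`, `code_b` (a before b in row-major/schema
#'   order), `coef_a_on_b` (= `D[a, b]`), `coef_b_on_a` (= `D[b, a]`).
#' @export
bidirectional_pairs <- function(D, zero_tol = 1e-8) {
  tab <- .as_coef_table(D, zero_tol)
  key <- paste(tab$response, tab$predictor)
  rev_key <- paste(tab$predictor, tab$response)
  has_rev <- rev_key %in% key
  first <- has_rev & !duplicated(pmin(tab$response, tab$predictor) |>
                                   paste(pmax(tab$response, tab$predictor)))
  a <- tab$response[first]; b <- tab$predictor[first]
  data.frame(code_a = a, code_b = b,
             coef_a_on_b = tab$coefficient[first],
             coef_b_on_a = tab$coefficient[match(paste(b, a), key)])
}

#' Trace a category sequence through the dependence matrix
#'
#' Collects the coefficients along consecutive pairs of `codes` in the given
#' order (the forward trace) and along the reversed order (the reverse
#' trace); with `closed = TRUE` the sequence wraps around, as in a feedback
#' loop. The path is a *complete bidirectional feedback loop* iff every
#' coefficient in both traces is nonzero.
#'
#' @param D square dependence matrix.
#' @param codes character vector of category codes, length >= 2.
#' @param closed wrap around from the last code back to the first.
#' @param zero_tol nonzero threshold for the completeness flag.
#' @return list: `forward`, `reverse` (named coefficient vectors) and
#'   `complete_bidirectional` (logical).
#' @export
trace_path <- function(D, codes, closed = TRUE, zero_tol = 1e-8) {
  stopifnot(length(codes) >= 2L)
  unknown <- setdiff(codes, rownames(D))
  if (length(unknown)) {
    stop("unknown code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  steps <- function(s) {
    from <- s[-length(s)]; to <- s[-1L]
    if (closed) { from <- c(from, s[length(s)]); to <- c(to, s[1L]) }
    stats::setNames(D[cbind(from, to)], paste(from, to, sep = "->"))
  }
  fwd <- steps(codes)
  rev_ <- steps(rev(codes))
  list(forward = fwd, reverse = rev_,
       complete_bidirectional = all(abs(c(fwd, rev_)) > zero_tol))
}

#' Negative dependence coefficients
#'
#' All strictly negative entries with their labels: pairs where confinement
#' of the predictor goes with *enhancement* of the response.
#'
#' @inheritParams threshold_count
#' @return data frame `response`, `predictor`, `coefficient`.
#' @export
negative_edges <- function(x, zero_tol = 1e-8) {
  tab <- .as_coef_table(x, zero_tol)
  tab[tab$coefficient < 0, , drop = FALSE]
}

#' Exhaustive simple-cycle search up to a length cap
#'
#' Enumerates simple directed cycles of length 2..`max_len` in the graph and
#' flags, via [trace_path()], those that are complete bidirectional feedback
#' loops (every step nonzero in both traversal directions). Search is
#' restricted to short cycles because unbounded cycle enumeration is
#' exponential.
#'
#' @param D square dependence matrix.
#' @param zero_tol nonzero threshold.
#' @param weight_cutoff only edges with `|weight| >= weight_cutoff` seed the
#'   search (the completeness flag still uses the full matrix).
#' @param max_len maximum cycle length.
#' @return list of cycle reports: each has `nodes`, `forward`, `reverse`,
#'   `complete_bidirectional`. Cycles are canonicalised to start at their
#'   lexicographically smallest node.
#' @export
find_cycles <- function(D, zero_tol = 1e-8, weight_cutoff = 0, max_len = 5L) {
  g <- build_graph(D, zero_tol, weight_cutoff)
  adj <- split(g$edges$target, factor(g$edges$source, levels = g$nodes))
  cycles <- list()
  seen <- character(0)
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1L] && length(path) >= 2L) {
        rot <- which(path == min(path))[1L]
        canon <- if (rot > 1L) c(path[rot:length(path)], path[seq_len(rot - 1L)])
                 else path
        key <- paste(canon, collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- canon
        }
      } else if (!w %in% path && length(path) < max_len) {
        dfs(c(path, w))
      }
    }
  }
  for (v in g$nodes) dfs(v)
  lapply(cycles, function(cyc) {
    tr <- trace_path(D, cyc, closed = TRUE, zero_tol = zero_tol)
    c(list(nodes = cyc), tr)
  })
}

#' Convert a dependency graph to igraph
#'
#' Node attribute `out_degree`, edge attributes `weight` and `width` (the
#' absolute weight, the edge-thickness hint used in published diagrams).
#'
#' @param g a [build_graph()] result.
#' @return an [igraph::graph_from_data_frame()] object.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges, directed = TRUE,
    vertices = data.frame(name = g$nodes, out_degree = out_degrees(g)))
  igraph::E(ig)$width <- abs(igraph::E(ig)$weight)
  ig
}

#' Export a dependency graph to GraphML or DOT
#'
#' @param g a [build_graph()] result.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(g), path, format = format)
  invisible(path)
}
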