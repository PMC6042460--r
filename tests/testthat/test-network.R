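random_sparse_D <- function(p, seed, density = 0.3) {
  set.seed(seed)
  codes <- sprintf("d%03d", 100 + seq_len(p))
  D <- matrix(rnorm(p * p) * (runif(p * p) < density), p,
              dimnames = list(codes, codes))
  diag(D) <- 0
  D
}

test_that("graph construction follows the predictor -> response convention", {
  codes <- c("b130", "b134")
  D <- matrix(0, 2, 2, dimnames = list(codes, codes))
  g0 <- build_graph(D)
  expect_equal(length(g0$nodes), 2L)
  expect_equal(nrow(g0$edges), 0L)

  D["b130", "b134"] <- 0.5  # response b130, predictor b134
  g <- build_graph(D)
  expect_equal(g$edges$source, "b134")
  expect_equal(g$edges$target, "b130")
  expect_equal(g$edges$weight, 0.5)

  for (seed in 1:5) {
    D <- random_sparse_D(6, seed)
    expect_equal(nrow(build_graph(D)$edges), sum(abs(D) > 1e-8))
  }
})

test_that("out-degrees count outgoing edges and sum to the edge count", {
  codes <- c("d101", "d102", "d103")
  D <- matrix(0, 3, 3, dimnames = list(codes, codes))
  # edges A->B, A->C, B->C with A=d101 etc: source is the predictor column
  D["d102", "d101"] <- 1; D["d103", "d101"] <- 1; D["d103", "d102"] <- 1
  deg <- out_degrees(build_graph(D))
  expect_equal(deg, c(d101 = 2L, d102 = 1L, d103 = 0L))

  for (seed in 1:5) {
    g <- build_graph(random_sparse_D(7, 10 + seed))
    deg <- out_degrees(g)
    expect_equal(sum(deg), nrow(g$edges))
    ig_deg <- igraph::degree(as_igraph(g), mode = "out")
    expect_equal(deg[names(ig_deg)], ig_deg)
  }
})

test_that("threshold counting is monotone and partitions the nonzeros", {
  for (seed in 1:5) {
    D <- random_sparse_D(6, 20 + seed)
    nz <- sum(abs(D) > 1e-8)
    cuts <- sort(runif(4, -1, 1))
    counts <- vapply(cuts, function(ct) threshold_count(D, ">", ct)$count, 0L)
    expect_true(all(diff(counts) <= 0))
    ct <- cuts[2]
    expect_equal(threshold_count(D, ">", ct)$count +
                   threshold_count(D, "<=", ct)$count, nz)
  }
  D <- random_sparse_D(6, 1)
  expect_equal(threshold_count(D, ">", max(abs(D)) + 1)$count, 0L)
})

test_that("extremes report value, labels and all ties", {
  codes <- c("d101", "d102")
  D <- matrix(0, 2, 2, dimnames = list(codes, codes))
  D["d101", "d102"] <- 0.3
  ex <- matrix_extremes(D)
  expect_equal(ex$max$value, 0.3)
  expect_equal(ex$min$value, 0.3)
  expect_equal(ex$max$entries$response, "d101")
  expect_equal(ex$max$entries$predictor, "d102")
  expect_error(matrix_extremes(matrix(0, 2, 2)), "no nonzero")

  D["d102", "d101"] <- 0.3  # tie: both reported
  expect_equal(nrow(matrix_extremes(D)$max$entries), 2L)
})

test_that("bidirectional pairs are symmetric and permutation-invariant", {
  # strictly upper-triangular matrix has no reciprocated pair
  D <- random_sparse_D(6, 31)
  D[lower.tri(D)] <- 0
  expect_equal(nrow(bidirectional_pairs(D)), 0L)

  for (seed in 1:5) {
    D <- random_sparse_D(6, 40 + seed, density = 0.5)
    bp <- bidirectional_pairs(D)
    # brute force over unordered pairs
    expected <- 0L
    for (i in 1:5) for (j in (i + 1):6) {
      if (abs(D[i, j]) > 1e-8 && abs(D[j, i]) > 1e-8) expected <- expected + 1L
    }
    expect_equal(nrow(bp), expected)
    key <- function(tab) sort(paste(pmin(tab$code_a, tab$code_b),
                                    pmax(tab$code_a, tab$code_b)))
    perm <- sample(6)
    expect_equal(key(bidirectional_pairs(D[perm, perm])), key(bp))
  }
})

test_that("path tracing flags complete bidirectional loops", {
  codes <- sprintf("d%03d", 101:105)
  D <- matrix(0.2, 5, 5, dimnames = list(codes, codes))
  diag(D) <- 0
  tr <- trace_path(D, codes)
  expect_length(tr$forward, 5L)
  expect_length(tr$reverse, 5L)
  expect_true(tr$complete_bidirectional)

  D2 <- D
  D2["d101", "d102"] <- 0  # kills one step of the forward traversal
  expect_false(trace_path(D2, codes)$complete_bidirectional)
  expect_error(trace_path(D, c("d101", "zzz")), "unknown code")

  # brute-force agreement on random sparse matrices
  for (seed in 1:10) {
    D <- random_sparse_D(6, 50 + seed, density = 0.6)
    seqn <- sample(rownames(D), 4)
    tr <- trace_path(D, seqn)
    closed <- c(seqn, seqn[1])
    fwd <- mapply(function(a, b) D[a, b], head(closed, -1), closed[-1])
    rev_closed <- c(rev(seqn), seqn[length(seqn)])
    rev_ <- mapply(function(a, b) D[a, b], head(rev_closed, -1), rev_closed[-1])
    expect_equal(tr$complete_bidirectional, all(abs(c(fwd, rev_)) > 1e-8))
  }
})

test_that("negative edges are listed with labels", {
  D <- random_sparse_D(5, 61)
  neg <- negative_edges(D)
  expect_equal(nrow(neg), sum(D < 0))
  expect_true(all(neg$coefficient < 0))
  expect_equal(nrow(negative_edges(abs(D))), 0L)
})

test_that("cycle search finds planted short cycles", {
  codes <- c("d101", "d102", "d103", "d104")
  D <- matrix(0, 4, 4, dimnames = list(codes, codes))
  # directed 3-cycle d101 -> d102 -> d103 -> d101 (edge j->i is D[i,j])
  D["d102", "d101"] <- 0.5; D["d103", "d102"] <- 0.5; D["d101", "d103"] <- 0.5
  cyc <- find_cycles(D, max_len = 4)
  expect_length(cyc, 1L)
  expect_equal(cyc[[1]]$nodes[1], "d101")
  expect_false(cyc[[1]]$complete_bidirectional)  # reverse steps absent

  # make it reciprocal: now both traversals are complete
  D["d101", "d102"] <- 0.4; D["d102", "d103"] <- 0.4; D["d103", "d101"] <- 0.4
  cyc <- find_cycles(D, max_len = 4)
  expect_true(any(vapply(cyc, function(cc) cc$complete_bidirectional, TRUE)))
})

test_that("graph exports are readable by igraph", {
  g <- build_graph(random_sparse_D(6, 71))
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".dot")
  export_graph(g, f1, "graphml")
  export_graph(g, f2, "dot")
  back <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(igraph::vcount(back), length(g$nodes))
  expect_gt(file.size(f2), 0)
})
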