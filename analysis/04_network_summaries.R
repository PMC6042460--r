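#!/usr/bin/env Rscript
# Network summaries of the estimated dependence matrix: directed graph,
# out-degrees, strong (>= 0.75) / weak (<= 0.25) / negative coefficients,
# reciprocated pairs, short feedback loops, and graph exports. Finishes by
# scoring the estimate against the planted ground truth.

library(icfnet)

D <- read_dependence_matrix("results/dependence_matrix.csv")
g <- build_graph(D)
deg <- out_degrees(g)
write.csv(data.frame(code = names(deg), out_degree = deg),
          "results/out_degree.csv", row.names = FALSE, quote = FALSE)

cat("graph:", length(g$nodes), "nodes,", nrow(g$edges), "edges\n")
top <- sort(deg, decreasing = TRUE)[1:8]
cat("highest out-degrees:",
    paste(names(top), top, sep = ":", collapse = " "), "\n")

strong <- threshold_count(D, ">=", 0.75)
weak <- threshold_count(D, "<=", 0.25)
neg <- negative_edges(D)
write.csv(strong$entries, "results/strong_edges.csv", row.names = FALSE,
          quote = FALSE)
write.csv(weak$entries, "results/weak_edges.csv", row.names = FALSE,
          quote = FALSE)
write.csv(neg, "results/negative_edges.csv", row.names = FALSE, quote = FALSE)
ex <- matrix_extremes(D)
cat(sprintf("coefficients >= 0.75: %d; nonzero <= 0.25: %d; negative: %d\n",
            strong$count, weak$count, nrow(neg)))
cat(sprintf("extremes: max %.3f (%s <- %s), min %.3f (%s <- %s)\n",
            ex$max$value, ex$max$entries$response[1], ex$max$entries$predictor[1],
            ex$min$value, ex$min$entries$response[1], ex$min$entries$predictor[1]))

bip <- bidirectional_pairs(D)
write.csv(bip, "results/bidirectional_pairs.csv", row.names = FALSE,
          quote = FALSE)
loops <- find_cycles(D, weight_cutoff = 0.25, max_len = 5)
complete <- Filter(function(x) x$complete_bidirectional, loops)
cat("reciprocated pairs:", nrow(bip),
    "; cycles (len <= 5, |w| >= 0.25):", length(loops),
    "; complete bidirectional:", length(complete), "\n")
jsonlite::write_json(loops, "results/loops.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
export_graph(g, "results/graph.graphml", "graphml")
export_graph(g, "results/graph.dot", "dot")

truth <- read.csv("results/cohort_truth_edges.csv")
score <- recovery_f1(truth, D)
cat(sprintf("planted-structure recovery: F1 %.3f (precision %.3f, recall %.3f)\n",
            score$f1, score$precision, score$recall))
cat("wrote results/out_degree.csv, *_edges.csv, bidirectional_pairs.csv, loops.json, graph.{graphml,dot}\n")
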