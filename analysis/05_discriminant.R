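#!/usr/bin/env Rscript
# Stage 5 — exhaustive leave-one-out LDA search over territories.
#
# Evaluates all 24 single-territory models and all 276 territory pairs
# as linear discriminants of cluster membership, each validated by
# leave-one-out; reports the ranking and the confusion matrix of the
# best model.

suppressPackageStartupMessages(library(temporient))

cbf <- read_cbf_table("results/data/cbf.csv")
assign <- read.csv("results/clusters.csv")
labels <- setNames(assign$cluster, assign$participant_id)

m <- cbf_matrix(cbf)
m <- m[intersect(rownames(m), names(labels)), ]
search <- exhaustive_search(m, labels[rownames(m)], max_size = 2)

write.csv(search$ranking, "results/lda_ranking.csv", row.names = FALSE)
cat(sprintf("evaluated %d models (24 single + 276 pairs)\n",
            nrow(search$ranking)))
cat("top five models by LOO hit rate:\n")
print(head(search$ranking, 5), row.names = FALSE)

cat(sprintf("\nbest single territory: %s (hit rate %.3f)\n",
            paste(search$best_single$feature_set, collapse = " + "),
            search$best_single$hit_rate))
cat(sprintf("any pair beats the best single territory: %s\n",
            ifelse(search$pair_beats_single, "yes", "no")))
cat("\nconfusion matrix of the best model (rows true, columns predicted):\n")
print(search$best$confusion)
cat("per-class hit fractions:",
    paste(round(search$best$per_class_hit, 3), collapse = ", "), "\n")

conf <- as.data.frame.matrix(search$best$confusion)
write.csv(cbind(true_cluster = rownames(conf), conf),
          "results/best_confusion.csv", row.names = FALSE)
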