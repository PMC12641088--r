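#!/usr/bin/env Rscript
# Stage 2 — standard response and pivotal regression features.
#
# Confirms the reference ND standard response (ascending sentence order,
# pivot sentence No. 5 at score 5) and fits the constrained line
# y = k(x - 5) + 5 to every participant, yielding the (slope, d.c.)
# feature pair used by the clustering stage.

suppressPackageStartupMessages(library(temporient))
dir.create("results", showWarnings = FALSE)

responses <- read_response_table("results/data/responses.csv")
std <- standard_scores_nd()

cat("reference standard response (ascending):\n")
print(std, row.names = FALSE)

# sanity: the self-fit of the standard response is the identity line
self <- fit_pivotal(std$mean_score, std$mean_score)
cat(sprintf("self-fit of the standard response: slope %.3f, d.c. %.3f\n",
            self$slope, self$dc))

feats <- extract_features(responses, std)
write.csv(feats, "results/features.csv", row.names = FALSE)

cat(sprintf("features for %d participants (%d included for clustering)\n",
            nrow(feats), sum(feats$included)))
by_group <- aggregate(cbind(slope, dc) ~ group, data = feats[feats$included, ],
                      FUN = function(v) round(mean(v), 2))
cat("mean (slope, d.c.) by clinical group:\n")
print(by_group, row.names = FALSE)
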