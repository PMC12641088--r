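#!/usr/bin/env Rscript
# Stage 4 — Bonferroni-corrected ANOVA screen over the 24 CBF territories.
#
# One-way ANOVA of CBF across the fitted clusters in each arterial
# territory; a territory is significant at P < 0.05/24.

suppressPackageStartupMessages(library(temporient))

cbf <- read_cbf_table("results/data/cbf.csv")
assign <- read.csv("results/clusters.csv")
labels <- setNames(assign$cluster, assign$participant_id)

m <- cbf_matrix(cbf)
m <- m[intersect(rownames(m), names(labels)), ]
scr <- screen_regions(m, labels[rownames(m)], alpha = 0.05, m = 24)

write.csv(scr$table, "results/screen.csv", row.names = FALSE)
cat(sprintf("%d of 24 territories significant at P < 0.05/24:\n",
            length(scr$significant_regions)))
print(scr$table[scr$table$significant,
                c("region", "f", "df_between", "df_within", "p")],
      row.names = FALSE)

# pericallosal detail with Tukey pairwise comparisons
for (r in c("pericallosal_right", "pericallosal_left")) {
  a <- anova_oneway(m[, r], labels[rownames(m)])
  cat(sprintf("\n%s: F(%d, %d) = %.1f, P = %.2g; cluster means %s\n",
              r, a$df_between, a$df_within, a$f, a$p,
              paste(round(a$group_means, 1), collapse = " / ")))
  print(tukey_hsd(m[, r], labels[rownames(m)]), row.names = FALSE)
}
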