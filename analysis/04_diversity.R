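#!/usr/bin/env Rscript
# Observed functional diversity: per-site alpha metrics (CWM, FRic, FEve,
# FDis, Rao's Q, Simpson, redundancy) and per-pair convex-hull beta
# diversity decomposed into turnover and nestedness.

library(traitpair)

cm <- read.csv("results/traits/merged_community.csv", check.names = FALSE)
comm <- as.matrix(cm[, -1]); rownames(comm) <- cm$site
tr <- read.csv("results/traits/final_traits.csv", check.names = FALSE)
gm <- read.csv("results/data/trait_groups.csv")
pairs <- read.csv("results/data/pairs.csv")
A <- as.matrix(tr[, -1]); rownames(A) <- tr$taxon
keep <- colnames(comm)[colSums(comm) > 0]
traits <- normalize_fuzzy(trait_table(A[keep, ], as.character(gm$group),
                                      normalized = TRUE))
space <- build_functional_space(traits)

alpha <- alpha_diversity(comm[, keep], traits, space)
beta <- beta_diversity(comm[, keep], pairs, space)

dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)
write.csv(alpha$metrics, "results/diversity/alpha_metrics.csv", row.names = FALSE)
write.csv(data.frame(site = rownames(alpha$cwm), alpha$cwm, check.names = FALSE),
          "results/diversity/cwm.csv", row.names = FALSE)
write.csv(beta, "results/diversity/beta.csv", row.names = FALSE)

cat(sprintf("Alpha metrics for %d sites (undefined: %s).\n", nrow(alpha$metrics),
            paste(names(alpha$n_undefined), alpha$n_undefined,
                  sep = "=", collapse = ", ")))
cat(sprintf("Beta components for %d pairs, %d undefined; median beta_total %.3f.\n",
            nrow(beta), sum(beta$undefined),
            median(beta$beta_total, na.rm = TRUE)))
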