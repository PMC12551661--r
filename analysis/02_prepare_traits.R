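#!/usr/bin/env Rscript
# Trait preparation: normalise fuzzy scores to per-group relative
# frequencies, fill coding gaps by taxonomic aggregation, merge community
# taxa that collapse onto the same raised parent, and report coverage.

library(traitpair)

data <- read_dataset("results/data")
traits_n <- normalize_fuzzy(data$traits)
gf <- fill_gaps(traits_n, data$taxonomy, community_taxa = colnames(data$comm))
comm <- merge_by_mapping(data$comm, gf$mapping)

dir.create("results/traits", showWarnings = FALSE, recursive = TRUE)
write.csv(gf$coverage, "results/traits/coverage.csv", row.names = FALSE)
write.csv(gf$mapping, "results/traits/taxon_mapping.csv", row.names = FALSE)
write.csv(data.frame(taxon = rownames(gf$traits$affinities),
                     gf$traits$affinities, check.names = FALSE),
          "results/traits/final_traits.csv", row.names = FALSE)
write.csv(data.frame(site = rownames(comm), comm, check.names = FALSE),
          "results/traits/merged_community.csv", row.names = FALSE)

cat(sprintf("%d community taxa resolved to %d final taxa (%d dropped).\n",
            nrow(gf$mapping), gf$n_final, length(gf$dropped)))
print(gf$coverage)
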