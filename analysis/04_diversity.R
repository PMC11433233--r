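#!/usr/bin/env Rscript
# Stage 4: taxonomic decomposition of family diversity.
#
# Builds the GCF-by-genome incidence matrix, classifies every family by its
# taxonomic specificity (lowest rank whose single taxon holds all
# carriers), types each family by its modal member BGC type, crosses the
# two, summarizes per-phylum resources, and runs the rank-variance analysis
# that identifies the rank below which diversity is homogeneous.

suppressMessages(library(gcfdiversity))

ds <- read_dataset(file.path("results", "corpus"))
asg_tab <- readr::read_tsv(file.path("results", "gcf_assignments.tsv"),
                           col_types = "cid", progress = FALSE)
asg <- structure(list(threshold = NA_real_, assignment = asg_tab,
                      centroids = matrix(0,
                                         nrow = length(unique(asg_tab$gcf_id)),
                                         ncol = 1)),
                 class = "gcf_assignment")

m <- incidence(asg, ds)
sp <- specificity(m, ds$taxonomy)
readr::write_tsv(sp$classes, file.path("results", "specificity.tsv"),
                 progress = FALSE)
readr::write_tsv(sp$per_genome,
                 file.path("results", "specificity_per_genome.tsv"),
                 progress = FALSE)

types <- gcf_types(asg, ds)
tbr <- type_by_range_matrix(sp, types)
readr::write_tsv(tibble::as_tibble(tbr$counts, rownames = "class"),
                 file.path("results", "type_by_range.tsv"),
                 progress = FALSE)

ps <- phylum_summary(m, ds$taxonomy, ds$anchors, asg, ds)
readr::write_tsv(ps, file.path("results", "phylum_summary.tsv"),
                 progress = FALSE)

rv <- rank_variance(m, ds$taxonomy)
readr::write_tsv(rv$table, file.path("results", "rank_variance.tsv"),
                 progress = FALSE)

cat("specificity classes:\n")
print(table(sp$classes$class))
cat("\nper-phylum summary:\n")
print(as.data.frame(ps), digits = 3)
if (!is.null(rv$test)) {
  cat(sprintf("\nrank-variance Kruskal-Wallis: chi2 = %.2f, p = %.3g\n",
              rv$test$statistic, rv$test$p.value))
}
med <- tapply(rv$table$variance, as.character(rv$table$rank), stats::median)
cat("median richness variance by rank:\n")
print(round(med[order(match(names(med),
                            c("phylum", "class", "order", "family",
                              "genus")))], 2))
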