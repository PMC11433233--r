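#!/usr/bin/env Rscript
# Stage 7: summary-report arithmetic.
#
# Derives the headline ratio statistics twice: once from this run's own
# synthetic-corpus outputs, and once from the published corpus counts of
# the 11,598-genome fungal survey (known-family fraction, singleton share,
# top-genus share, virtual families, drug-census shares), each rendered at
# printed precision.

suppressMessages(library(gcfdiversity))

asg_tab <- readr::read_tsv(file.path("results", "gcf_assignments.tsv"),
                           col_types = "cid", progress = FALSE)
ann <- readr::read_tsv(file.path("results", "annotations.tsv"),
                       col_types = readr::cols(), progress = FALSE)
pg <- readr::read_tsv(file.path("results", "pgcf.tsv"),
                      col_types = readr::cols(), progress = FALSE)
sizes <- readr::read_tsv(file.path("results", "size_distribution.tsv"),
                         col_types = readr::cols(), progress = FALSE)

n_gcfs <- length(unique(asg_tab$gcf_id))
n_bgcs <- nrow(asg_tab)
top <- pg[order(-pg$pgcf), ][1, ]

own <- summary_report(list(
  known_gcfs = length(unique(ann$gcf_id)),
  total_gcfs = n_gcfs, total_bgcs = n_bgcs,
  singleton_gcf_fraction = sizes$n_gcf[sizes$bin == "=1"] / n_gcfs,
  genus_gcfs = top$s_obs, pgcf = top$pgcf, gcfs = top$s_obs))
cat("this run's corpus:\n")
print(as.data.frame(own), digits = 4)

published <- summary_report(list(
  known_gcfs = 165, total_gcfs = 26825, total_bgcs = 293926,
  singleton_gcf_fraction = 0.4994,
  genus_gcfs = 4130, pgcf = 6924, gcfs = 4130,
  group_gcfs = 11783, focal_hits = 417, total_hits = 874,
  genus_hit_counts = c(32, 13, 18, 14)))
cat("\npublished corpus counts:\n")
print(as.data.frame(published), digits = 4)

readr::write_tsv(own, file.path("results", "report_own_corpus.tsv"),
                 progress = FALSE)
readr::write_tsv(published,
                 file.path("results", "report_published_counts.tsv"),
                 progress = FALSE)
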