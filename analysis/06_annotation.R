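#!/usr/bin/env Rscript
# Stage 6: anchor-based annotation and the drug-similarity census.
#
# Links every family containing an anchored BGC to that anchor's compound
# structural cluster, annotating all member BGCs. Then builds drug-like
# query clusters from five anchored families (core genes = their heaviest
# domains) and screens the representative BGC of every family with the
# core-gene-required matcher; hits are expanded to whole families,
# re-clustered into a similarity network, and censused by genus.

suppressMessages(library(gcfdiversity))

ds <- read_dataset(file.path("results", "corpus"))
asg_tab <- readr::read_tsv(file.path("results", "gcf_assignments.tsv"),
                           col_types = "cid", progress = FALSE)
asg <- structure(list(threshold = NA_real_, assignment = asg_tab,
                      centroids = matrix(0,
                                         nrow = length(unique(asg_tab$gcf_id)),
                                         ncol = 1)),
                 class = "gcf_assignment")

linked <- link_anchors(asg, ds$anchors)
readr::write_tsv(linked$annotated, file.path("results", "annotations.tsv"),
                 progress = FALSE)
cat(sprintf("known families: %d (%.1f%% of %d GCFs); %d BGCs annotated\n",
            linked$n_known_gcfs,
            100 * linked$n_known_gcfs / length(unique(asg_tab$gcf_id)),
            length(unique(asg_tab$gcf_id)), linked$n_annotated_bgcs))

reps <- representatives(asg, seed = 42)

# synthetic drug-like queries built from five anchored BGCs: three genes
# of up to three domains each, the first two marked core
set.seed(42)
anchor_bgcs <- head(ds$anchors$bgc_id, 5)
queries <- list()
for (i in seq_along(anchor_bgcs)) {
  ord <- ds$bgcs$domain_order[[match(anchor_bgcs[i], ds$bgcs$bgc_id)]]
  chunks <- split(ord, ceiling(seq_along(ord) /
                                 max(1L, ceiling(length(ord) / 3))))
  genes <- lapply(seq_along(chunks), function(k) {
    list(domains = unname(chunks[[k]]), core = k <= 2)
  })
  qid <- paste0("drug_like_", i)
  queries[[qid]] <- query_cluster(qid, genes)
}

hits <- lapply(queries, function(q) {
  query_search(q, reps, asg, ds, min_gene_frac = 0.6)$hit_bgcs
})

pg <- readr::read_tsv(file.path("results", "pgcf.tsv"),
                      col_types = readr::cols(), progress = FALSE)
focal <- head(pg$genus[order(-pg$pgcf)], 10)
census <- drug_census(hits, ds, focal_genera = focal)
readr::write_tsv(census$per_query, file.path("results", "drug_census.tsv"),
                 progress = FALSE)
readr::write_tsv(census$by_genus,
                 file.path("results", "drug_census_by_genus.tsv"),
                 progress = FALSE)

all_hits <- unique(unlist(lapply(hits, function(h) h$bgc_id)))
cat(sprintf("drug-similar BGCs: %d total; %.1f%% in the top-10 pGCF genera\n",
            census$total$n_hits, census$total$focal_pct))
if (length(all_hits) >= 2) {
  net <- similarity_network(all_hits, ds, cutoff = 0.3)
  readr::write_tsv(net$edges, file.path("results", "network_edges.tsv"),
                   progress = FALSE)
  cat(sprintf("similarity network: %d nodes, %d edges, %d components\n",
              length(all_hits), nrow(net$edges),
              length(unique(net$components$component))))
}
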