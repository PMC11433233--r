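asg_of <- function(bgc_ids, gcf_ids) {
  structure(list(threshold = 0.5,
                 assignment = tibble::tibble(bgc_id = bgc_ids,
                                             gcf_id = gcf_ids,
                                             dist_to_centroid = 0),
                 centroids = matrix(0, nrow = length(unique(gcf_ids)),
                                    ncol = 1)),
            class = "gcf_assignment")
}

test_that("anchor links annotate whole families and flag conflicts", {
  asg <- asg_of(paste0("b", 1:7), c(1L, 1L, 1L, 1L, 1L, 2L, 3L))
  anchors <- tibble::tibble(bgc_id = "b1", compound_id = "c1",
                            np_cluster_id = "NPC1")
  out <- link_anchors(asg, anchors)
  expect_equal(out$n_known_gcfs, 1L)
  expect_equal(out$n_annotated_bgcs, 5L)  # whole family inherits
  expect_false(any(out$links$ambiguous))

  # conservation: annotated BGCs = sum of linked family sizes
  sizes <- table(asg$assignment$gcf_id)
  expect_equal(out$n_annotated_bgcs,
               sum(sizes[unique(out$links$gcf_id)]))

  out0 <- link_anchors(asg, anchors[0, ])
  expect_equal(out0$n_known_gcfs, 0L)
  expect_equal(nrow(out0$links), 0)

  two <- tibble::tibble(bgc_id = c("b1", "b2"),
                        compound_id = c("c1", "c2"),
                        np_cluster_id = c("NPC1", "NPC2"))
  out2 <- link_anchors(asg, two)
  expect_true(all(out2$links$ambiguous))
  expect_equal(out2$annotated$np_cluster_ids[1], "NPC1;NPC2")

  bad <- tibble::tibble(bgc_id = "zz", compound_id = "c", np_cluster_id = "n")
  expect_error(link_anchors(asg, bad), "unassigned")
})

test_that("representatives are seeded, member-valid and stable", {
  asg <- asg_of(paste0("b", 1:9), c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
  r1 <- representatives(asg, seed = 99)
  r2 <- representatives(asg, seed = 99)
  expect_identical(r1, r2)
  for (i in seq_len(nrow(r1))) {
    members <- asg$assignment$bgc_id[asg$assignment$gcf_id ==
                                       as.integer(r1$gcf_id[i])]
    expect_true(r1$bgc_id[i] %in% members)
  }
  solo <- asg_of("only", 1L)
  expect_equal(representatives(solo)$bgc_id, "only")
})

test_that("query search requires core genes and the gene fraction", {
  tax <- toy_taxonomy()
  bgcs <- tibble::tibble(
    bgc_id = c("t1", "t2", "t3"),
    genome_id = c("g1", "g2", "g4"),
    bgc_type = "NRPS", length_kb = 30,
    domains = list(c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1),
                   c(A = 1, B = 1, X = 1, Y = 1),
                   c(Q = 1, R = 1)),
    domain_order = list(c("A", "B", "C", "D", "E", "F"),
                        c("A", "B", "X", "Y"),
                        c("Q", "R")))
  ds <- new_dataset(tax, bgcs)
  asg <- asg_of(c("t1", "t2", "t3"), c(1L, 2L, 3L))
  reps <- representatives(asg)
  q <- query_cluster("drug", list(
    list(domains = c("A", "B"), core = TRUE),
    list(domains = c("C", "D"), core = TRUE),
    list(domains = c("E", "F"), core = FALSE)))

  hits <- query_search(q, reps, asg, ds, min_gene_frac = 0.6)
  # t1 matches everything; t2 lacks the C,D core gene; t3 lacks all
  expect_equal(hits$hit_reps$bgc_id, "t1")

  # 2 core genes matched out of 3 total genes: 2/3 >= 0.6 -> hit
  bgcs2 <- bgcs
  bgcs2$domains[[1]] <- c(A = 1, B = 1, C = 1, D = 1)
  bgcs2$domain_order[[1]] <- c("A", "B", "C", "D")
  ds2 <- new_dataset(tax, bgcs2)
  hits2 <- query_search(q, reps, asg, ds2, min_gene_frac = 0.6)
  expect_equal(hits2$hit_reps$bgc_id, "t1")
  expect_equal(hits2$hit_reps$matched_frac, 2 / 3)
  # ... but not with a stricter gene fraction
  hits3 <- query_search(q, reps, asg, ds2, min_gene_frac = 0.8)
  expect_equal(nrow(hits3$hit_reps), 0)

  expect_error(query_cluster("bad", list(list(domains = "A", core = FALSE))),
               "core")
})

test_that("every self-query hits its own representative", {
  gen <- generate_dataset(sim_config(seed = 67, n_genomes = 25,
                                     n_archetypes = 12))
  ds <- gen$dataset
  f <- featurize(ds$bgcs, ds$vocabulary)
  asg <- gcf_cluster(f, 0.4)
  reps <- representatives(asg, seed = 1)
  for (i in head(seq_len(nrow(reps)), 5)) {
    ord <- ds$bgcs$domain_order[[match(reps$bgc_id[i], ds$bgcs$bgc_id)]]
    # one core gene per 3-domain chunk of the representative itself
    chunks <- split(ord, ceiling(seq_along(ord) / 3))
    q <- query_cluster(paste0("self", i),
                       lapply(chunks, function(d)
                         list(domains = unname(d), core = TRUE)))
    hits <- query_search(q, reps, asg, ds, min_gene_frac = 1)
    expect_true(reps$bgc_id[i] %in% hits$hit_reps$bgc_id)
    expect_true(reps$bgc_id[i] %in% hits$hit_bgcs$bgc_id)
  }
})

test_that("BGC similarity combines Jaccard and adjacency as specified", {
  expect_equal(bgc_similarity(c("A", "B", "C"), c("A", "B", "C")), 1.0)
  expect_equal(bgc_similarity(c("A", "B"), c("X", "Y")), 0.0)
  # hand-evaluated: Jaccard 2/4, adjacency 1/3
  expect_equal(bgc_similarity(c("A", "B", "C"), c("A", "B", "D")),
               0.5 * (2 / 4) + 0.5 * (1 / 3))
  # both shorter than 2 domains: adjacency contributes 0
  expect_equal(bgc_similarity("A", "A"), 0.5)
  # symmetry and bounds on random orders
  set.seed(71)
  for (i in 1:20) {
    a <- sample(LETTERS[1:8], sample(1:6, 1), replace = TRUE)
    b <- sample(LETTERS[1:8], sample(1:6, 1), replace = TRUE)
    s1 <- bgc_similarity(a, b); s2 <- bgc_similarity(b, a)
    expect_equal(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
})

test_that("the similarity network respects the cutoff and components", {
  tax <- toy_taxonomy()
  bgcs <- tibble::tibble(
    bgc_id = paste0("n", 1:4),
    genome_id = c("g1", "g2", "g4", "g5"),
    bgc_type = "T1PKS", length_kb = 10,
    domains = list(c(A = 1, B = 1), c(A = 1, B = 1),
                   c(C = 1, D = 1), c(C = 1, E = 1)),
    domain_order = list(c("A", "B"), c("A", "B"),
                        c("C", "D"), c("C", "E")))
  ds <- new_dataset(tax, bgcs)
  net <- similarity_network(paste0("n", 1:4), ds, cutoff = 0.5)
  # n1-n2 identical (w=1); n3-n4 share C only (w=0.25*... below 0.5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$source, net$edges$target)), c("n1", "n2"))
  expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 1))
  comp <- net$components
  expect_equal(length(unique(comp$component)), 3)
  # cutoff 0 joins any pair with an edge entry -> one component over the
  # connected support
  net0 <- similarity_network(paste0("n", 1:4), ds, cutoff = 0)
  expect_equal(length(unique(net0$components$component)), 1)
})

test_that("drug census aggregates per-genus hits and focal shares", {
  gen <- generate_dataset(sim_config(seed = 73, n_genomes = 40,
                                     n_archetypes = 15))
  ds <- gen$dataset
  hits <- list(drugA = tibble::tibble(bgc_id = ds$bgcs$bgc_id[1:10]),
               drugB = tibble::tibble(bgc_id = character()))
  genome <- ds$bgcs$genome_id[1:10]
  genera <- ds$taxonomy$genus[match(genome, ds$taxonomy$genome_id)]
  focal <- unique(genera)[1]
  cen <- drug_census(hits, ds, focal_genera = focal)
  expect_equal(cen$per_query$n_hits, c(10L, 0L))
  expect_equal(cen$per_query$focal_hits[1], sum(genera == focal))
  expect_equal(cen$total$n_hits, 10L)
  expect_equal(sum(cen$by_genus$n_hits), 10L)
  expect_equal(cen$per_query$focal_pct[1],
               100 * sum(genera == focal) / 10)
})
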