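make_assignment <- function(bgc_ids, gcf_ids) {
  structure(list(threshold = 0.5,
                 assignment = tibble::tibble(bgc_id = bgc_ids,
                                             gcf_id = gcf_ids,
                                             dist_to_centroid = 0),
                 centroids = matrix(0, nrow = length(unique(gcf_ids)),
                                    ncol = 1)),
            class = "gcf_assignment")
}

test_that("incidence is boolean, idempotent and covers empty genomes", {
  ds <- toy_dataset()
  # b1,b2 (g1,g2) in family 1; the rest singletons; no BGC references g3
  bgcs2 <- ds$bgcs[ds$bgcs$genome_id != "g3", ]
  ds2 <- new_dataset(ds$taxonomy, bgcs2,
                     ds$anchors[ds$anchors$bgc_id %in% bgcs2$bgc_id, ])
  asg <- make_assignment(bgcs2$bgc_id, c(1L, 1L, 2L, 3L, 4L))
  m <- incidence(asg, ds2)
  expect_true(m["1", "g1"] && m["1", "g2"])
  expect_false(m["1", "g3"])
  expect_equal(sum(m[, "g3"]), 0)

  # two BGCs of one family in the same genome -> one TRUE cell
  ds3 <- new_dataset(ds$taxonomy,
                     dplyr::mutate(ds$bgcs, genome_id = "g1"), NULL)
  asg3 <- make_assignment(ds3$bgcs$bgc_id, rep(1L, 6))
  m3 <- incidence(asg3, ds3)
  expect_equal(sum(m3), 1)
})

test_that("specificity classes follow the lowest shared rank", {
  tax <- toy_taxonomy()
  m <- matrix(FALSE, nrow = 4, ncol = 6,
              dimnames = list(paste0("f", 1:4), tax$genome_id))
  m["f1", c("g1", "g2")] <- TRUE   # same species -> species-specific
  m["f2", c("g1", "g3")] <- TRUE   # two species, one genus -> genus-specific
  m["f3", c("g1", "g4")] <- TRUE   # two classes, one phylum -> phylum-specific
  m["f4", c("g1", "g5")] <- TRUE   # two phyla -> multi-phyla
  sp <- specificity(m, tax)
  cls <- setNames(as.character(sp$classes$class), sp$classes$gcf_id)
  expect_equal(cls[["f1"]], "species-specific")
  expect_equal(cls[["f2"]], "genus-specific")
  expect_equal(cls[["f3"]], "phylum-specific")
  expect_equal(cls[["f4"]], "multi-phyla")
})

test_that("per-genome class counts sum to genome richness", {
  set.seed(11)
  for (i in 1:5) {
    gen <- generate_dataset(sim_config(seed = i, n_genomes = 30,
                                       n_archetypes = 20))
    f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
    asg <- gcf_cluster(f, 0.4)
    m <- incidence(asg, gen$dataset)
    sp <- specificity(m, gen$dataset$taxonomy)
    per <- tapply(sp$per_genome$n_gcf, sp$per_genome$genome_id, sum)
    rich <- colSums(m)
    expect_equal(as.integer(per[names(rich)]), unname(as.integer(rich)))
  }
})

test_that("specificity agrees with the brute-force lowest-rank scan", {
  set.seed(19)
  for (i in 1:5) {
    gen <- generate_dataset(sim_config(seed = 100 + i, n_genomes = 40,
                                       n_archetypes = 25))
    f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
    asg <- gcf_cluster(f, 0.4)
    m <- incidence(asg, gen$dataset)
    sp <- specificity(m, gen$dataset$taxonomy)
    expect_equal(as.character(sp$classes$class),
                 oracle_specificity(m, gen$dataset$taxonomy))
  }
})

test_that("adding a carrier can only widen the specificity class", {
  tax <- toy_taxonomy()
  lvl <- c("species-specific", "genus-specific", "family-specific",
           "order-specific", "class-specific", "phylum-specific",
           "multi-phyla")
  set.seed(5)
  for (rep in 1:20) {
    order_in <- sample(tax$genome_id)
    prev <- 1L
    for (k in seq_along(order_in)) {
      m <- matrix(FALSE, nrow = 1, ncol = 6,
                  dimnames = list("f1", tax$genome_id))
      m[1, order_in[seq_len(k)]] <- TRUE
      cls <- as.character(specificity(m, tax)$classes$class)
      cur <- match(cls, lvl)
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("GCF types take the modal member type with lexicographic ties", {
  ds <- toy_dataset()
  asg <- make_assignment(ds$bgcs$bgc_id, c(1L, 1L, 1L, 2L, 2L, 3L))
  ty <- gcf_types(asg, ds)
  tv <- setNames(ty$bgc_type, ty$gcf_id)
  expect_equal(tv[["1"]], "T1PKS")      # T1PKS,T1PKS,NRPS -> majority
  expect_equal(tv[["2"]], "NRPS")       # terpene vs NRPS tie -> lexicographic
  expect_equal(tv[["3"]], "other")      # singleton
})

test_that("type-by-range table conserves class totals", {
  gen <- generate_dataset(sim_config(seed = 37, n_genomes = 40,
                                     n_archetypes = 25))
  f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
  asg <- gcf_cluster(f, 0.4)
  m <- incidence(asg, gen$dataset)
  sp <- specificity(m, gen$dataset$taxonomy)
  ty <- gcf_types(asg, gen$dataset)
  tbr <- type_by_range_matrix(sp, ty)
  class_totals <- table(sp$classes$class)
  expect_equal(unname(rowSums(tbr$counts)),
               as.integer(class_totals[rownames(tbr$counts)]))
  expect_equal(sum(tbr$counts), nrow(sp$classes))
  nonzero <- rowSums(tbr$counts) > 0
  expect_true(all(abs(rowSums(tbr$percent[nonzero, , drop = FALSE]) - 100)
                  < 1e-9))
})

test_that("rank variance matches closed forms and flags homogeneity", {
  tax <- toy_taxonomy()
  # three genomes in GenA over two species with richness 2 vs 4
  m <- matrix(FALSE, nrow = 6, ncol = 6,
              dimnames = list(paste0("f", 1:6), tax$genome_id))
  m[c("f1", "f2"), "g1"] <- TRUE               # GenA sp1 richness 2
  m[c("f3", "f4", "f5", "f6"), "g3"] <- TRUE   # GenA sp2 richness 4
  rv <- rank_variance(m, tax)
  genus_rows <- rv$table[rv$table$rank == "genus", ]
  gA <- genus_rows[genus_rows$parent == "GenA", ]
  expect_equal(gA$variance, var(c(2, 4)))  # sample variance 2
  # equal richness across children -> zero variance
  m2 <- m
  m2[c("f3", "f4"), "g3"] <- c(TRUE, TRUE)
  m2[c("f5", "f6"), "g3"] <- FALSE
  rv2 <- rank_variance(m2, tax)
  gA2 <- rv2$table[rv2$table$rank == "genus" & rv2$table$parent == "GenA", ]
  expect_equal(gA2$variance, 0)
})

test_that("genus-homogeneous richness pushes genus variance below family", {
  # genomes of the same genus share their families; different genera in a
  # family differ strongly -> variance across species (genus rank) ~ 0,
  # variance across genera (family rank) large
  gv <- c(); fv <- c()
  for (i in 1:20) {
    gen <- generate_dataset(sim_config(seed = 200 + i, n_genomes = 60,
                                       n_archetypes = 30,
                                       singleton_fraction = 0,
                                       occupancy_range = c(0.9, 1)))
    f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
    asg <- gcf_cluster(f, 0.4)
    m <- incidence(asg, gen$dataset)
    rv <- rank_variance(m, gen$dataset$taxonomy)
    gv <- c(gv, rv$table$variance[rv$table$rank == "genus"])
    fv <- c(fv, rv$table$variance[rv$table$rank == "family"])
  }
  expect_lte(stats::median(gv), stats::median(fv))
  w <- suppressWarnings(stats::wilcox.test(gv, fv, alternative = "less"))
  expect_lt(w$p.value, 0.05)
})

test_that("phylum summary reports means, anchors and BGC counts", {
  ds <- toy_dataset()
  # one phylum view: g1 carries 3 families, g2 carries 5
  tax1 <- ds$taxonomy[1:2, ]
  m <- matrix(FALSE, nrow = 6, ncol = 2,
              dimnames = list(paste0("f", 1:6), c("g1", "g2")))
  m[1:3, "g1"] <- TRUE
  m[c(1:4, 6), "g2"] <- TRUE
  asg <- make_assignment(paste0("b", 1:6), 1:6)
  ps <- phylum_summary(m, tax1, ds$anchors[0, ], asg)
  expect_equal(ps$gcfs_per_genome, 4.0)
  expect_equal(ps$n_known_gcfs, 0L)
  expect_equal(ps$known_pct, 0)

  gen <- generate_dataset(sim_config(seed = 43, n_genomes = 40,
                                     n_archetypes = 20))
  f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
  asg2 <- gcf_cluster(f, 0.4)
  m2 <- incidence(asg2, gen$dataset)
  ps2 <- phylum_summary(m2, gen$dataset$taxonomy, gen$dataset$anchors,
                        asg2, gen$dataset)
  expect_equal(sum(ps2$n_genomes), nrow(gen$dataset$taxonomy))
  expect_equal(sum(ps2$n_bgcs), nrow(gen$dataset$bgcs))
  # per-phylum distinct families cover the kingdom total (shared counted
  # once in the union)
  union_gcfs <- sum(rowSums(m2) > 0)
  expect_gte(sum(ps2$n_gcfs), union_gcfs)
})
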