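# Independent oracle implementations used to cross-check the package.
# These deliberately take a different computational route from the code
# under test (explicit loops, base-2 logs, from-scratch recomputation).

# V-measure via explicit probability loops in base-2 logs
oracle_vscore <- function(true_labels, cluster_labels) {
  n <- length(true_labels)
  ts <- unique(true_labels); cs <- unique(cluster_labels)
  h_t <- 0
  for (t in ts) {
    p <- sum(true_labels == t) / n
    h_t <- h_t - p * log2(p)
  }
  h_c <- 0
  for (k in cs) {
    p <- sum(cluster_labels == k) / n
    h_c <- h_c - p * log2(p)
  }
  h_tc <- 0  # H(true | cluster)
  for (k in cs) {
    in_k <- cluster_labels == k
    for (t in ts) {
      p_joint <- sum(in_k & true_labels == t) / n
      if (p_joint > 0) {
        p_cond <- p_joint / (sum(in_k) / n)
        h_tc <- h_tc - p_joint * log2(p_cond)
      }
    }
  }
  h_ct <- 0  # H(cluster | true)
  for (t in ts) {
    in_t <- true_labels == t
    for (k in cs) {
      p_joint <- sum(in_t & cluster_labels == k) / n
      if (p_joint > 0) {
        p_cond <- p_joint / (sum(in_t) / n)
        h_ct <- h_ct - p_joint * log2(p_cond)
      }
    }
  }
  h <- if (h_t == 0) 1 else 1 - h_tc / h_t
  cm <- if (h_c == 0) 1 else 1 - h_ct / h_c
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  c(homogeneity = h, completeness = cm, v = v)
}

# single-pass threshold clustering, recomputing centroids from scratch
oracle_pass1 <- function(features, t_clust) {
  members <- list()
  assign <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    v <- features[i, ]
    best <- 0L; best_d <- Inf
    for (j in seq_along(members)) {
      cen <- colMeans(features[members[[j]], , drop = FALSE])
      d <- sqrt(sum((v - cen)^2))
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (best > 0L && best_d <= t_clust) {
      members[[best]] <- c(members[[best]], i)
      assign[i] <- best
    } else {
      members[[length(members) + 1L]] <- i
      assign[i] <- length(members)
    }
  }
  assign
}

# expected rarefied richness by exhaustive enumeration of unit subsets
oracle_rarefy_exhaustive <- function(mat, t) {
  units <- colnames(mat)
  subsets <- utils::combn(units, t, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    sum(rowSums(mat[, s, drop = FALSE]) > 0)
  }, numeric(1)))
}

# lowest-common-rank specificity by direct scan over rank columns
oracle_specificity <- function(mat, taxonomy) {
  classes <- c("species-specific", "genus-specific", "family-specific",
               "order-specific", "class-specific", "phylum-specific")
  ranks <- c("species", "genus", "family", "order", "class", "phylum")
  out <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    carriers <- colnames(mat)[mat[i, ]]
    rows <- taxonomy[taxonomy$genome_id %in% carriers, ]
    found <- "multi-phyla"
    for (k in seq_along(ranks)) {
      # shared taxon at this rank AND at every rank above it
      above <- ranks[k:length(ranks)]
      keys <- apply(rows[, rev(above), drop = FALSE], 1, paste,
                    collapse = "|")
      if (length(unique(keys)) == 1L) { found <- classes[k]; break }
    }
    out[i] <- found
  }
  out
}

# small handcrafted taxonomy: 2 phyla, nested names
toy_taxonomy <- function() {
  tibble::tibble(
    genome_id = paste0("g", 1:6),
    phylum  = c("P1", "P1", "P1", "P1", "P2", "P2"),
    class   = c("P1C1", "P1C1", "P1C1", "P1C2", "P2C1", "P2C1"),
    order   = c("P1C1O1", "P1C1O1", "P1C1O1", "P1C2O1", "P2C1O1", "P2C1O1"),
    family  = c("P1C1O1F1", "P1C1O1F1", "P1C1O1F1", "P1C2O1F1",
                "P2C1O1F1", "P2C1O1F1"),
    genus   = c("GenA", "GenA", "GenA", "GenB", "GenC", "GenC"),
    species = c("GenA sp1", "GenA sp1", "GenA sp2", "GenB sp1",
                "GenC sp1", "GenC sp2"),
    organism = paste0("org", 1:6))
}

toy_bgcs <- function() {
  tibble::tibble(
    bgc_id = paste0("b", 1:6),
    genome_id = paste0("g", 1:6),
    bgc_type = c("T1PKS", "T1PKS", "NRPS", "terpene", "NRPS", "other"),
    length_kb = c(10, 20, 30, 40, 50, 60),
    domains = list(c(d1 = 3, d2 = 4), c(d1 = 3, d2 = 4), c(d3 = 1),
                   c(d4 = 2, d5 = 2), c(d3 = 1, d5 = 1), c(d6 = 9)),
    domain_order = list(c("d1", "d2"), c("d1", "d2"), "d3",
                        c("d4", "d5"), c("d3", "d5"), "d6"))
}

toy_dataset <- function() {
  anchors <- tibble::tibble(bgc_id = c("b1", "b4"),
                            compound_id = c("c1", "c2"),
                            np_cluster_id = c("NPC1", "NPC2"))
  new_dataset(toy_taxonomy(), toy_bgcs(), anchors)
}

# random incidence matrix for property tests
random_incidence <- function(n_gcf, n_genomes, p = 0.3) {
  m <- matrix(stats::runif(n_gcf * n_genomes) < p, nrow = n_gcf,
              dimnames = list(paste0("f", seq_len(n_gcf)),
                              paste0("g", seq_len(n_genomes))))
  # every family must have at least one carrier
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_genomes, sum(empty), replace = TRUE))] <- TRUE
  m
}
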