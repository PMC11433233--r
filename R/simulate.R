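#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a seven-rank fungal-style taxonomy, GCF archetypes with a home
#' taxon and rank that control their taxonomic breadth, per-BGC noisy domain
#' vectors around the archetype profile, a fraction of singleton archetypes
#' (families observed exactly once kingdom-wide), BGC type labels, BGC
#' lengths, and an anchored subset linking BGCs to compound structural
#' families.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_phyla number of phyla.
#' @param fanout children per internal taxon at each rank below phylum
#'   (class, order, family, genus, species); scalar or length-5 vector.
#' @param n_genomes number of genomes, assigned to species uniformly at
#'   random.
#' @param vocab_size number of domain names in the vocabulary.
#' @param n_archetypes number of GCF archetypes (true families).
#' @param singleton_fraction probability an archetype is a singleton
#'   (contributes exactly one BGC kingdom-wide).
#' @param noise_sd standard deviation of the Gaussian noise added to an
#'   archetype profile for each BGC (profile weights are on a 20-100 scale).
#' @param anchor_fraction fraction of archetypes whose families receive one
#'   anchored (known-compound) BGC.
#' @param length_range_kb BGC length range in kb; lengths drawn uniformly.
#' @param occupancy_range range of the per-archetype occupancy probability
#'   (probability a genome under the home taxon carries the family).
#' @return a `gcf_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_phyla = 2L,
                       fanout = 2L,
                       n_genomes = 100L,
                       vocab_size = 200L,
                       n_archetypes = 60L,
                       singleton_fraction = 0.2,
                       noise_sd = 1.0,
                       anchor_fraction = 0.25,
                       length_range_kb = c(0.8, 242),
                       occupancy_range = c(0.5, 0.9)) {
  if (length(fanout) == 1L) fanout <- rep(as.integer(fanout), 5L)
  stopifnot(length(fanout) == 5L, all(fanout >= 1L),
            n_phyla >= 1L, n_genomes >= 1L, vocab_size >= 1L,
            n_archetypes >= 1L,
            singleton_fraction >= 0, singleton_fraction <= 1,
            noise_sd >= 0,
            anchor_fraction >= 0, anchor_fraction <= 1,
            length(length_range_kb) == 2L, all(length_range_kb > 0),
            length(occupancy_range) == 2L)
  structure(list(seed = as.integer(seed), n_phyla = as.integer(n_phyla),
                 fanout = fanout, n_genomes = as.integer(n_genomes),
                 vocab_size = as.integer(vocab_size),
                 n_archetypes = as.integer(n_archetypes),
                 singleton_fraction = singleton_fraction,
                 noise_sd = noise_sd, anchor_fraction = anchor_fraction,
                 length_range_kb = length_range_kb,
                 occupancy_range = occupancy_range),
            class = "gcf_sim_config")
}

# Deterministic balanced taxon tree: names encode the full path so every
# taxon name is globally unique and parent-child consistency is by
# construction.
build_taxon_tree <- function(config) {
  prefixes <- c("p", "c", "o", "f", "g", "s")
  lineages <- lapply(seq_len(config$n_phyla),
                     function(i) sprintf("p%02d", i))
  for (k in seq_len(5L)) {
    fan <- config$fanout[k]
    lineages <- unlist(lapply(lineages, function(parent) {
      lapply(seq_len(fan), function(j) {
        c(parent, sprintf("%s_%s%02d", parent[length(parent)],
                          prefixes[k + 1L], j))
      })
    }), recursive = FALSE)
  }
  # rows: one species per row, columns phylum..species
  mat <- do.call(rbind, lineages)
  colnames(mat) <- RANKS[1:6]
  mat
}

#' Generate a synthetic genome taxonomy
#'
#' Builds a balanced taxon tree with the configured fan-outs and assigns
#' `n_genomes` genomes to species uniformly at random. The `organism` rank is
#' the species name with a strain suffix. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return tibble with `genome_id` and the seven rank columns.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "gcf_sim_config"))
  set.seed(config$seed)
  tree <- build_taxon_tree(config)
  idx <- sample.int(nrow(tree), config$n_genomes, replace = TRUE)
  tab <- tibble::as_tibble(tree[idx, , drop = FALSE])
  tab$organism <- sprintf("%s_t%03d", tab$species, seq_len(config$n_genomes))
  tab <- tibble::add_column(tab,
    genome_id = sprintf("G%05d", seq_len(config$n_genomes)), .before = 1)
  tab
}

draw_archetypes <- function(config, tree) {
  n <- config$n_archetypes
  vocab <- sprintf("PF%05d", seq_len(config$vocab_size))
  # NP structural families: archetypes sharing a profile backbone (a common
  # sparse support with shared weights) belong to the same family of
  # similar compounds. The backbone carries most of the vector mass so that
  # same-family archetypes sit close together (distance ~0.6 after
  # normalization) while different families are nearly orthogonal (~1.4);
  # the per-archetype extra domains keep archetypes of one family distinct.
  n_backbones <- max(1L, ceiling(n / 3))
  backbone_size <- max(4L, round(0.04 * config$vocab_size))
  backbones <- lapply(seq_len(n_backbones), function(i) {
    setNames(runif(backbone_size, 40, 80), sample(vocab, backbone_size))
  })

  ranks_pool <- c(RANKS[1:6], "multi-phyla")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    b <- sample.int(n_backbones, 1L)
    extra <- sample(setdiff(vocab, names(backbones[[b]])),
                    2L + sample.int(8L, 1L))
    profile <- c(backbones[[b]],
                 setNames(runif(length(extra), 25, 50), extra))
    home_rank <- sample(ranks_pool, 1L)
    home_taxon <- if (home_rank == "multi-phyla") {
      NA_character_
    } else {
      sample(unique(tree[, home_rank]), 1L)
    }
    recs[[i]] <- tibble::tibble(
      archetype_id = sprintf("A%04d", i),
      np_family_id = sprintf("NPC%03d", b),
      home_rank = home_rank,
      home_taxon = home_taxon,
      bgc_type = sample(BGC_TYPES, 1L,
                        prob = c(0.35, 0.12, 0.14, 0.12, 0.10, 0.09, 0.08)),
      singleton = runif(1) < config$singleton_fraction,
      occupancy_prob = runif(1, config$occupancy_range[1],
                             config$occupancy_range[2]),
      profile = list(profile)
    )
  }
  dplyr::bind_rows(recs)
}

noisy_vector <- function(profile, vocab, noise_sd, max_retry = 10L) {
  dense <- setNames(numeric(length(vocab)), vocab)
  dense[names(profile)] <- profile
  for (try in seq_len(max_retry)) {
    v <- dense + rnorm(length(dense), sd = noise_sd)
    v[v < 0] <- 0
    if (any(v > 0)) return(v[v > 0])
  }
  stop("noise produced an all-zero domain vector after ", max_retry,
       " retries")
}

#' Generate a synthetic dataset with ground truth
#'
#' Each genome receives BGCs from the archetypes whose home taxon lies on its
#' lineage (or from any archetype for `multi-phyla` homes), sampled with the
#' archetype's occupancy probability. A BGC's domain vector is the archetype
#' profile plus independent Gaussian noise truncated at zero. Singleton
#' archetypes contribute exactly one BGC kingdom-wide. A fraction of the
#' realized archetypes yields one anchored BGC each, whose `np_cluster_id` is
#' the archetype's structural-family label.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a `gcf_dataset`) and `truth` (a list
#'   with `bgc_archetype` — tibble mapping `bgc_id` to `archetype_id` — the
#'   `archetypes` table, and `genus_richness` — per-genus true richness,
#'   counting the archetypes whose taxonomic home makes them accessible to
#'   the genus (`richness`) and the distinct structural families they span
#'   (`richness_np`)).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "gcf_sim_config"))
  taxonomy <- generate_taxonomy(config)
  set.seed(config$seed + 1L)
  tree <- build_taxon_tree(config)
  arch <- draw_archetypes(config, tree)
  vocab <- sprintf("PF%05d", seq_len(config$vocab_size))

  # eligible genomes per archetype
  eligible <- lapply(seq_len(nrow(arch)), function(i) {
    hr <- arch$home_rank[i]
    if (hr == "multi-phyla") taxonomy$genome_id
    else taxonomy$genome_id[taxonomy[[hr]] == arch$home_taxon[i]]
  })

  set.seed(config$seed + 2L)
  rows <- list()
  bgc_n <- 0L
  for (i in seq_len(nrow(arch))) {
    elig <- eligible[[i]]
    if (length(elig) == 0) next
    if (arch$singleton[i]) {
      carriers <- sample(elig, 1L)
    } else {
      take <- runif(length(elig)) < arch$occupancy_prob[i]
      carriers <- elig[take]
      if (length(carriers) == 0) carriers <- sample(elig, 1L)
    }
    for (g in carriers) {
      bgc_n <- bgc_n + 1L
      dom <- noisy_vector(arch$profile[[i]], vocab, config$noise_sd)
      rows[[bgc_n]] <- tibble::tibble(
        bgc_id = sprintf("BGC%06d", bgc_n),
        genome_id = g,
        bgc_type = arch$bgc_type[i],
        length_kb = runif(1, config$length_range_kb[1],
                          config$length_range_kb[2]),
        domains = list(dom),
        # the order of domains along the cluster is the archetype's
        # support; truncated noise only perturbs the weight vector
        domain_order = list(names(arch$profile[[i]])),
        archetype_id = arch$archetype_id[i])
    }
  }
  if (bgc_n == 0L) stop("configuration produced no BGCs")
  bgcs <- dplyr::bind_rows(rows)

  # anchors: one member BGC for a fraction of the realized archetypes
  set.seed(config$seed + 3L)
  realized <- unique(bgcs$archetype_id)
  n_anchor <- round(config$anchor_fraction * length(realized))
  anchors <- tibble::tibble(bgc_id = character(), compound_id = character(),
                            np_cluster_id = character())
  if (n_anchor > 0) {
    picked <- sample(realized, n_anchor)
    anchor_rows <- lapply(picked, function(a) {
      members <- bgcs$bgc_id[bgcs$archetype_id == a]
      tibble::tibble(
        bgc_id = if (length(members) == 1L) members else sample(members, 1L),
        compound_id = paste0("cmpd_", a),
        np_cluster_id = arch$np_family_id[arch$archetype_id == a])
    })
    anchors <- dplyr::bind_rows(anchor_rows)
  }

  truth_map <- bgcs[, c("bgc_id", "archetype_id")]
  bgcs$archetype_id <- NULL
  dataset <- new_dataset(taxonomy, bgcs, anchors, vocab)

  # per-genus accessible archetype richness: non-singleton archetypes whose
  # home taxon subtree intersects the genus subtree, plus singletons realized
  # in the genus.
  genera <- unique(taxonomy$genus)
  genus_rich <- lapply(genera, function(g) {
    sub <- tree[tree[, "genus"] == g, , drop = FALSE]
    acc <- vapply(seq_len(nrow(arch)), function(i) {
      if (arch$singleton[i]) {
        carriers <- truth_map$bgc_id[truth_map$archetype_id ==
                                       arch$archetype_id[i]]
        if (length(carriers) == 0) return(FALSE)
        gm <- bgcs$genome_id[bgcs$bgc_id %in% carriers]
        return(any(taxonomy$genus[match(gm, taxonomy$genome_id)] == g))
      }
      hr <- arch$home_rank[i]
      if (hr == "multi-phyla") return(TRUE)
      if (hr %in% colnames(sub)) return(any(sub[, hr] == arch$home_taxon[i]))
      FALSE
    }, logical(1))
    tibble::tibble(genus = g, richness = sum(acc),
                   richness_np = length(unique(arch$np_family_id[acc])))
  })

  list(dataset = dataset,
       truth = list(
         bgc_archetype = truth_map,
         archetypes = arch,
         genus_richness = dplyr::bind_rows(genus_rich)))
}
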