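#' Link GCFs to natural-product structural clusters through anchor BGCs
#'
#' Every family containing at least one anchored BGC inherits that anchor's
#' structural-cluster label, and all member BGCs of the family are emitted
#' with the inherited putative cluster. Families linked to more than one
#' structural cluster are flagged ambiguous (reported, not resolved).
#'
#' @param assignment a `gcf_assignment`.
#' @param anchors anchor tibble; every `bgc_id` must be assigned.
#' @return list with `links` (tibble `gcf_id`, `np_cluster_id`,
#'   `ambiguous`), `annotated` (tibble `bgc_id`, `gcf_id`,
#'   `np_cluster_ids` — `;`-joined), `n_known_gcfs`, `n_annotated_bgcs`.
#' @export
link_anchors <- function(assignment, anchors) {
  stopifnot(inherits(assignment, "gcf_assignment"))
  asg <- assignment$assignment
  if (nrow(anchors) == 0) {
    return(list(links = tibble::tibble(gcf_id = character(),
                                       np_cluster_id = character(),
                                       ambiguous = logical()),
                annotated = tibble::tibble(bgc_id = character(),
                                           gcf_id = character(),
                                           np_cluster_ids = character()),
                n_known_gcfs = 0L, n_annotated_bgcs = 0L))
  }
  idx <- match(anchors$bgc_id, asg$bgc_id)
  if (anyNA(idx)) stop("anchor references an unassigned BGC")
  a <- tibble::tibble(gcf_id = as.character(asg$gcf_id[idx]),
                      np_cluster_id = anchors$np_cluster_id)
  links <- dplyr::distinct(a)
  n_np_per_gcf <- table(links$gcf_id)
  links$ambiguous <- as.integer(n_np_per_gcf[links$gcf_id]) > 1L

  known <- unique(links$gcf_id)
  members <- asg[as.character(asg$gcf_id) %in% known, c("bgc_id", "gcf_id")]
  members$gcf_id <- as.character(members$gcf_id)
  np_join <- tapply(links$np_cluster_id, links$gcf_id,
                    function(x) paste(sort(unique(x)), collapse = ";"))
  members$np_cluster_ids <- as.character(np_join[members$gcf_id])
  list(links = links, annotated = members,
       n_known_gcfs = length(known),
       n_annotated_bgcs = nrow(members))
}

#' Pick one representative BGC per GCF
#'
#' Uniform seeded choice among each family's members; deterministic for a
#' fixed seed.
#'
#' @param assignment a `gcf_assignment`.
#' @param seed integer seed.
#' @return tibble `gcf_id` (character), `bgc_id`.
#' @export
representatives <- function(assignment, seed = 1L) {
  stopifnot(inherits(assignment, "gcf_assignment"))
  asg <- assignment$assignment
  set.seed(seed)
  rows <- lapply(sort(unique(asg$gcf_id)), function(g) {
    members <- sort(asg$bgc_id[asg$gcf_id == g])
    tibble::tibble(gcf_id = as.character(g),
                   bgc_id = if (length(members) == 1L) members
                            else sample(members, 1L))
  })
  dplyr::bind_rows(rows)
}

#' Build a query cluster
#'
#' @param query_id identifier (e.g. a drug name).
#' @param genes list of genes in cluster order; each a list with `domains`
#'   (character vector) and `core` (logical). At least one gene must be
#'   core.
#' @return a `query_cluster`.
#' @export
query_cluster <- function(query_id, genes) {
  stopifnot(length(genes) >= 1)
  core <- vapply(genes, function(g) isTRUE(g$core), logical(1))
  if (!any(core)) stop("query must contain at least one core gene")
  structure(list(query_id = query_id, genes = genes), class = "query_cluster")
}

#' Read query clusters from a tab-separated file
#'
#' Layout: `query_id`, `gene_index`, `core` (TRUE/FALSE), `domains`
#' (`;`-joined domain names), one row per gene.
#'
#' @param path file path.
#' @return named list of `query_cluster` objects.
#' @export
read_queries <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("query_id", "gene_index", "core", "domains")
  if (!all(need %in% names(tab))) {
    stop("query file is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- lapply(split(tab, tab$query_id), function(q) {
    q <- q[order(as.integer(q$gene_index)), ]
    genes <- lapply(seq_len(nrow(q)), function(i) {
      list(domains = strsplit(q$domains[i], ";", fixed = TRUE)[[1]],
           core = toupper(q$core[i]) %in% c("TRUE", "T", "1"))
    })
    query_cluster(q$query_id[1], genes)
  })
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# does a gene's domain set match anywhere along the target's domain order?
gene_matches <- function(gene_domains, target_order, min_jaccard = 0.5) {
  w <- length(gene_domains)
  if (length(target_order) == 0) return(FALSE)
  if (length(target_order) <= w) {
    return(jaccard(gene_domains, target_order) >= min_jaccard)
  }
  for (s in seq_len(length(target_order) - w + 1L)) {
    if (jaccard(gene_domains, target_order[s:(s + w - 1L)]) >= min_jaccard) {
      return(TRUE)
    }
  }
  FALSE
}

#' Core-gene-required cluster homology search
#'
#' Screens the representative BGC of every family against a query cluster.
#' A representative is a hit iff (a) every core query gene matches the
#' target — a gene matches when the Jaccard similarity between its domain
#' set and some sliding window of the target's domain order (window length
#' = the gene's domain count) is at least 0.5 — and (b) the fraction of all
#' query genes matched is at least `min_gene_frac`. Hits are expanded to
#' every member of the hit representative's family.
#'
#' @param query a `query_cluster`.
#' @param reps tibble from [representatives()].
#' @param assignment the `gcf_assignment`.
#' @param dataset the `gcf_dataset` (for the targets' domain orders).
#' @param min_gene_frac minimum matched fraction of all query genes
#'   (default 0.6).
#' @return list with `hit_reps` (tibble `gcf_id`, `bgc_id`,
#'   `matched_frac`) and `hit_bgcs` (tibble `bgc_id`, `gcf_id` over all
#'   members of hit families).
#' @export
query_search <- function(query, reps, assignment, dataset,
                         min_gene_frac = 0.6) {
  stopifnot(inherits(query, "query_cluster"),
            min_gene_frac >= 0, min_gene_frac <= 1)
  core <- vapply(query$genes, function(g) isTRUE(g$core), logical(1))
  if (!any(core)) stop("query has no core genes")
  orders <- setNames(dataset$bgcs$domain_order, dataset$bgcs$bgc_id)

  hit_rows <- list()
  for (i in seq_len(nrow(reps))) {
    target <- orders[[reps$bgc_id[i]]]
    if (is.null(target)) next
    matched <- vapply(query$genes, function(g) {
      gene_matches(g$domains, target)
    }, logical(1))
    if (!all(matched[core])) next
    frac <- mean(matched)
    if (frac >= min_gene_frac) {
      hit_rows[[length(hit_rows) + 1L]] <-
        tibble::tibble(gcf_id = reps$gcf_id[i], bgc_id = reps$bgc_id[i],
                       matched_frac = frac)
    }
  }
  hit_reps <- if (length(hit_rows)) dplyr::bind_rows(hit_rows) else
    tibble::tibble(gcf_id = character(), bgc_id = character(),
                   matched_frac = numeric())
  asg <- assignment$assignment
  hit_bgcs <- asg[as.character(asg$gcf_id) %in% hit_reps$gcf_id,
                  c("bgc_id", "gcf_id")]
  hit_bgcs$gcf_id <- as.character(hit_bgcs$gcf_id)
  list(hit_reps = hit_reps, hit_bgcs = hit_bgcs)
}

adjacent_pairs <- function(ord) {
  if (length(ord) < 2) return(character())
  a <- ord[-length(ord)]; b <- ord[-1]
  unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

#' Pairwise BGC similarity
#'
#' `0.5 * Jaccard(domain sets) + 0.5 * adjacency index`, where the adjacency
#' index is the Jaccard similarity of the unordered adjacent-domain pairs of
#' the two domain orders (0 when both clusters have fewer than two domains).
#'
#' @param order_a,order_b character vectors of domain names along the two
#'   clusters.
#' @return similarity in `[0, 1]`.
#' @export
bgc_similarity <- function(order_a, order_b) {
  js <- jaccard(unique(order_a), unique(order_b))
  pa <- adjacent_pairs(order_a); pb <- adjacent_pairs(order_b)
  ai <- if (length(pa) == 0 && length(pb) == 0) 0 else jaccard(pa, pb)
  0.5 * js + 0.5 * ai
}

#' Similarity network over a set of BGCs
#'
#' Computes all pairwise similarities with [bgc_similarity()], keeps edges
#' at or above the cutoff, and reports connected components.
#'
#' @param bgc_ids character vector of BGC ids.
#' @param dataset the `gcf_dataset` holding their domain orders.
#' @param cutoff edge-retention similarity cutoff in `[0, 1]`
#'   (default 0.3).
#' @return list with `edges` (tibble `source`, `target`, `weight`),
#'   `components` (tibble `bgc_id`, `component`) and `graph` (igraph
#'   object).
#' @export
similarity_network <- function(bgc_ids, dataset, cutoff = 0.3) {
  stopifnot(length(bgc_ids) >= 1, cutoff >= 0, cutoff <= 1)
  orders <- setNames(dataset$bgcs$domain_order, dataset$bgcs$bgc_id)
  missing <- setdiff(bgc_ids, names(orders))
  if (length(missing)) stop("unknown bgc_id: ", missing[1])
  ids <- sort(unique(bgc_ids))
  m <- length(ids)
  edges <- list()
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        w <- bgc_similarity(orders[[ids[i]]], orders[[ids[j]]])
        if (w >= cutoff) {
          edges[[length(edges) + 1L]] <-
            tibble::tibble(source = ids[i], target = ids[j], weight = w)
        }
      }
    }
  }
  edge_tab <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(source = character(), target = character(),
                   weight = numeric())
  g <- igraph::graph_from_data_frame(edge_tab, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  list(edges = edge_tab,
       components = tibble::tibble(bgc_id = names(comp$membership),
                                   component = as.integer(comp$membership)),
       graph = g)
}

#' Census of drug-similar BGCs by genus
#'
#' Summarizes each query's hit list by genus and reports the share of hits
#' falling in a focal set of genera (e.g. the top producers of potential
#' diversity).
#'
#' @param hits named list: query id -> tibble of hit BGCs (with `bgc_id`).
#' @param dataset the `gcf_dataset` (for genome and genus lookup).
#' @param focal_genera character vector of focal genus names.
#' @return list with `per_query` (tibble `query_id`, `n_hits`,
#'   `n_genera`, `focal_hits`, `focal_pct`), `by_genus` (tibble `query_id`,
#'   `genus`, `n_hits`) and `total` (list `n_hits`, `focal_hits`,
#'   `focal_pct`).
#' @export
drug_census <- function(hits, dataset, focal_genera = character()) {
  tax <- dataset$taxonomy
  genome_of <- setNames(dataset$bgcs$genome_id, dataset$bgcs$bgc_id)
  genus_of <- setNames(tax$genus, tax$genome_id)
  per_query <- list(); by_genus <- list()
  for (qid in names(hits)) {
    h <- hits[[qid]]
    genera <- as.character(genus_of[as.character(genome_of[h$bgc_id])])
    tab <- table(genera)
    focal <- sum(genera %in% focal_genera)
    per_query[[qid]] <- tibble::tibble(
      query_id = qid, n_hits = length(genera),
      n_genera = length(tab), focal_hits = focal,
      focal_pct = if (length(genera)) 100 * focal / length(genera) else 0)
    if (length(tab)) {
      by_genus[[qid]] <- tibble::tibble(query_id = qid, genus = names(tab),
                                        n_hits = as.integer(tab))
    }
  }
  pq <- dplyr::bind_rows(per_query)
  total_hits <- sum(pq$n_hits)
  total_focal <- sum(pq$focal_hits)
  list(per_query = pq,
       by_genus = dplyr::bind_rows(by_genus),
       total = list(n_hits = total_hits, focal_hits = total_focal,
                    focal_pct = if (total_hits > 0)
                      100 * total_focal / total_hits else 0))
}
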