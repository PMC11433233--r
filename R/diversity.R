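SPECIFICITY_CLASSES <- c("species-specific", "genus-specific",
                         "family-specific", "order-specific",
                         "class-specific", "phylum-specific", "multi-phyla")

#' GCF-by-genome incidence matrix
#'
#' Boolean presence/absence of each family in each genome. A cell is true
#' iff at least one member BGC of that family lies in that genome; genomes
#' without BGCs appear as all-false columns.
#'
#' @param assignment a `gcf_assignment`.
#' @param dataset the `gcf_dataset` the assignment was computed on.
#' @return logical matrix, rows = `gcf_id` (as character), columns =
#'   `genome_id`.
#' @export
incidence <- function(assignment, dataset) {
  stopifnot(inherits(assignment, "gcf_assignment"),
            inherits(dataset, "gcf_dataset"))
  asg <- assignment$assignment
  genome <- dataset$bgcs$genome_id[match(asg$bgc_id, dataset$bgcs$bgc_id)]
  if (anyNA(genome)) stop("assignment contains BGCs absent from the dataset")
  gcfs <- sort(unique(asg$gcf_id))
  genomes <- dataset$taxonomy$genome_id
  m <- matrix(FALSE, nrow = length(gcfs), ncol = length(genomes),
              dimnames = list(as.character(gcfs), genomes))
  m[cbind(match(asg$gcf_id, gcfs), match(genome, genomes))] <- TRUE
  m
}

#' Taxonomic specificity of each GCF
#'
#' A family's specificity class is the lowest taxonomic rank at which all of
#' its carrier genomes share a single taxon — `species-specific` when all
#' carriers are one species, up through `phylum-specific`; families whose
#' carriers span phyla are `multi-phyla`. Lineage identity is judged on the
#' full rank path so that identically named taxa under different parents are
#' not conflated.
#'
#' @param matrix incidence matrix from [incidence()].
#' @param taxonomy taxonomy tibble covering all its genome columns.
#' @return list with `classes` (tibble `gcf_id`, `class`) and
#'   `per_genome` (tibble of per-genome counts per class; class counts sum
#'   to the genome's family richness).
#' @export
specificity <- function(matrix, taxonomy) {
  stopifnot(all(colnames(matrix) %in% taxonomy$genome_id))
  tax <- taxonomy[match(colnames(matrix), taxonomy$genome_id), ]
  # full-path labels, lowest first: species, genus, ..., phylum
  paths <- lapply(6:1, function(k) {
    do.call(paste, c(tax[, RANKS[1:k], drop = FALSE], sep = "|"))
  })
  names(paths) <- SPECIFICITY_CLASSES[1:6]

  zero <- rowSums(matrix) == 0
  if (any(zero)) {
    warning(sum(zero), " GCF(s) with zero carriers excluded")
    matrix <- matrix[!zero, , drop = FALSE]
  }
  cls <- vapply(seq_len(nrow(matrix)), function(i) {
    carriers <- which(matrix[i, ])
    for (j in seq_along(paths)) {
      if (length(unique(paths[[j]][carriers])) == 1L) {
        return(SPECIFICITY_CLASSES[j])
      }
    }
    "multi-phyla"
  }, character(1))
  classes <- tibble::tibble(gcf_id = rownames(matrix),
                            class = factor(cls,
                                           levels = SPECIFICITY_CLASSES))
  per_genome <- lapply(colnames(matrix), function(g) {
    counts <- table(classes$class[matrix[, g]])
    tibble::tibble(genome_id = g, class = names(counts),
                   n_gcf = as.integer(counts))
  })
  list(classes = classes, per_genome = dplyr::bind_rows(per_genome))
}

#' Modal BGC type of each GCF
#'
#' A family's type is the most frequent member BGC type; ties break toward
#' the lexicographically smallest type string.
#'
#' @param assignment a `gcf_assignment`.
#' @param dataset the matching `gcf_dataset`.
#' @return tibble `gcf_id` (character), `bgc_type`.
#' @export
gcf_types <- function(assignment, dataset) {
  asg <- assignment$assignment
  type <- dataset$bgcs$bgc_type[match(asg$bgc_id, dataset$bgcs$bgc_id)]
  modal <- tapply(type, asg$gcf_id, function(tt) {
    counts <- table(tt)
    names(counts)[which.max(counts)]  # table is name-sorted; first max wins
  })
  tibble::tibble(gcf_id = names(modal), bgc_type = as.character(modal))
}

#' Specificity-class by BGC-type contingency of GCFs
#'
#' @param spec result of [specificity()].
#' @param types result of [gcf_types()].
#' @return list with `counts` (class x type integer matrix, all seven
#'   classes as rows) and `percent` (row-wise percentages; zero rows stay
#'   zero).
#' @export
type_by_range_matrix <- function(spec, types) {
  cls <- spec$classes
  ty <- types$bgc_type[match(cls$gcf_id, types$gcf_id)]
  counts <- table(cls$class, ty)
  m <- matrix(0L, nrow = length(SPECIFICITY_CLASSES), ncol = ncol(counts),
              dimnames = list(SPECIFICITY_CLASSES, colnames(counts)))
  m[rownames(counts), ] <- counts
  rs <- rowSums(m)
  pct <- 100 * m / ifelse(rs == 0, 1, rs)
  list(counts = m, percent = pct)
}

#' Variance of GCF richness across sub-taxa, per rank
#'
#' For each rank from phylum down to genus, and for every taxon at that rank
#' with at least two observed children at the next lower rank, computes the
#' sample variance of distinct-GCF richness across those children (richness
#' of a child = number of distinct families carried by its genomes). The
#' rank whose variances are smallest marks the level below which
#' biosynthetic diversity is homogeneous. Cross-rank differences are tested
#' with a Kruskal-Wallis rank test on the variance values.
#'
#' @param matrix incidence matrix from [incidence()].
#' @param taxonomy matching taxonomy tibble.
#' @return list with `table` (tibble `rank`, `parent`, `n_children`,
#'   `variance`) and `test` (the `htest` from [stats::kruskal.test()], or
#'   `NULL` when fewer than two ranks are eligible).
#' @export
rank_variance <- function(matrix, taxonomy) {
  tax <- taxonomy[match(colnames(matrix), taxonomy$genome_id), ]
  richness_of <- function(genomes) {
    cols <- match(genomes, colnames(matrix))
    sum(rowSums(matrix[, cols, drop = FALSE]) > 0)
  }
  rows <- list()
  for (k in 1:5) {           # phylum..genus; children at rank k+1
    parent_rank <- RANKS[k]; child_rank <- RANKS[k + 1]
    for (p in unique(tax[[parent_rank]])) {
      sub <- tax[tax[[parent_rank]] == p, ]
      kids <- unique(sub[[child_rank]])
      if (length(kids) < 2) next
      rich <- vapply(kids, function(ch) {
        richness_of(sub$genome_id[sub[[child_rank]] == ch])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rank = parent_rank, parent = p,
        n_children = length(kids), variance = var(rich))
    }
  }
  if (length(rows) == 0) {
    warning("no rank has a parent with >= 2 observed children")
    return(list(table = tibble::tibble(rank = character(),
                                       parent = character(),
                                       n_children = integer(),
                                       variance = numeric()),
                test = NULL))
  }
  tab <- dplyr::bind_rows(rows)
  tab$rank <- factor(tab$rank, levels = RANKS[1:5])
  test <- NULL
  if (length(unique(tab$rank[!is.na(tab$variance)])) >= 2) {
    test <- kruskal.test(variance ~ rank, data = tab)
  }
  list(table = tab, test = test)
}

#' Per-phylum biosynthetic resource summary
#'
#' @param matrix incidence matrix from [incidence()].
#' @param taxonomy matching taxonomy tibble.
#' @param anchors anchor tibble (may be empty).
#' @param assignment the `gcf_assignment`.
#' @param dataset optional `gcf_dataset`; when supplied, per-phylum BGC
#'   counts are included (otherwise `NA`).
#' @return tibble with one row per phylum: `n_genomes`, `n_bgcs`, `n_gcfs`
#'   (distinct families observed in the phylum), `gcfs_per_genome` (mean
#'   distinct families per genome), `n_known_gcfs` (families containing an
#'   anchored BGC of that phylum) and `known_pct`.
#' @export
phylum_summary <- function(matrix, taxonomy, anchors, assignment,
                           dataset = NULL) {
  asg <- assignment$assignment
  tax <- taxonomy
  anchored_gcf_by_genome <- NULL
  if (nrow(anchors) > 0) {
    a_gcf <- asg$gcf_id[match(anchors$bgc_id, asg$bgc_id)]
    anchored <- tibble::tibble(gcf_id = as.character(a_gcf),
                               bgc_id = anchors$bgc_id)
  } else {
    anchored <- tibble::tibble(gcf_id = character(), bgc_id = character())
  }
  # genome of each BGC for per-phylum BGC counts
  bgc_genome <- NULL
  if (!is.null(dataset)) {
    bgc_genome <- setNames(dataset$bgcs$genome_id, dataset$bgcs$bgc_id)
  }

  rows <- lapply(unique(tax$phylum), function(ph) {
    genomes <- tax$genome_id[tax$phylum == ph]
    sub <- matrix[, genomes, drop = FALSE]
    present <- rowSums(sub) > 0
    n_gcfs <- sum(present)
    per_genome <- colSums(sub)
    n_bgcs <- if (!is.null(bgc_genome)) {
      sum(bgc_genome %in% genomes)
    } else NA_integer_
    known <- sum(rownames(sub)[present] %in% anchored$gcf_id)
    tibble::tibble(phylum = ph, n_genomes = length(genomes),
                   n_bgcs = n_bgcs, n_gcfs = n_gcfs,
                   gcfs_per_genome = mean(per_genome),
                   n_known_gcfs = known,
                   known_pct = if (n_gcfs > 0) 100 * known / n_gcfs else 0)
  })
  dplyr::bind_rows(rows)
}
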