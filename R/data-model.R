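#' gcfdiversity: biosynthetic gene cluster family diversity analysis
#'
#' Tools for quantifying the biosynthetic diversity encoded in large genome
#' collections: clustering of biosynthetic gene clusters (BGCs) into gene
#' cluster families (GCFs) with a calibrated distance threshold, taxonomic
#' decomposition of GCF diversity, incidence-based rarefaction to potential
#' GCF richness, and anchor-based annotation of GCFs with known
#' natural-product structural clusters.
#'
#' @keywords internal
#' @importFrom stats rnorm runif setNames var kruskal.test
#' @importFrom utils head
"_PACKAGE"

RANKS <- c("phylum", "class", "order", "family", "genus", "species", "organism")

BGC_TYPES <- c("T1PKS", "NRPS", "NRPS-like", "terpene",
               "T1PKS&NRPS", "T1PKS&NRPS-like", "other")

#' Assemble and validate a dataset
#'
#' Bundles the three tables the pipeline consumes — genome taxonomy, BGC
#' records, and compound anchors — together with the domain vocabulary that
#' defines the feature space. All referential invariants are checked: every
#' BGC must resolve to a genome, every anchor to a BGC, and every domain name
#' to the vocabulary.
#'
#' @param taxonomy tibble with columns `genome_id` plus the seven ranks
#'   `phylum`, `class`, `order`, `family`, `genus`, `species`, `organism`.
#' @param bgcs tibble with columns `bgc_id`, `genome_id`, `bgc_type`,
#'   `length_kb`, `domains` (list column of named non-negative numeric
#'   vectors) and optionally `domain_order` (list column of character
#'   vectors).
#' @param anchors tibble with columns `bgc_id`, `compound_id`,
#'   `np_cluster_id`; may have zero rows.
#' @param vocabulary ordered character vector of domain names. If `NULL`,
#'   inferred as the sorted union of domain names used by `bgcs`.
#' @return an object of class `gcf_dataset`: a list with elements
#'   `taxonomy`, `bgcs`, `anchors`, `vocabulary`.
#' @export
new_dataset <- function(taxonomy, bgcs, anchors = NULL, vocabulary = NULL) {
  taxonomy <- tibble::as_tibble(taxonomy)
  bgcs <- tibble::as_tibble(bgcs)
  if (is.null(anchors)) {
    anchors <- tibble::tibble(bgc_id = character(), compound_id = character(),
                              np_cluster_id = character())
  }
  anchors <- tibble::as_tibble(anchors)

  need_tax <- c("genome_id", RANKS)
  if (!all(need_tax %in% names(taxonomy))) {
    stop("taxonomy is missing columns: ",
         paste(setdiff(need_tax, names(taxonomy)), collapse = ", "))
  }
  if (anyDuplicated(taxonomy$genome_id)) {
    stop("duplicate genome_id in taxonomy")
  }
  need_bgc <- c("bgc_id", "genome_id", "bgc_type", "length_kb", "domains")
  if (!all(need_bgc %in% names(bgcs))) {
    stop("bgcs is missing columns: ",
         paste(setdiff(need_bgc, names(bgcs)), collapse = ", "))
  }
  if (anyDuplicated(bgcs$bgc_id)) stop("duplicate bgc_id in bgcs")
  if (any(bgcs$length_kb <= 0)) stop("length_kb must be positive")
  if (!"domain_order" %in% names(bgcs)) {
    bgcs$domain_order <- lapply(bgcs$domains, names)
  }
  for (d in bgcs$domains) {
    if (length(d) == 0 || is.null(names(d))) stop("empty domain vector")
    if (any(d < 0)) stop("negative domain weight")
    if (!any(d > 0)) stop("domain vector has no positive weight")
  }
  used <- sort(unique(unlist(lapply(bgcs$domains, names))))
  if (is.null(vocabulary)) {
    vocabulary <- used
  } else if (!all(used %in% vocabulary)) {
    stop("domain names outside vocabulary: ",
         paste(head(setdiff(used, vocabulary), 5), collapse = ", "))
  }
  if (!all(bgcs$genome_id %in% taxonomy$genome_id)) {
    stop("BGC references unknown genome_id")
  }
  if (nrow(anchors) > 0) {
    if (anyDuplicated(anchors$bgc_id)) stop("anchor bgc_id not unique")
    if (!all(anchors$bgc_id %in% bgcs$bgc_id)) {
      stop("anchor references unknown bgc_id")
    }
    if (any(!nzchar(anchors$np_cluster_id))) stop("empty np_cluster_id")
  }
  structure(list(taxonomy = taxonomy, bgcs = bgcs, anchors = anchors,
                 vocabulary = vocabulary),
            class = "gcf_dataset")
}

#' @export
print.gcf_dataset <- function(x, ...) {
  cat("<gcf_dataset>\n")
  cat("  genomes:   ", nrow(x$taxonomy), "\n")
  cat("  BGCs:      ", nrow(x$bgcs), "\n")
  cat("  anchors:   ", nrow(x$anchors), "\n")
  cat("  vocabulary:", length(x$vocabulary), "domains\n")
  invisible(x)
}
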