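#' Homogeneity, completeness and V-measure of a clustering
#'
#' Entropy-based agreement between a clustering and reference labels.
#' Homogeneity `h = 1 - H(true|cluster)/H(true)` (1 when the reference
#' labelling has zero entropy); completeness
#' `c = 1 - H(cluster|true)/H(cluster)` (1 when the clustering has zero
#' entropy); the V-measure is their harmonic mean (0 when `h + c = 0`).
#' The result does not depend on the entropy base or on label names.
#'
#' @param true_labels,cluster_labels equal-length vectors of labels.
#' @return named numeric vector `c(homogeneity, completeness, v)`.
#' @export
v_score <- function(true_labels, cluster_labels) {
  if (length(true_labels) != length(cluster_labels)) {
    stop("label vectors differ in length")
  }
  stopifnot(length(true_labels) >= 1)
  ct <- table(true_labels, cluster_labels)
  n <- sum(ct)
  p <- ct / n
  pt <- rowSums(p)
  pc <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h_t <- ent(pt)
  h_c <- ent(pc)
  # conditional entropies from the joint
  h_t_given_c <- ent(as.numeric(p)) - h_c   # H(T,C) - H(C)
  h_c_given_t <- ent(as.numeric(p)) - h_t
  h <- if (h_t == 0) 1 else 1 - h_t_given_c / h_t
  cm <- if (h_c == 0) 1 else 1 - h_c_given_t / h_c
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  c(homogeneity = h, completeness = cm, v = v)
}

#' Signed difference between family count and reference-cluster count
#'
#' The calibration criterion compares the number of GCFs produced at a
#' threshold with the number of reference natural-product structural
#' clusters; threshold selection uses the magnitude of this difference while
#' the sign records the direction (negative = fewer families than reference
#' clusters).
#'
#' @param n_gcf,n_np non-negative integers.
#' @return signed integer `n_gcf - n_np`.
#' @export
delta_gcf <- function(n_gcf, n_np) {
  stopifnot(n_gcf >= 0, n_np >= 0)
  as.integer(n_gcf) - as.integer(n_np)
}

#' Calibrate the clustering threshold against compound structural clusters
#'
#' Clusters only the anchored BGCs at each grid threshold and scores the
#' resulting partition against the anchors' structural-cluster labels with
#' the V-measure and the family-count difference. The chosen threshold is
#' the grid value maximizing the V-measure among those exceeding 0.9 (a
#' conventional quality gate); ties break toward the smaller
#' `|delta_gcf|`, then the smaller threshold. If no grid point clears the
#' gate the global V-measure maximum is taken with a warning.
#'
#' @param dataset a `gcf_dataset` with at least 2 anchors spanning at least
#'   2 structural clusters.
#' @param grid numeric vector of candidate thresholds.
#' @return a `gcf_calibration`: list with `table` (tibble: `t_clust`,
#'   `n_gcf`, `n_np_clusters`, `delta_gcf`, `homogeneity`, `completeness`,
#'   `v_score`) and `chosen_t`.
#' @export
calibrate <- function(dataset, grid = seq(0.1, 1.1, by = 0.05)) {
  stopifnot(inherits(dataset, "gcf_dataset"), length(grid) >= 1)
  anchors <- dataset$anchors
  if (nrow(anchors) < 2 || length(unique(anchors$np_cluster_id)) < 2) {
    stop("calibration needs >= 2 anchors spanning >= 2 structural clusters")
  }
  bgcs <- dataset$bgcs[dataset$bgcs$bgc_id %in% anchors$bgc_id, ]
  feats <- featurize(bgcs, dataset$vocabulary)
  labels <- anchors$np_cluster_id[match(rownames(feats), anchors$bgc_id)]
  n_np <- length(unique(labels))

  rows <- lapply(sort(grid), function(t) {
    asg <- gcf_cluster(feats, t)
    cl <- asg$assignment$gcf_id[match(rownames(feats),
                                      asg$assignment$bgc_id)]
    sc <- v_score(labels, cl)
    tibble::tibble(t_clust = t, n_gcf = nrow(asg$centroids),
                   n_np_clusters = n_np,
                   delta_gcf = delta_gcf(nrow(asg$centroids), n_np),
                   homogeneity = sc[["homogeneity"]],
                   completeness = sc[["completeness"]],
                   v_score = sc[["v"]])
  })
  tab <- dplyr::bind_rows(rows)

  pass <- tab[tab$v_score > 0.9, ]
  if (nrow(pass) == 0) {
    warning("no grid threshold reaches v > 0.9; taking the global maximum")
    pass <- tab
  }
  pass <- pass[order(-pass$v_score, abs(pass$delta_gcf), pass$t_clust), ]
  structure(list(table = tab, chosen_t = pass$t_clust[1]),
            class = "gcf_calibration")
}

#' @export
print.gcf_calibration <- function(x, ...) {
  cat("<gcf_calibration> chosen threshold =", x$chosen_t, "\n")
  best <- x$table[x$table$t_clust == x$chosen_t, ]
  cat(sprintf("  v = %.3f, delta_gcf = %+d (n_gcf %d vs %d NP clusters)\n",
              best$v_score, best$delta_gcf, best$n_gcf,
              best$n_np_clusters))
  invisible(x)
}
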