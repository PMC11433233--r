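#' Featurize BGCs into L2-normalized domain vectors
#'
#' Expands each BGC's sparse domain map into a dense vector over the ordered
#' vocabulary and scales it to unit Euclidean norm, so that pairwise
#' distances lie in `[0, sqrt(2)]` for non-negative vectors.
#'
#' @param bgcs tibble of BGC records (with a `domains` list column).
#' @param vocabulary ordered character vector of domain names covering every
#'   domain used.
#' @return numeric matrix, one row per BGC (rownames `bgc_id`, rows sorted by
#'   `bgc_id`), columns the vocabulary; each row has unit norm.
#' @export
featurize <- function(bgcs, vocabulary) {
  stopifnot(nrow(bgcs) >= 1)
  used <- unique(unlist(lapply(bgcs$domains, names)))
  if (!all(used %in% vocabulary)) {
    stop("domain names outside vocabulary: ",
         paste(head(setdiff(used, vocabulary), 5), collapse = ", "))
  }
  m <- matrix(0, nrow = nrow(bgcs), ncol = length(vocabulary),
              dimnames = list(bgcs$bgc_id, vocabulary))
  for (i in seq_len(nrow(bgcs))) {
    d <- bgcs$domains[[i]]
    m[i, names(d)] <- as.numeric(d)
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("all-zero domain vector for: ",
                          paste(rownames(m)[nrm == 0], collapse = ", "))
  m <- m / nrm
  m[order(rownames(m)), , drop = FALSE]
}

#' Cluster feature vectors into gene cluster families
#'
#' Threshold-governed incremental clustering: in pass 1 the BGCs are visited
#' in ascending `bgc_id` order and each is assigned to the nearest existing
#' centroid if its Euclidean distance is at most `t_clust`, otherwise it
#' opens a new family; centroids are running means of their members. Pass 2
#' freezes the centroids and reassigns every BGC to its nearest centroid
#' (ties broken toward the lowest family id), which makes the final
#' partition independent of input order given the centroid set. Family ids
#' are dense integers in creation order.
#'
#' @param features matrix from [featurize()] (rows are unit vectors).
#' @param t_clust non-negative distance threshold in normalized-feature
#'   units (distances lie in `[0, sqrt(2)]`).
#' @return a `gcf_assignment`: list with `threshold`, `assignment` (tibble
#'   `bgc_id`, `gcf_id`, `dist_to_centroid`), `centroids` (matrix, one row
#'   per family) and `pass1` (named integer vector: the pass-1 membership
#'   before reassignment).
#' @export
gcf_cluster <- function(features, t_clust) {
  stopifnot(is.matrix(features), nrow(features) >= 1, t_clust >= 0)
  features <- features[order(rownames(features)), , drop = FALSE]
  n <- nrow(features)
  cap <- min(n, 1024L)
  centroids <- matrix(0, nrow = cap, ncol = ncol(features))
  sizes <- integer(cap)
  k <- 0L
  member <- integer(n)
  for (i in seq_len(n)) {
    v <- features[i, ]
    if (k == 0L) {
      k <- 1L; centroids[1L, ] <- v; sizes[1L] <- 1L; member[i] <- 1L
      next
    }
    d2 <- rowSums((centroids[seq_len(k), , drop = FALSE] -
                     rep(v, each = k))^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= t_clust) {
      sizes[j] <- sizes[j] + 1L
      centroids[j, ] <- centroids[j, ] + (v - centroids[j, ]) / sizes[j]
      member[i] <- j
    } else {
      if (k == nrow(centroids)) {  # grow storage
        centroids <- rbind(centroids,
                           matrix(0, nrow = nrow(centroids),
                                  ncol = ncol(features)))
        sizes <- c(sizes, integer(length(sizes)))
      }
      k <- k + 1L
      centroids[k, ] <- v; sizes[k] <- 1L; member[i] <- k
    }
  }
  centroids <- centroids[seq_len(k), , drop = FALSE]
  rownames(centroids) <- seq_len(k)

  # pass 2: frozen centroids, global nearest reassignment
  cross <- features %*% t(centroids)
  d2 <- outer(rowSums(features^2), rep(1, k)) +
    outer(rep(1, n), rowSums(centroids^2)) - 2 * cross
  d2[d2 < 0] <- 0
  gcf <- apply(d2, 1L, which.min)  # which.min takes the first (lowest id) tie
  dist <- sqrt(d2[cbind(seq_len(n), gcf)])

  # reassignment can empty a pass-1 family; drop unoccupied centroids and
  # renumber densely, preserving creation order
  occupied <- sort(unique(gcf))
  if (length(occupied) < k) {
    centroids <- centroids[occupied, , drop = FALSE]
    gcf <- match(gcf, occupied)
    rownames(centroids) <- seq_along(occupied)
  }

  structure(list(threshold = t_clust,
                 assignment = tibble::tibble(
                   bgc_id = rownames(features),
                   gcf_id = as.integer(gcf),
                   dist_to_centroid = as.numeric(dist)),
                 centroids = centroids,
                 pass1 = setNames(member, rownames(features))),
            class = "gcf_assignment")
}

#' @export
print.gcf_assignment <- function(x, ...) {
  cat("<gcf_assignment> threshold =", x$threshold, "\n")
  cat("  BGCs:", nrow(x$assignment), " GCFs:", nrow(x$centroids), "\n")
  invisible(x)
}

#' GCF size distribution
#'
#' Tallies families and their member BGCs into the size bins
#' `=1`, `2-10`, `11-100`, `>100`, and reports the singleton fractions.
#'
#' @param assignment a `gcf_assignment`.
#' @return list with `bins` (tibble `bin`, `n_gcf`, `n_bgc`),
#'   `singleton_gcf_fraction` (share of families with a single member) and
#'   `singleton_bgc_fraction` (share of BGCs inside such families).
#' @export
size_distribution <- function(assignment) {
  stopifnot(inherits(assignment, "gcf_assignment"))
  sizes <- table(assignment$assignment$gcf_id)
  s <- as.integer(sizes)
  size_bin <- cut(s, breaks = c(0, 1, 10, 100, Inf),
                  labels = c("=1", "2-10", "11-100", ">100"))
  bins <- tibble::tibble(bin = levels(size_bin),
                         n_gcf = as.integer(table(size_bin)),
                         n_bgc = as.integer(tapply(s, size_bin, sum,
                                                   default = 0L)))
  list(bins = bins,
       singleton_gcf_fraction = mean(s == 1L),
       singleton_bgc_fraction = sum(s[s == 1L]) / sum(s))
}
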