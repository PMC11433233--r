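test_that("featurization L2-normalizes over the vocabulary", {
  bgcs <- tibble::tibble(bgc_id = c("b1", "b2"), genome_id = c("g1", "g1"),
                         bgc_type = "T1PKS", length_kb = 1,
                         domains = list(c(d1 = 3, d2 = 4), c(d1 = 7)),
                         domain_order = list(c("d1", "d2"), "d1"))
  f <- featurize(bgcs, c("d1", "d2", "d3"))
  expect_equal(f["b1", ], c(d1 = 0.6, d2 = 0.8, d3 = 0))
  expect_equal(f["b2", ], c(d1 = 1, d2 = 0, d3 = 0))
  expect_equal(sqrt(rowSums(f^2)), c(b1 = 1, b2 = 1), tolerance = 1e-9)
  expect_error(featurize(bgcs, c("d1")), "vocabulary")
})

test_that("threshold extremes give singleton and saturated partitions", {
  set.seed(42)
  m <- matrix(abs(rnorm(8 * 5)), nrow = 8,
              dimnames = list(paste0("b", 1:8), paste0("d", 1:5)))
  m <- m / sqrt(rowSums(m^2))
  a0 <- gcf_cluster(m, 0)
  expect_equal(nrow(a0$centroids), 8)
  a2 <- gcf_cluster(m, 2.0)  # >= sqrt(2), the max distance here
  expect_equal(nrow(a2$centroids), 1)
})

test_that("well-separated noisy families are recovered exactly", {
  set.seed(7)
  base <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  rows <- lapply(1:12, function(i) {
    v <- abs(base[(i - 1) %% 2 + 1, ] + rnorm(4, sd = 0.02))
    v / sqrt(sum(v^2))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("b%02d", 1:12)
  colnames(m) <- paste0("d", 1:4)
  truth <- rep(c("A", "B"), 6)
  # brute-force separation check: within-family < T < between-family
  dmat <- as.matrix(dist(m))
  within <- max(dmat[truth[row(dmat)] == truth[col(dmat)]])
  between <- min(dmat[truth[row(dmat)] != truth[col(dmat)]])
  expect_lt(within, 0.3)
  expect_gt(between, 0.3)
  asg <- gcf_cluster(m, 0.3)
  expect_equal(nrow(asg$centroids), 2)
  expect_equal(unname(v_score(truth, asg$assignment$gcf_id)["v"]), 1)
})

test_that("pass 1 matches an independent from-scratch implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:12, 1)
    m <- matrix(abs(rnorm(n * 6)), nrow = n,
                dimnames = list(sprintf("b%02d", 1:n), paste0("d", 1:6)))
    m <- m / sqrt(rowSums(m^2))
    t_clust <- runif(1, 0.2, 1.0)
    expected <- oracle_pass1(m, t_clust)
    asg <- gcf_cluster(m, t_clust)
    expect_equal(unname(asg$pass1), expected)
  }
})

test_that("family count is non-increasing in the threshold", {
  gen <- generate_dataset(sim_config(seed = 13, n_genomes = 30,
                                     n_archetypes = 20, noise_sd = 2))
  f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
  grid <- seq(0, 1.2, by = 0.1)
  counts <- vapply(grid, function(t) nrow(gcf_cluster(f, t)$centroids),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the partition is invariant to input row order", {
  gen <- generate_dataset(sim_config(seed = 21, n_genomes = 20,
                                     n_archetypes = 10))
  f <- featurize(gen$dataset$bgcs, gen$dataset$vocabulary)
  a1 <- gcf_cluster(f, 0.5)
  set.seed(1)
  perm <- sample(nrow(f))
  a2 <- gcf_cluster(f[perm, ], 0.5)
  expect_identical(a1$assignment, a2$assignment)
})

test_that("size distribution bins and singleton fractions are exact", {
  fake <- function(sizes) {
    ids <- unlist(lapply(seq_along(sizes), function(i) rep(i, sizes[i])))
    structure(list(threshold = 0.5,
                   assignment = tibble::tibble(
                     bgc_id = sprintf("b%04d", seq_along(ids)),
                     gcf_id = ids,
                     dist_to_centroid = 0),
                   centroids = matrix(0, nrow = length(sizes), ncol = 1)),
              class = "gcf_assignment")
  }
  sd1 <- size_distribution(fake(c(1, 1, 3, 200)))
  expect_equal(sd1$bins$n_gcf, c(2L, 1L, 0L, 1L))
  expect_equal(sd1$bins$n_bgc, c(2L, 3L, 0L, 200L))
  expect_equal(sum(sd1$bins$n_gcf), 4L)
  expect_equal(sum(sd1$bins$n_bgc), 205L)

  sd2 <- size_distribution(fake(c(1, 1, 1)))
  expect_equal(sd2$singleton_bgc_fraction, 1.0)

  sd3 <- size_distribution(fake(c(1, 9)))
  expect_equal(sd3$singleton_gcf_fraction, 0.5)
  expect_equal(sd3$singleton_bgc_fraction, 0.1)
})
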