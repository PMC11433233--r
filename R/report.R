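round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summary-report arithmetic over a counts table
#'
#' Computes the derived ratio statistics of the analysis purely from named
#' counts, with the printed-precision rendering used in reporting
#' (percentages rounded half-up at the stated number of decimals). Only the
#' statistics whose input counts are present are computed; a statistic with
#' a zero denominator is omitted with a warning.
#'
#' Recognized inputs: `known_gcfs`, `total_gcfs`, `total_bgcs`,
#' `singleton_gcf_fraction`, `genus_gcfs`, `pgcf`, `gcfs`, `group_gcfs`,
#' `type_gcfs`, `known_phylum_gcfs`, `phylum_gcfs`, `focal_hits`,
#' `total_hits`, `genus_hit_counts` (vector).
#'
#' @param counts named list of counts.
#' @return tibble `statistic`, `raw`, `printed` (character), `unit`.
#' @export
summary_report <- function(counts) {
  stopifnot(is.list(counts))
  rows <- list()
  add <- function(name, raw, digits, unit) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      statistic = name, raw = raw,
      printed = if (unit == "percent") {
        format(round_half_up(raw, digits), nsmall = digits, trim = TRUE)
      } else {
        format(round_half_up(raw, digits), trim = TRUE, scientific = FALSE)
      },
      unit = unit)
  }
  ratio <- function(num, den, name, digits = 1) {
    if (is.null(counts[[num]]) || is.null(counts[[den]])) return()
    if (counts[[den]] == 0) {
      warning("zero denominator for ", name, "; omitted")
      return()
    }
    add(name, 100 * counts[[num]] / counts[[den]], digits, "percent")
  }
  ratio("known_gcfs", "total_gcfs", "known_gcf_pct")
  if (!is.null(counts$singleton_gcf_fraction) &&
      !is.null(counts$total_gcfs) && !is.null(counts$total_bgcs)) {
    if (counts$total_bgcs == 0) {
      warning("zero denominator for singleton_bgc_pct; omitted")
    } else {
      add("singleton_bgc_pct",
          100 * counts$singleton_gcf_fraction * counts$total_gcfs /
            counts$total_bgcs, 2, "percent")
    }
  }
  ratio("genus_gcfs", "total_gcfs", "genus_gcf_pct")
  if (!is.null(counts$pgcf) && !is.null(counts$gcfs)) {
    add("virtual_gcfs", counts$pgcf - counts$gcfs, 0, "count")
  }
  ratio("group_gcfs", "total_gcfs", "group_gcf_pct")
  ratio("type_gcfs", "genus_gcfs", "type_in_genus_pct")
  ratio("known_phylum_gcfs", "phylum_gcfs", "known_in_phylum_pct")
  ratio("focal_hits", "total_hits", "focal_hit_pct")
  if (!is.null(counts$genus_hit_counts)) {
    add("total_drug_hits", sum(counts$genus_hit_counts), 0, "count")
  }
  if (length(rows) == 0) {
    return(tibble::tibble(statistic = character(), raw = numeric(),
                          printed = character(), unit = character()))
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: dataset generation (or loading) →
#' optional threshold calibration → family clustering → size distribution →
#' incidence and specificity → rank variance → per-phylum summary →
#' per-genus rarefaction and the promising-genus screen → anchor linking →
#' optional drug-similarity search. Every stage's table is written
#' tab-separated under `out_dir`, together with a `run_log.txt` recording
#' the seed and thresholds. Runs are deterministic for a fixed
#' configuration.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] used to generate the dataset (ignored when
#'   `dataset` is given).
#' @param dataset an existing `gcf_dataset`, or `NULL` to simulate.
#' @param threshold explicit clustering threshold; exactly one of
#'   `threshold` and `grid` must be non-`NULL`.
#' @param grid calibration grid of candidate thresholds.
#' @param endpoint,n_knots rarefaction settings (defaults 10000 and 500).
#' @param queries optional named list of `query_cluster` objects for the
#'   drug-similarity census.
#' @param network_cutoff similarity-network edge cutoff.
#' @param seed seed for the representative draw.
#' @return invisibly, a list with every stage's result.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), dataset = NULL,
                         threshold = NULL, grid = NULL,
                         endpoint = 10000L, n_knots = 500L,
                         queries = NULL, network_cutoff = 0.3,
                         seed = 1L) {
  if (is.null(threshold) == is.null(grid)) {
    stop("exactly one of `threshold` and `grid` must be supplied")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(dataset)) {
    gen <- generate_dataset(sim)
    dataset <- gen$dataset
    truth <- gen$truth
    readr::write_tsv(gen$truth$bgc_archetype,
                     file.path(out_dir, "ground_truth.tsv"),
                     progress = FALSE)
  }
  write_tables(dataset, out_dir)

  calib <- NULL
  if (!is.null(grid)) {
    calib <- calibrate(dataset, grid)
    readr::write_tsv(calib$table, file.path(out_dir, "calibration.tsv"),
                     progress = FALSE)
    threshold <- calib$chosen_t
  }

  feats <- featurize(dataset$bgcs, dataset$vocabulary)
  assignment <- gcf_cluster(feats, threshold)
  readr::write_tsv(assignment$assignment,
                   file.path(out_dir, "gcf_assignments.tsv"),
                   progress = FALSE)
  sizes <- size_distribution(assignment)
  readr::write_tsv(sizes$bins, file.path(out_dir, "size_distribution.tsv"),
                   progress = FALSE)

  mat <- incidence(assignment, dataset)
  spec <- specificity(mat, dataset$taxonomy)
  readr::write_tsv(spec$classes, file.path(out_dir, "specificity.tsv"),
                   progress = FALSE)
  types <- gcf_types(assignment, dataset)
  tbr <- type_by_range_matrix(spec, types)
  readr::write_tsv(tibble::as_tibble(tbr$counts, rownames = "class"),
                   file.path(out_dir, "type_by_range.tsv"),
                   progress = FALSE)
  rv <- rank_variance(mat, dataset$taxonomy)
  readr::write_tsv(rv$table, file.path(out_dir, "rank_variance.tsv"),
                   progress = FALSE)
  phyla <- phylum_summary(mat, dataset$taxonomy, dataset$anchors,
                          assignment, dataset)
  readr::write_tsv(phyla, file.path(out_dir, "phylum_summary.tsv"),
                   progress = FALSE)

  pgcf <- genus_pgcf(mat, dataset$taxonomy, endpoint, n_knots)
  np_counts <- genus_np_counts(dataset)
  pgcf <- promising_genera(pgcf, np_counts)
  readr::write_tsv(pgcf, file.path(out_dir, "pgcf.tsv"), progress = FALSE)

  linked <- link_anchors(assignment, dataset$anchors)
  readr::write_tsv(linked$annotated, file.path(out_dir, "annotations.tsv"),
                   progress = FALSE)

  census <- NULL; net <- NULL
  if (!is.null(queries)) {
    reps <- representatives(assignment, seed)
    hits <- lapply(queries, function(q) {
      query_search(q, reps, assignment, dataset)$hit_bgcs
    })
    focal <- head(pgcf$genus[order(-pgcf$pgcf)], 10L)
    census <- drug_census(hits, dataset, focal)
    readr::write_tsv(census$per_query,
                     file.path(out_dir, "drug_census.tsv"),
                     progress = FALSE)
    all_hits <- unique(unlist(lapply(hits, function(h) h$bgc_id)))
    if (length(all_hits)) {
      net <- similarity_network(all_hits, dataset, network_cutoff)
      readr::write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"),
                       progress = FALSE)
    }
  }

  writeLines(c(paste("package gcfdiversity", "version",
                     as.character(utils::packageVersion("gcfdiversity"))),
               paste("seed:", seed),
               paste("threshold:", threshold),
               paste("endpoint:", endpoint, "knots:", n_knots),
               paste("genomes:", nrow(dataset$taxonomy),
                     "bgcs:", nrow(dataset$bgcs),
                     "gcfs:", nrow(assignment$centroids))),
             file.path(out_dir, "run_log.txt"))

  invisible(list(dataset = dataset, truth = truth, calibration = calib,
                 threshold = threshold, assignment = assignment,
                 sizes = sizes, incidence = mat, specificity = spec,
                 types = types, type_by_range = tbr, rank_variance = rv,
                 phylum_summary = phyla, pgcf = pgcf, links = linked,
                 census = census, network = net))
}

#' Known-compound counts per genus derived from the anchor table
#'
#' @param dataset a `gcf_dataset`.
#' @return tibble `genus`, `np_count` (distinct anchored compounds whose
#'   BGC lies in the genus).
#' @export
genus_np_counts <- function(dataset) {
  anchors <- dataset$anchors
  if (nrow(anchors) == 0) {
    return(tibble::tibble(genus = character(), np_count = integer()))
  }
  genome <- dataset$bgcs$genome_id[match(anchors$bgc_id,
                                         dataset$bgcs$bgc_id)]
  genus <- dataset$taxonomy$genus[match(genome,
                                        dataset$taxonomy$genome_id)]
  counts <- tapply(anchors$compound_id, genus,
                   function(x) length(unique(x)))
  tibble::tibble(genus = names(counts), np_count = as.integer(counts))
}
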