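#' Read a genome taxonomy table
#'
#' Reads a tab-separated taxonomy file with one row per genome and columns
#' `genome_id`, `phylum`, `class`, `order`, `family`, `genus`, `species`,
#' `organism`. Missing ranks (empty or NA cells) are filled with
#' `"unclassified_<parent taxon>"` so that every genome carries a complete
#' seven-rank lineage; the parent of the phylum rank is taken to be the
#' kingdom ("Fungi"). Filling is deterministic and idempotent.
#'
#' @param path path to a tab-separated file with a header line.
#' @return tibble with columns `genome_id` plus the seven ranks.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"genome_id" %in% names(tab)) {
    stop("taxonomy file has no genome_id column (missing header?)")
  }
  missing <- setdiff(RANKS, names(tab))
  for (m in missing) tab[[m]] <- NA_character_
  tab <- tab[, c("genome_id", RANKS)]
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicate genome_id in taxonomy file")
  }
  fill_lineage(tab)
}

#' Fill missing taxonomy ranks with placeholders
#'
#' @param tab tibble with `genome_id` and the seven rank columns.
#' @return the table with every empty/NA rank replaced by
#'   `"unclassified_<parent taxon>"`.
#' @export
fill_lineage <- function(tab) {
  parent <- rep("Fungi", nrow(tab))
  for (r in RANKS) {
    v <- tab[[r]]
    blank <- is.na(v) | !nzchar(trimws(v))
    v[blank] <- paste0("unclassified_", parent[blank])
    tab[[r]] <- v
    parent <- v
  }
  tab
}

#' Read a BGC table
#'
#' Reads a tab-separated BGC table with columns `bgc_id`, `genome_id`,
#' `bgc_type`, `length_kb`, `domains` and optionally `domain_order`. The
#' sparse domain vector is encoded `"name:weight;name:weight"`; domain names
#' must not contain `:` or `;`. `domain_order` is a `;`-joined list of domain
#' names along the cluster.
#'
#' @param path path to the tab-separated file.
#' @param vocabulary optional ordered character vector of domain names; when
#'   absent it is inferred as the sorted union of names used.
#' @return tibble of BGC records with `domains` and `domain_order` list
#'   columns, plus a `vocabulary` attribute.
#' @export
read_bgc_table <- function(path, vocabulary = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("bgc_id", "genome_id", "bgc_type", "length_kb", "domains")
  if (!all(need %in% names(tab))) {
    stop("BGC table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab$length_kb <- as.numeric(tab$length_kb)
  tab$domains <- lapply(tab$domains, parse_domain_vector)
  if ("domain_order" %in% names(tab)) {
    tab$domain_order <- lapply(tab$domain_order, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  } else {
    tab$domain_order <- lapply(tab$domains, names)
  }
  used <- sort(unique(unlist(lapply(tab$domains, names))))
  if (is.null(vocabulary)) vocabulary <- used
  attr(tab, "vocabulary") <- vocabulary
  tab
}

parse_domain_vector <- function(s) {
  if (is.na(s) || !nzchar(s)) stop("empty domain vector field")
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed domain vector entry: ", parts[bad][1])
  w <- as.numeric(vapply(kv, `[[`, character(1), 2L))
  names(w) <- vapply(kv, `[[`, character(1), 1L)
  if (anyNA(w)) stop("non-numeric domain weight")
  if (any(w < 0)) stop("negative domain weight")
  if (!any(w > 0)) stop("domain vector has no positive weight")
  w
}

#' Read an anchor table
#'
#' @param path tab-separated file with columns `bgc_id`, `compound_id`,
#'   `np_cluster_id`.
#' @return tibble of anchor records.
#' @export
read_anchors <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("bgc_id", "compound_id", "np_cluster_id")
  if (!all(need %in% names(tab))) {
    stop("anchor table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab$bgc_id)) stop("anchor bgc_id not unique")
  tab
}

#' Import a single BGC from hmmscan domain-table output
#'
#' Parses the standard `hmmscan --domtblout` whitespace-delimited layout
#' (comment lines start with `#`). Hits whose independent E-value exceeds
#' `evalue_cutoff` are dropped; the weight of a domain is its per-domain
#' bitscore summed over all retained hits to the same profile name, and
#' `domain_order` lists the retained profile names by first alignment start
#' coordinate.
#'
#' @param path path to a domtblout file.
#' @param genome_id,bgc_id identifiers for the resulting record.
#' @param evalue_cutoff independent-E-value screening threshold
#'   (default `1e-5`).
#' @param bgc_type,length_kb optional metadata carried into the record.
#' @return one-row tibble in the `read_bgc_table()` layout.
#' @export
import_domtblout <- function(path, genome_id, bgc_id, evalue_cutoff = 1e-5,
                             bgc_type = "other", length_kb = 1) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no hits in domain table: ", path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- vapply(fields, length, integer(1)) < 22L
  if (any(short)) stop("malformed domtblout line (fewer than 22 columns)")
  hits <- tibble::tibble(
    target   = vapply(fields, `[[`, character(1), 1L),
    i_evalue = as.numeric(vapply(fields, `[[`, character(1), 13L)),
    score    = as.numeric(vapply(fields, `[[`, character(1), 14L)),
    ali_from = as.numeric(vapply(fields, `[[`, character(1), 18L))
  )
  hits <- hits[hits$i_evalue <= evalue_cutoff, ]
  if (nrow(hits) == 0) stop("no hits pass the E-value cutoff in: ", path)
  w <- tapply(hits$score, hits$target, sum)
  first_pos <- tapply(hits$ali_from, hits$target, min)
  ord <- names(sort(first_pos))
  domains <- setNames(as.numeric(w[ord]), ord)
  tibble::tibble(bgc_id = bgc_id, genome_id = genome_id, bgc_type = bgc_type,
                 length_kb = length_kb, domains = list(domains),
                 domain_order = list(ord))
}

#' Write a dataset to a directory of tab-separated tables
#'
#' Writes `taxonomy.tsv`, `bgcs.tsv`, `anchors.tsv` and `vocabulary.tsv`.
#' Domain weights are serialized at full double precision so that
#' `read_dataset()` round-trips the dataset exactly.
#'
#' @param dataset a `gcf_dataset`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the paths written, invisibly.
#' @export
write_tables <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "gcf_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(taxonomy = file.path(out_dir, "taxonomy.tsv"),
             bgcs = file.path(out_dir, "bgcs.tsv"),
             anchors = file.path(out_dir, "anchors.tsv"),
             vocabulary = file.path(out_dir, "vocabulary.tsv"))
  readr::write_tsv(dataset$taxonomy, paths["taxonomy"], progress = FALSE)

  bgc_flat <- dataset$bgcs
  bgc_flat$domains <- vapply(bgc_flat$domains, function(d) {
    paste(sprintf("%s:%.17g", names(d), as.numeric(d)), collapse = ";")
  }, character(1))
  bgc_flat$domain_order <- vapply(bgc_flat$domain_order, paste,
                                  character(1), collapse = ";")
  bgc_flat$length_kb <- sprintf("%.17g", bgc_flat$length_kb)
  readr::write_tsv(bgc_flat, paths["bgcs"], progress = FALSE)

  readr::write_tsv(dataset$anchors, paths["anchors"], progress = FALSE)
  readr::write_tsv(tibble::tibble(domain = dataset$vocabulary),
                   paths["vocabulary"], progress = FALSE)
  invisible(paths)
}

#' Read a dataset written by [write_tables()]
#'
#' @param dir directory containing `taxonomy.tsv`, `bgcs.tsv`, `anchors.tsv`
#'   and optionally `vocabulary.tsv`.
#' @return a `gcf_dataset`.
#' @export
read_dataset <- function(dir) {
  vocab_path <- file.path(dir, "vocabulary.tsv")
  vocabulary <- if (file.exists(vocab_path)) {
    readr::read_tsv(vocab_path, col_types = "c", progress = FALSE)$domain
  } else NULL
  taxonomy <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  bgcs <- read_bgc_table(file.path(dir, "bgcs.tsv"), vocabulary)
  anchors_path <- file.path(dir, "anchors.tsv")
  anchors <- if (file.exists(anchors_path)) read_anchors(anchors_path) else NULL
  new_dataset(taxonomy, bgcs, anchors,
              vocabulary %||% attr(bgcs, "vocabulary"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
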