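#' Incidence frequency counts for a genome group
#'
#' Summarizes a sub-matrix of the incidence matrix into the frequency
#' counts `Q_j` (number of families detected in exactly `j` of the group's
#' genomes) that drive the incidence-based richness estimators.
#'
#' @param matrix incidence matrix from [incidence()].
#' @param group character vector of genome ids (a non-empty subset of the
#'   columns).
#' @return list of class `incidence_freq`: `n_units` (number of sampling
#'   units, i.e. genomes), `s_obs` (observed distinct families), `q` (named
#'   integer vector, `q[j]` = Q_j for j = 1..n_units).
#' @export
frequencies <- function(matrix, group) {
  if (length(group) == 0) stop("empty genome group")
  if (!all(group %in% colnames(matrix))) {
    stop("group contains genomes absent from the incidence matrix")
  }
  sub <- matrix[, group, drop = FALSE]
  det <- rowSums(sub)
  det <- det[det > 0]
  n <- length(group)
  q <- integer(n)
  if (length(det)) {
    tab <- table(factor(det, levels = seq_len(n)))
    q <- as.integer(tab)
  }
  names(q) <- seq_len(n)
  structure(list(n_units = n, s_obs = length(det), q = q),
            class = "incidence_freq")
}

#' Chao2 asymptotic richness estimator (incidence data)
#'
#' `S_chao2 = S_obs + ((n-1)/n) * Q1^2 / (2*Q2)` when `Q2 > 0`; otherwise
#' the bias-corrected form `S_obs + ((n-1)/n) * Q1*(Q1-1)/2`.
#'
#' @param freq an `incidence_freq`.
#' @return estimated asymptotic richness (always `>= s_obs`).
#' @export
chao2 <- function(freq) {
  stopifnot(inherits(freq, "incidence_freq"), freq$n_units >= 1)
  n <- freq$n_units
  q1 <- if (n >= 1) freq$q[["1"]] else 0L
  q2 <- if (n >= 2) freq$q[["2"]] else 0L
  if (q2 > 0) {
    freq$s_obs + ((n - 1) / n) * q1^2 / (2 * q2)
  } else {
    freq$s_obs + ((n - 1) / n) * q1 * (q1 - 1) / 2
  }
}

# log binomial coefficient, valid for real-valued a >= b >= 0; -Inf when the
# coefficient vanishes
lchoose_real <- function(a, b) {
  ifelse(b > a + 1e-12 | b < 0, -Inf,
         lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1))
}

#' Interpolated (rarefied) richness at t sampling units
#'
#' Expected number of distinct families detected in a random subset of `t`
#' of the `n` sampling units:
#' `S(t) = S_obs - sum_j Q_j * C(n-j, t) / C(n, t)`.
#' Binomial coefficients are evaluated in log space so large `n` is safe;
#' non-integer `t` is accepted (the formula extends continuously through the
#' gamma function), which is how evenly spaced curve knots are evaluated.
#'
#' @param freq an `incidence_freq`.
#' @param t number of units, `1 <= t <= n_units`.
#' @return expected richness at `t`.
#' @export
rarefy <- function(freq, t) {
  stopifnot(inherits(freq, "incidence_freq"))
  n <- freq$n_units
  if (t < 1 || t > n) stop("t must lie in [1, n_units]")
  j <- seq_len(n)
  qj <- freq$q
  keep <- qj > 0
  if (!any(keep)) return(0)
  j <- j[keep]; qj <- qj[keep]
  lr <- lchoose_real(n - j, t) - lchoose_real(n, t)
  freq$s_obs - sum(qj * exp(lr))
}

#' Extrapolated richness t_star units beyond the sample
#'
#' `S(n + t*) = S_obs + Q0_hat * (1 - (1 - Q1/(n*Q0_hat + Q1))^t*)` with
#' `Q0_hat = chao2 - S_obs`. With no uniques (`Q1 = 0`) the estimate stays
#' at `S_obs` for all `t_star`; as `t_star` grows the estimate approaches
#' the Chao2 asymptote.
#'
#' @param freq an `incidence_freq`.
#' @param t_star number of additional units, `>= 0`.
#' @return extrapolated richness at `n_units + t_star`.
#' @export
extrapolate <- function(freq, t_star) {
  stopifnot(inherits(freq, "incidence_freq"), t_star >= 0)
  n <- freq$n_units
  q1 <- freq$q[["1"]]
  if (q1 == 0) return(as.numeric(freq$s_obs))
  q0 <- chao2(freq) - freq$s_obs
  if (q0 <= 0) return(as.numeric(freq$s_obs))
  freq$s_obs + q0 * (1 - (1 - q1 / (n * q0 + q1))^t_star)
}

#' Sample-size-based rarefaction/extrapolation curve and pGCF
#'
#' Evaluates the expected-richness curve at `n_knots` evenly spaced sizes on
#' `[1, endpoint]` (interpolating below the observed number of genomes and
#' extrapolating above it) and reports the estimate at the endpoint as the
#' potential family richness (pGCF) of the group.
#'
#' @param matrix incidence matrix from [incidence()].
#' @param group character vector of genome ids.
#' @param endpoint target number of genomes (default 10000); raised to the
#'   group size with a warning if smaller.
#' @param n_knots number of evaluation points (default 500).
#' @return list of class `rarefaction_curve`: `knots` (tibble `t`,
#'   `estimate`, `method`), `endpoint`, `pgcf`, `s_obs`, `chao2`,
#'   `n_units`.
#' @export
rarefaction_curve <- function(matrix, group, endpoint = 10000L,
                              n_knots = 500L) {
  freq <- frequencies(matrix, group)
  n <- freq$n_units
  if (endpoint < n) {
    warning("endpoint below the number of genomes; raised to ", n)
    endpoint <- n
  }
  ts <- seq(1, endpoint, length.out = n_knots)
  est <- vapply(ts, function(t) {
    if (t <= n) rarefy(freq, t) else extrapolate(freq, t - n)
  }, numeric(1))
  ch <- chao2(freq)
  structure(list(
    knots = tibble::tibble(t = ts, estimate = est,
                           method = ifelse(ts <= n, "interpolated",
                                           "extrapolated")),
    endpoint = endpoint,
    pgcf = if (endpoint <= n) rarefy(freq, endpoint)
           else extrapolate(freq, endpoint - n),
    s_obs = freq$s_obs, chao2 = ch, n_units = n),
    class = "rarefaction_curve")
}

#' Per-genus pGCF table
#'
#' Runs [rarefaction_curve()] for every genus and assembles the potential-
#' richness table used for the promising-genus screen.
#'
#' @param matrix incidence matrix.
#' @param taxonomy matching taxonomy tibble.
#' @param endpoint,n_knots passed to [rarefaction_curve()].
#' @return tibble: `genus`, `n_genomes`, `s_obs`, `chao2`, `pgcf`.
#' @export
genus_pgcf <- function(matrix, taxonomy, endpoint = 10000L,
                       n_knots = 500L) {
  tax <- taxonomy[match(colnames(matrix), taxonomy$genome_id), ]
  rows <- lapply(unique(tax$genus), function(g) {
    group <- tax$genome_id[tax$genus == g]
    cv <- rarefaction_curve(matrix, group, endpoint, n_knots)
    tibble::tibble(genus = g, n_genomes = cv$n_units, s_obs = cv$s_obs,
                   chao2 = cv$chao2, pgcf = cv$pgcf)
  })
  dplyr::bind_rows(rows)
}

#' Flag genera whose known-compound count lags their potential richness
#'
#' A genus is flagged promising when its number of known compounds is
#' strictly below 10 percent of its potential family richness (pGCF).
#' Genera with no entry in the compound-count table are treated as having
#' zero known compounds, with a warning.
#'
#' @param pgcf_table tibble from [genus_pgcf()] (needs `genus`, `pgcf`).
#' @param np_counts tibble with `genus` and `np_count`.
#' @param threshold the flagging ratio (default 0.1).
#' @return `pgcf_table` with `np_count` and logical `promising` columns.
#' @export
promising_genera <- function(pgcf_table, np_counts, threshold = 0.1) {
  idx <- match(pgcf_table$genus, np_counts$genus)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " genus/genera missing an NP count; treated as 0")
  }
  npc <- ifelse(is.na(idx), 0, np_counts$np_count[idx])
  pgcf_table$np_count <- npc
  pgcf_table$promising <- npc < threshold * pgcf_table$pgcf
  pgcf_table
}
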