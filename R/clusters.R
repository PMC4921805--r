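#' Detect clusters of phylogenetically equivalent, closely spaced variants
#'
#' A cluster is a maximal chain of two or more variants assigned to the
#' same branch of the phylogeny in which every adjacent pair of member
#' positions is no more than `max_gap` bp apart (single-linkage chaining;
#' the overall span may exceed `max_gap`). Homoplasic variants enter the
#' detection once per (variant, branch) event, so a recurrent variant can
#' be a member of one cluster on each branch where it mutated.
#'
#' @param events A data.frame with columns `pos` and `branch` (and
#'   optionally `variant`, `region`), one row per mutational event — the
#'   shape produced by [assignment_events()].
#' @param max_gap Maximum distance (bp) between adjacent members; 50 by
#'   default.
#' @return A `snp_cluster_set` data.frame, one row per cluster, ordered by
#'   `start` then `branch`: `id`, `branch`, `start`, `end`, `span`
#'   (`end - start + 1`), `n_members`, list column `members` (variant
#'   names, ordered by position) and, when `events` has a `region` column,
#'   `region`.
#' @examples
#' ev <- data.frame(
#'   variant = c("V1", "V2", "V3"), pos = c(10, 55, 120), branch = "b1"
#' )
#' detect_clusters(ev)
#' @export
detect_clusters <- function(events, max_gap = 50L) {
  stopifnot(all(c("pos", "branch") %in% names(events)), max_gap >= 0)
  if (is.null(events$variant)) {
    events$variant <- if (nrow(events) > 0L) {
      paste0("V", seq_len(nrow(events)))
    } else {
      character(0)
    }
  }
  rows <- list()
  for (br in unique(events$branch)) {
    e <- events[events$branch == br, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    if (nrow(e) < 2L) next
    chain <- cumsum(c(TRUE, diff(e$pos) > max_gap))
    for (ch in unique(chain)) {
      m <- e[chain == ch, , drop = FALSE]
      if (nrow(m) < 2L) next
      row <- data.frame(
        branch = br, start = min(m$pos), end = max(m$pos),
        span = max(m$pos) - min(m$pos) + 1L, n_members = nrow(m),
        stringsAsFactors = FALSE
      )
      if (!is.null(events$region)) row$region <- m$region[1L]
      row$members <- list(m$variant)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      id = integer(0), branch = character(0), start = integer(0),
      end = integer(0), span = integer(0), n_members = integer(0)
    )
    out$members <- list()
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$branch), , drop = FALSE]
    out <- cbind(id = seq_len(nrow(out)), out)
  }
  rownames(out) <- NULL
  structure(out, max_gap = max_gap, class = c("snp_cluster_set", "data.frame"))
}

#' Inclusive span of a cluster
#'
#' The cluster length is the distance between its two outermost members,
#' counted inclusively: `end - start + 1`. Degenerate single-position
#' spans return 1.
#'
#' @param start,end Outermost member positions (1-based), or a
#'   `snp_cluster_set` as `start` with `end` missing.
#' @return Integer span(s) in bp.
#' @examples
#' cluster_span(2866271, 2866356) # 86
#' @export
cluster_span <- function(start, end = NULL) {
  if (is.null(end)) {
    stopifnot(is.data.frame(start))
    return(start$end - start$start + 1L)
  }
  stopifnot(all(end >= start))
  as.integer(end - start + 1L)
}

# count of variants that belong to >= 1 cluster; fast path shared by
# permutation_null and the user-facing clustered_proportion
count_clustered <- function(pos, branch, max_gap) {
  n <- length(pos)
  if (n < 2L) return(0L)
  o <- order(branch, pos)
  p <- pos[o]; b <- branch[o]
  link <- diff(p) <= max_gap & b[-n] == b[-1L]
  sum(c(link, FALSE) | c(FALSE, link))
}

#' Permutation null for the clustered-variant count
#'
#' Emulates the randomization behind the clustered-SNP excess test: in
#' each replicate, `n_variants` distinct positions are drawn uniformly
#' from `1..L` and each is assigned a branch uniformly at random among
#' `n_branches`; the number of variants falling in clusters (per
#' [detect_clusters()] chaining with `max_gap`) is recorded. `lambda` is
#' the mean clustered count across replicates and parameterizes the
#' Poisson tail test of [poisson_tail_p()].
#'
#' @param n_variants Number of variants to place per replicate.
#' @param L Sequence length (bp) positions are drawn from.
#' @param n_branches Number of branches of the phylogeny.
#' @param reps Number of replicates (default 1000).
#' @param max_gap Clustering distance (default 50 bp).
#' @param seed Optional integer seed for reproducibility.
#' @param replace Draw positions with replacement instead of the default
#'   distinct-site sampling.
#' @return A `permutation_null` list: `lambda`, `counts` (per replicate),
#'   `n_variants`, `L`, `n_branches`, `max_gap`, `reps`, `seed`.
#' @export
permutation_null <- function(n_variants, L, n_branches, reps = 1000L,
                             max_gap = 50L, seed = NULL, replace = FALSE) {
  stopifnot(n_variants >= 1L, L > max_gap, n_branches >= 1L, reps >= 1L)
  if (!replace && n_variants > L) {
    stop("cannot place ", n_variants, " distinct positions in ", L, " sites")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    pos <- sample.int(L, n_variants, replace = replace)
    br <- sample.int(n_branches, n_variants, replace = TRUE)
    counts[r] <- count_clustered(pos, br, max_gap)
  }
  structure(
    list(
      lambda = mean(counts), counts = counts, n_variants = n_variants,
      L = L, n_branches = n_branches, max_gap = max_gap, reps = reps,
      seed = seed
    ),
    class = "permutation_null"
  )
}

#' Poisson upper-tail probability of the clustered-variant count
#'
#' P(X >= observed) for X ~ Poisson(lambda), evaluated in log space so
#' extreme tails (p << 1e-300 on the log scale) remain finite; the
#' returned probability underflows to 0 only below the double-precision
#' floor, and the exact base-10 logarithm is attached as attribute
#' `log10_p`.
#'
#' @param observed Observed clustered-variant count (>= 0).
#' @param lambda Null mean, typically from [permutation_null()].
#' @return Upper-tail probability, with attribute `log10_p`.
#' @examples
#' poisson_tail_p(2, 1) # 1 - exp(-1) * 2 = 0.26424...
#' @export
poisson_tail_p <- function(observed, lambda) {
  stopifnot(observed >= 0)
  if (lambda <= 0) stop("lambda must be positive")
  if (observed == 0) {
    return(structure(1, log10_p = 0))
  }
  lp <- ppois(observed - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  structure(exp(lp), log10_p = lp / log(10))
}

#' Clustered-SNP excess test against a permutation null
#'
#' Convenience wrapper: Poisson tail probability of the observed
#' clustered-variant count under the permutation-derived `lambda`. When a
#' finite-replicate null produced `lambda = 0`, the probability is 1 for
#' an observed count of 0; otherwise `lambda` is replaced by the
#' continuity guard `1 / (2 * reps)` and the result flagged.
#'
#' @param null A `permutation_null`.
#' @param observed Observed clustered-variant count.
#' @return A list: `observed`, `lambda`, `p`, `log10_p`, `lambda_guarded`.
#' @export
excess_test <- function(null, observed) {
  stopifnot(inherits(null, "permutation_null"))
  guarded <- FALSE
  lambda <- null$lambda
  if (lambda == 0) {
    if (observed == 0) {
      return(list(
        observed = 0L, lambda = 0, p = 1, log10_p = 0, lambda_guarded = FALSE
      ))
    }
    lambda <- 1 / (2 * null$reps)
    guarded <- TRUE
  }
  p <- poisson_tail_p(observed, lambda)
  list(
    observed = observed, lambda = lambda, p = as.numeric(p),
    log10_p = attr(p, "log10_p"), lambda_guarded = guarded
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table, the same
#' convention as [stats::fisher.test()] for 2x2 tables. Computed from
#' log-scale hypergeometric mass so vanishing tails (p < 1e-300) keep
#' their magnitude.
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(2, 0, 0, 2) # 1/3
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b # row 1 total
  n <- c + d # row 2 total
  k <- a + c # column 1 total
  if (m + n == 0) {
    stop("Fisher test undefined: all cells are zero")
  }
  # a degenerate margin admits a single table, which has probability 1
  if (k == 0 || k == m + n || m == 0 || n == 0) {
    return(1)
  }
  support <- max(0L, k - n):min(k, m)
  lp <- dhyper(support, m, n, k, log = TRUE)
  lobs <- dhyper(a, m, n, k, log = TRUE)
  # relative tolerance as in fisher.test to absorb rounding at ties
  keep <- lp <= lobs + 1e-7
  min(1, sum(exp(lp[keep])))
}

#' Proportion of variants organized in clusters
#'
#' @param clusters A `snp_cluster_set` from [detect_clusters()].
#' @param n_variants Total number of variants in the dataset the clusters
#'   were detected on.
#' @return A list: `k` (distinct variants that are members of at least
#'   one cluster), `n`, `percent` (= 100 k / n).
#' @export
clustered_proportion <- function(clusters, n_variants) {
  stopifnot(n_variants >= 0)
  k <- length(unique(unlist(clusters$members)))
  list(
    k = k, n = n_variants,
    percent = if (n_variants > 0) 100 * k / n_variants else NA_real_
  )
}
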