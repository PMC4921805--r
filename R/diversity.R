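#' Pairwise difference matrix between aligned haplotypes
#'
#' Counts, for every pair of haploid sequences, the aligned sites at which
#' both carry a non-`N` state and the states differ. Runs of consecutive
#' differing columns in which at least one member of the pair is gapped are
#' collapsed so that an indel of any length counts as a single difference.
#'
#' @param haplotypes A `seq_set` (or character vector) of equal-length
#'   aligned sequences.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(haplotypes) {
  seqs <- if (inherits(haplotypes, "seq_set")) {
    setNames(haplotypes$seq, haplotypes$id)
  } else {
    haplotypes
  }
  n <- length(seqs)
  if (length(unique(nchar(seqs))) > 1L) {
    stop("sequences differ in length")
  }
  L <- nchar(seqs[1L])
  M <- matrix(
    unlist(strsplit(seqs, ""), use.names = FALSE),
    nrow = n, ncol = L, byrow = TRUE
  )
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- M[i, ]; b <- M[j, ]
      diff <- a != b & a != "N" & b != "N"
      gap <- diff & (a == "-" | b == "-")
      # each maximal run of gapped differing columns is one indel difference
      n_indel <- sum(gap & !c(FALSE, gap[-L]))
      d[i, j] <- d[j, i] <- sum(diff & !gap) + n_indel
    }
  }
  d
}

#' Nei nucleotide diversity and its standard deviation
#'
#' Estimates per-site nucleotide diversity as the average number of
#' pairwise differences per site,
#' \deqn{\pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2} L},}
#' and, with `variance = "nei"`, its standard deviation as the square root
#' of Nei's (1987, eq. 10.7) sampling variance
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2.}
#' Sites where either member of a pair is `N` are excluded pairwise
#' (`L` is not reduced, matching fixed published region lengths); indel
#' runs contribute one difference regardless of length.
#'
#' @param haplotypes A `seq_set` or character vector of aligned sequences
#'   (n >= 2).
#' @param L Number of sites compared (defaults to the alignment length).
#' @param region Optional region label for the output row.
#' @param variance `"nei"` (default) or `"none"` (sd reported as `NA`).
#' @return A one-row data.frame: `region`, `n`, `L`, `pi`, `sd`.
#' @examples
#' nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT"))
#' @export
nucleotide_diversity <- function(haplotypes, L = NULL, region = NA_character_,
                                 variance = c("nei", "none")) {
  variance <- match.arg(variance)
  seqs <- if (inherits(haplotypes, "seq_set")) haplotypes$seq else haplotypes
  n <- length(seqs)
  if (n < 2L) stop("nucleotide diversity needs at least 2 haplotypes")
  if (is.null(L)) L <- nchar(seqs[1L])
  stopifnot(L > 0)
  d <- pairwise_differences(haplotypes)
  k <- mean(d[upper.tri(d)]) # average pairwise differences
  pi <- k / L
  sd <- if (variance == "none") {
    NA_real_
  } else {
    sqrt(
      (n + 1) * pi / (3 * (n - 1) * L) +
        2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
    )
  }
  data.frame(
    region = region, n = n, L = L, pi = pi, sd = sd,
    stringsAsFactors = FALSE
  )
}

#' Per-region diversity table with pooled rows
#'
#' Computes [nucleotide_diversity()] for each region of an aligned panel
#' and appends pooled rows per region kind (`acceptor-LTR`, `flanking`,
#' ...). Pooling concatenates the regions of a kind: pooled pairwise
#' differences over pooled length.
#'
#' @param haplotypes A `seq_set` of full-locus aligned sequences (one per
#'   sample) in reference coordinates.
#' @param regions A data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive positions in the alignment) and optionally `kind`.
#' @param ref_start Chromosome position of alignment column 1 (used to
#'   translate region coordinates); default 1 means `start`/`end` are
#'   alignment columns already.
#' @return A data.frame of diversity estimates, one row per region plus
#'   one pooled row per kind.
#' @export
diversity_by_region <- function(haplotypes, regions, ref_start = 1L) {
  stopifnot(inherits(haplotypes, "seq_set"))
  if (anyDuplicated(regions$name)) stop("duplicate region names")
  if (any(regions$end < regions$start)) stop("region end < start")
  rows <- list()
  sub <- function(s, e) substr(haplotypes$seq, s, e)
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i] - ref_start + 1L
    e <- regions$end[i] - ref_start + 1L
    rows[[i]] <- nucleotide_diversity(sub(s, e), region = regions$name[i])
  }
  if (!is.null(regions$kind)) {
    for (k in unique(regions$kind)) {
      idx <- which(regions$kind == k)
      cat_seq <- do.call(paste0, lapply(idx, function(i) {
        sub(regions$start[i] - ref_start + 1L, regions$end[i] - ref_start + 1L)
      }))
      rows[[length(rows) + 1L]] <-
        nucleotide_diversity(cat_seq, region = paste0("pooled:", k))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
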