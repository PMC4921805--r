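#' Paralogous sequence variants between an acceptor and a donor
#'
#' Lists every aligned position at which the acceptor reference and a
#' donor paralog carry different non-missing, non-gap bases. Positions are
#' reported in acceptor chromosome coordinates.
#'
#' @param acceptor_ref One-row `seq_set`: the ungapped acceptor reference
#'   with coordinates.
#' @param donor One-row `seq_set`: a donor sequence aligned 1:1 to the
#'   acceptor reference (equal length; use [align_donor()] for raw
#'   paralogs).
#' @return A `psv_set` data.frame: `pos`, `acceptor_base`, `donor_base`,
#'   sorted by position, with the donor id as attribute `donor`.
#' @export
identify_psvs <- function(acceptor_ref, donor) {
  stopifnot(inherits(acceptor_ref, "seq_set"), nrow(acceptor_ref) == 1L)
  stopifnot(nrow(donor) == 1L)
  if (nchar(donor$seq) != nchar(acceptor_ref$seq)) {
    stop("donor must be aligned to the acceptor (equal length)")
  }
  a <- strsplit(acceptor_ref$seq, "")[[1L]]
  d <- strsplit(donor$seq, "")[[1L]]
  informative <- a %in% c("A", "C", "G", "T") & d %in% c("A", "C", "G", "T")
  idx <- which(informative & a != d)
  start <- if (is.na(acceptor_ref$start)) 1L else acceptor_ref$start
  structure(
    data.frame(
      pos = start + idx - 1L,
      acceptor_base = a[idx], donor_base = d[idx],
      stringsAsFactors = FALSE
    ),
    donor = donor$id, class = c("psv_set", "data.frame")
  )
}

#' Align a donor paralog to the acceptor by ungapped sliding
#'
#' A deliberately simple exact-match aligner for near-equal-length
#' paralogs: the donor is slid across the acceptor over a window of
#' offsets and the offset maximizing base matches is kept; the donor is
#' then trimmed/padded with `N` to acceptor length. Gapped alignment is
#' out of scope — supply pre-aligned donors when indels matter.
#'
#' @param acceptor_ref One-row `seq_set`, ungapped.
#' @param donor One-row `seq_set`, ungapped.
#' @param max_shift Maximum |offset| explored (default 30 bp).
#' @return `donor` with its sequence replaced by the acceptor-aligned,
#'   N-padded version (same length as the acceptor).
#' @export
align_donor <- function(acceptor_ref, donor, max_shift = 30L) {
  a <- strsplit(acceptor_ref$seq, "")[[1L]]
  d <- strsplit(donor$seq, "")[[1L]]
  La <- length(a); Ld <- length(d)
  best <- NULL; best_score <- -1L
  for (off in -max_shift:max_shift) {
    # donor base j aligns to acceptor position j + off
    j <- seq_len(Ld)
    tgt <- j + off
    ok <- tgt >= 1L & tgt <= La
    score <- sum(d[j[ok]] == a[tgt[ok]])
    if (score > best_score) {
      best_score <- score
      best <- off
    }
  }
  aligned <- rep("N", La)
  j <- seq_len(Ld)
  tgt <- j + best
  ok <- tgt >= 1L & tgt <= La
  aligned[tgt[ok]] <- d[j[ok]]
  donor$seq <- paste(aligned, collapse = "")
  donor
}

#' Drop clusters too short for a meaningful donor search
#'
#' Clusters spanning fewer than `min_span` bp are removed (and reported in
#' a message): a 2-bp derived tract matches paralogs all over the genome
#' by chance, so identity over it carries no evidence of conversion.
#'
#' @param clusters A `snp_cluster_set`.
#' @param min_span Minimum inclusive span in bp (default 3).
#' @return The filtered `snp_cluster_set`.
#' @export
filter_clusters_for_donor_search <- function(clusters, min_span = 3L) {
  drop <- clusters$span < min_span
  if (any(drop)) {
    message(
      "excluding ", sum(drop), " cluster(s) with span < ", min_span,
      " bp from donor search: ", paste(clusters$id[drop], collapse = ", ")
    )
  }
  out <- clusters[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derived state of a cluster over its span
#'
#' The acceptor reference bases across the cluster span with the derived
#' allele substituted at every member position — the query sequence for
#' the exact-identity donor search.
#'
#' @param acceptor_ref One-row ungapped `seq_set` covering the span.
#' @param cluster One row of a `snp_cluster_set`.
#' @param assignments A `branch_assignment` holding the members' polarity.
#' @return Character scalar of length `cluster$span`.
#' @export
build_derived_tract <- function(acceptor_ref, cluster, assignments) {
  stopifnot(nrow(cluster) == 1L)
  start <- if (is.na(acceptor_ref$start)) 1L else acceptor_ref$start
  ref_chars <- strsplit(acceptor_ref$seq, "")[[1L]]
  s_idx <- cluster$start - start + 1L
  e_idx <- cluster$end - start + 1L
  if (s_idx < 1L || e_idx > length(ref_chars)) {
    stop("cluster span outside the acceptor reference")
  }
  tract <- ref_chars[s_idx:e_idx]
  members <- cluster$members[[1L]]
  rows <- match(members, assignments$name)
  if (anyNA(rows)) {
    stop(
      "no polarity for cluster member(s): ",
      paste(members[is.na(rows)], collapse = ", ")
    )
  }
  for (r in rows) {
    if (assignments$derived_allele[r] == assignments$ancestral_allele[r]) {
      stop("polarity violation at ", assignments$name[r],
           ": derived equals ancestral")
    }
    off <- assignments$pos[r] - cluster$start + 1L
    if (off < 1L || off > length(tract)) {
      stop("member ", assignments$name[r], " outside the cluster span")
    }
    tract[off] <- assignments$derived_allele[r]
  }
  paste(tract, collapse = "")
}

#' Match donor candidates against the derived tract of a cluster
#'
#' A donor-library entry is a hit iff its acceptor-aligned bases over the
#' cluster span are 100% identical to the derived tract — a single
#' mismatch destroys the hit. Donors not covering the span (out of range,
#' or carrying `N`/gaps inside it) are skipped with a warning.
#'
#' @param derived_tract Character scalar from [build_derived_tract()].
#' @param cluster One row of a `snp_cluster_set` (for the span).
#' @param donor_library `seq_set` of donors aligned 1:1 to the acceptor
#'   reference (equal length; see [align_donor()]).
#' @param acceptor_ref One-row ungapped `seq_set` the donors are aligned
#'   to.
#' @return A `donor_hit` data.frame, one row per hit: `cluster_id`,
#'   `donor_id`, `chrom`, `start`, `end`, `identity` (all `TRUE`),
#'   `multi_donor` (more than one hit for this cluster).
#' @export
match_donors <- function(derived_tract, cluster, donor_library, acceptor_ref) {
  stopifnot(nrow(cluster) == 1L, inherits(donor_library, "seq_set"))
  start <- if (is.na(acceptor_ref$start)) 1L else acceptor_ref$start
  s_idx <- cluster$start - start + 1L
  e_idx <- cluster$end - start + 1L
  hits <- list()
  for (i in seq_len(nrow(donor_library))) {
    dseq <- donor_library$seq[i]
    if (nchar(dseq) != nchar(acceptor_ref$seq)) {
      warning("donor ", donor_library$id[i],
              " is not aligned to the acceptor; skipped")
      next
    }
    window <- substr(dseq, s_idx, e_idx)
    if (grepl("[N-]", window)) {
      warning("donor ", donor_library$id[i],
              " does not cover the cluster span; skipped")
      next
    }
    if (identical(window, derived_tract)) {
      hits[[length(hits) + 1L]] <- data.frame(
        cluster_id = cluster$id, donor_id = donor_library$id[i],
        chrom = donor_library$chrom[i], start = donor_library$start[i],
        end = donor_library$end[i], identity = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits) == 0L) {
    data.frame(
      cluster_id = integer(0), donor_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), identity = logical(0)
    )
  } else {
    do.call(rbind, hits)
  }
  out$multi_donor <- rep(nrow(out) > 1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Minimum and maximum conversion-tract bounds for a cluster
#'
#' The minimum tract is the observed converted span (`end - start + 1`).
#' The maximum tract is bounded by the nearest paralogous sequence
#' variants flanking the cluster at which the converted chromosome still
#' carries the acceptor base (non-converted PSVs): with flanking PSVs at
#' positions `L` and `R`, the default `"between"` convention counts the
#' bases strictly between them (`R - L - 1`); `"inclusive"` counts
#' `R - L + 1`. If no non-converted PSV exists on a side within the
#' locus, the maximum is `NA` (unbounded within the data).
#'
#' @param cluster One row of a `snp_cluster_set`, or a list/data.frame
#'   with `start` and `end`.
#' @param psvs A `psv_set` for the donor under consideration.
#' @param converted_bases Optional named character vector giving the base
#'   carried by the converted chromosome at PSV positions (names =
#'   positions). When supplied, only PSVs at which it equals the acceptor
#'   base count as non-converted; by default every PSV outside the
#'   cluster span is taken as non-converted.
#' @param mode `"between"` (default) or `"inclusive"`.
#' @return A list: `min_tract`, `max_tract` (bp; `max_tract` may be `NA`).
#' @examples
#' psvs <- data.frame(
#'   pos = c(100, 200), acceptor_base = c("A", "G"), donor_base = c("T", "C")
#' )
#' tract_bounds(list(start = 130, end = 160), psvs) # min 31, max 99
#' @export
tract_bounds <- function(cluster, psvs, converted_bases = NULL,
                         mode = c("between", "inclusive")) {
  mode <- match.arg(mode)
  s <- cluster$start; e <- cluster$end
  min_tract <- as.integer(e - s + 1L)
  keep <- rep(TRUE, nrow(psvs))
  if (!is.null(converted_bases)) {
    obs <- converted_bases[as.character(psvs$pos)]
    keep <- !is.na(obs) & obs == psvs$acceptor_base
  }
  nc <- psvs$pos[keep]
  left <- nc[nc < s]
  right <- nc[nc > e]
  if (length(left) == 0L || length(right) == 0L) {
    return(list(min_tract = min_tract, max_tract = NA_integer_))
  }
  l <- max(left); r <- min(right)
  max_tract <- if (mode == "between") r - l - 1L else r - l + 1L
  list(min_tract = min_tract, max_tract = as.integer(max_tract))
}

#' Classify a gene-conversion event by donor location
#'
#' @param donor_chrom,donor_start,donor_end Donor region coordinates.
#' @param acceptor_chrom Acceptor chromosome (normally the Y).
#' @param element_start,element_end Boundaries of the acceptor element
#'   itself; a donor interval contained in them is intra-element
#'   conversion between duplicated stretches of the same LTR.
#' @return One of `"intra-LTR"`, `"Y-to-Y"`, `"X-to-Y"`,
#'   `"autosome-to-Y"`, `"inter-chromosomal"`.
#' @export
classify_conversion <- function(donor_chrom, donor_start, donor_end,
                                acceptor_chrom, element_start = NA,
                                element_end = NA) {
  norm <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))
  dc <- norm(donor_chrom); ac <- norm(acceptor_chrom)
  known <- c("X", "Y", as.character(1:22))
  if (!dc %in% known) stop("unknown chromosome label: ", donor_chrom)
  if (!ac %in% known) stop("unknown chromosome label: ", acceptor_chrom)
  if (dc == ac && !is.na(element_start) && !is.na(element_end) &&
      donor_start >= element_start && donor_end <= element_end) {
    return("intra-LTR")
  }
  if (ac == "Y") {
    if (dc == "Y") return("Y-to-Y")
    if (dc == "X") return("X-to-Y")
    return("autosome-to-Y")
  }
  # non-Y acceptors fall outside the named Y-centric classes
  if (dc == ac) "intra-chromosomal" else "inter-chromosomal"
}
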