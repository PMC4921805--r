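#' Polarize variants on a fixed rooted tree and assign mutational events
#'
#' For each biallelic variant, internal-node states are reconstructed by
#' Fitch small parsimony on the fixed tree (the tree is never re-estimated).
#' The ancestral allele is the state taken by the root under parsimony;
#' when the root state is ambiguous the tie is broken by the allele carried
#' by a designated outgroup tip, or, absent that, by the major allele —
#' and the variant is flagged `placement_ambiguous`. Remaining ambiguity in
#' the refinement is resolved deterministically by propagating the parent
#' state wherever the child's state set allows it, so output never depends
#' on tip order. Each state change along an edge becomes one mutational
#' event on the corresponding named branch: `forward` events introduce the
#' derived allele, `back` events restore the ancestral allele. Missing
#' genotypes (`N`) do not constrain their tip; tips absent from the sample
#' set are likewise unconstrained.
#'
#' @param variants A [variant_table()] whose sample columns match tips.
#' @param tree A `"phylo"` tree from [read_newick_tree()].
#' @param outgroup Optional tip name used to break root-state ties — the
#'   basal lineage whose allele is taken as ancestral, mirroring how
#'   polarity is fixed from prior haplogroup knowledge on the human Y.
#' @param on_multiallelic `"error"` (default) rejects variants with more
#'   than two observed alleles rather than guessing a polarization;
#'   `"drop"` skips them with a warning (used by the pipeline, where
#'   they are reported but not polarized).
#' @return A `branch_assignment` data.frame with one row per polarized
#'   variant: `name`, `chrom`, `pos`, `ancestral_allele`, `derived_allele`,
#'   `n_events`, `homoplasic` (`n_events > 1`), `placement_ambiguous`, and
#'   a list column `events` of data.frames (`branch`, `direction`).
#'   Variants that are all-missing or non-segregating are dropped with a
#'   warning.
#' @export
polarize_and_assign <- function(variants, tree, outgroup = NULL,
                                on_multiallelic = c("error", "drop")) {
  stopifnot(inherits(variants, "variant_table"), inherits(tree, "phylo"))
  on_multiallelic <- match.arg(on_multiallelic)
  samples <- variant_samples(variants)
  missing_tip <- setdiff(samples, tree$tip.label)
  if (length(missing_tip) > 0L) {
    stop("sample not on tree: ", paste(missing_tip, collapse = ", "))
  }
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  ntip <- length(tree$tip.label)
  bt <- branch_table(tree)
  po <- ape::reorder.phylo(tree, "postorder")$edge # children before parents
  pre <- tree$edge                                 # cladewise: parents first
  branch_of_edge <- setNames(bt$branch, paste(bt$parent, bt$child))
  geno <- genotype_matrix(variants)
  tip_sample <- match(tree$tip.label, samples) # NA for tips without data

  rows <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    alleles <- c(variants$ref_allele[v], variants$alt_allele[v])
    g <- geno[v, ]
    obs <- g[g != "N"]
    if (length(obs) == 0L) {
      warning("variant ", variants$name[v], " has all-missing genotypes; skipped")
      next
    }
    if (variants$multiallelic[v] || !all(obs %in% alleles)) {
      if (on_multiallelic == "error") {
        stop("multi-allelic variant ", variants$name[v], " is not supported")
      }
      warning("multi-allelic variant ", variants$name[v], " skipped")
      next
    }
    if (length(unique(obs)) == 1L) {
      warning("variant ", variants$name[v], " is non-segregating; skipped")
      next
    }

    # Fitch up-pass with 2-bit state sets: 1 = allele 1, 2 = allele 2, 3 = both
    mask <- integer(ntip + tree$Nnode)
    tg <- g[tip_sample]
    mask[seq_len(ntip)] <- ifelse(
      is.na(tip_sample) | tg == "N", 3L, match(tg, alleles)
    )
    and_acc <- rep(3L, ntip + tree$Nnode)
    or_acc <- integer(ntip + tree$Nnode)
    for (e in seq_len(nrow(po))) {
      p <- po[e, 1L]; ch <- po[e, 2L]
      if (ch > ntip) {
        mask[ch] <- if (and_acc[ch] != 0L) and_acc[ch] else or_acc[ch]
      }
      and_acc[p] <- bitwAnd(and_acc[p], mask[ch])
      or_acc[p] <- bitwOr(or_acc[p], mask[ch])
    }
    root <- po[nrow(po), 1L]
    mask[root] <- if (and_acc[root] != 0L) and_acc[root] else or_acc[root]

    ambiguous <- mask[root] == 3L
    anc_idx <- if (!ambiguous) {
      mask[root]
    } else if (!is.null(outgroup) && g[outgroup] %in% alleles) {
      match(g[outgroup], alleles)
    } else {
      counts <- tabulate(match(obs, alleles), 2L)
      which.max(counts) # ties resolve to the first (reference) allele
    }

    # down-pass: keep the parent state whenever the child's set allows it
    state <- integer(ntip + tree$Nnode)
    state[root] <- anc_idx
    ev_branch <- character(0)
    ev_dir <- character(0)
    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1L]; ch <- pre[e, 2L]
      pbit <- state[p]
      state[ch] <- if (bitwAnd(mask[ch], pbit) != 0L) pbit else mask[ch]
      if (state[ch] != state[p]) {
        ev_branch <- c(ev_branch, branch_of_edge[[paste(p, ch)]])
        ev_dir <- c(
          ev_dir,
          if (state[ch] == anc_idx) "back" else "forward"
        )
      }
    }

    rows[[v]] <- data.frame(
      name = variants$name[v], chrom = variants$chrom[v],
      pos = variants$pos[v],
      ancestral_allele = alleles[anc_idx],
      derived_allele = alleles[3L - anc_idx],
      n_events = length(ev_branch),
      homoplasic = length(ev_branch) > 1L,
      placement_ambiguous = ambiguous,
      stringsAsFactors = FALSE
    )
    rows[[v]]$events <- list(data.frame(
      branch = ev_branch, direction = ev_dir, stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(
      name = character(0), chrom = character(0), pos = integer(0),
      ancestral_allele = character(0), derived_allele = character(0),
      n_events = integer(0), homoplasic = logical(0),
      placement_ambiguous = logical(0)
    )
    out$events <- list()
  }
  rownames(out) <- NULL
  structure(out, class = c("branch_assignment", "data.frame"))
}

#' Flatten branch assignments to one row per mutational event
#'
#' @param assignments A `branch_assignment` from [polarize_and_assign()].
#' @return A data.frame with columns `variant`, `pos`, `branch`,
#'   `direction`, one row per event; the shape [detect_clusters()] expects.
#' @export
assignment_events <- function(assignments) {
  stopifnot(inherits(assignments, "branch_assignment"))
  if (nrow(assignments) == 0L) {
    return(data.frame(
      variant = character(0), pos = integer(0),
      branch = character(0), direction = character(0)
    ))
  }
  pieces <- lapply(seq_len(nrow(assignments)), function(i) {
    ev <- assignments$events[[i]]
    data.frame(
      variant = assignments$name[i], pos = assignments$pos[i],
      branch = ev$branch, direction = ev$direction,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Summarize mutational events and homoplasy
#'
#' `total_events` sums events over variants; `recurrent_events` counts the
#' extra events beyond the first for homoplasic variants, so
#' `total_events = n_variants + recurrent_events` for biallelic variants.
#'
#' @param assignments A `branch_assignment`.
#' @return A list: `n_variants`, `total_events`, `n_homoplasic`,
#'   `recurrent_events`, `percent_homoplasic`.
#' @export
count_events <- function(assignments) {
  stopifnot(inherits(assignments, "branch_assignment"))
  n <- nrow(assignments)
  total <- sum(assignments$n_events)
  nh <- sum(assignments$homoplasic)
  list(
    n_variants = n,
    total_events = total,
    n_homoplasic = nh,
    recurrent_events = sum(pmax(assignments$n_events - 1L, 0L)),
    percent_homoplasic = if (n > 0L) 100 * nh / n else NA_real_
  )
}

#' Compare homoplasy rates between two datasets
#'
#' Two-sided Fisher's exact test on the 2x2 table of homoplasic vs
#' non-homoplasic variant counts in two studies.
#'
#' @param k1,n1 Homoplasic count and total in dataset 1.
#' @param k2,n2 Homoplasic count and total in dataset 2.
#' @return Two-sided p-value.
#' @export
compare_homoplasy_rates <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  fisher_exact_two_sided(k1, n1 - k1, k2, n2 - k2)
}
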