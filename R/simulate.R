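#' Simulation configuration
#'
#' Bundles and validates the parameters of the forward simulator. The
#' defaults emulate the empirical scale of Y-chromosome LTR resequencing
#' panels: a 16-tip fixed phylogeny (30 branches), a 1550 bp locus,
#' donor paralogs diverged at ~2% (paralogous sequence variants), about
#' one point mutation per branch, occasional conversion events, and
#' geometric tract lengths with mean 100 bp — matching observed maximum
#' tracts of tens to hundreds of bp.
#'
#' @param seed Integer seed; every random draw of the simulator descends
#'   from it, so identical configs give byte-identical outputs.
#' @param n_tips Number of haploid samples (tips of the generated
#'   asymmetric tree) when `tree` is not supplied.
#' @param tree Optional Newick string or `"phylo"` for a user topology.
#' @param locus_length Locus length in bp.
#' @param n_donors Number of donor paralogs in the library.
#' @param psv_rate Per-bp donor-acceptor divergence (0 to 0.2).
#' @param mut_rate Expected point mutations per branch.
#' @param conv_rate Expected conversion events per branch.
#' @param tract_mean Mean of the geometric conversion-tract length (bp).
#' @param error_rate Optional per-base sequencing-error rate applied to
#'   the tips (0 by default: chromatogram-grade data).
#' @param chrom,locus_start Coordinate frame of the simulated locus.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_tips = 16L, tree = NULL,
                       locus_length = 1550L, n_donors = 5L,
                       psv_rate = 0.02, mut_rate = 1, conv_rate = 0.3,
                       tract_mean = 100, error_rate = 0,
                       chrom = "chrY", locus_start = 1L) {
  stopifnot(
    n_tips >= 2L, locus_length > tract_mean, n_donors >= 1L,
    psv_rate >= 0, psv_rate <= 0.2, mut_rate >= 0, conv_rate >= 0,
    tract_mean >= 1, error_rate >= 0, error_rate < 1, locus_start >= 1L
  )
  structure(
    list(
      seed = as.integer(seed), n_tips = as.integer(n_tips), tree = tree,
      locus_length = as.integer(locus_length),
      n_donors = as.integer(n_donors), psv_rate = psv_rate,
      mut_rate = mut_rate, conv_rate = conv_rate, tract_mean = tract_mean,
      error_rate = error_rate, chrom = chrom,
      locus_start = as.integer(locus_start)
    ),
    class = "sim_config"
  )
}

#' Asymmetric (caterpillar) rooted tree with n tips
#'
#' A fully pectinate rooted binary topology with tips `S01..Snn`; a
#' rooted binary tree with n tips has 2n - 2 named branches. Used as the
#' default scaffold standing in for a ladder-like haplogroup phylogeny.
#'
#' @param n_tips Number of tips (>= 2).
#' @return A `"phylo"` tree with auto-named internal branches.
#' @export
caterpillar_tree <- function(n_tips) {
  stopifnot(n_tips >= 2L)
  tips <- sprintf("S%02d", seq_len(n_tips))
  txt <- tips[n_tips]
  for (i in (n_tips - 1L):1L) {
    txt <- paste0("(", tips[i], ",", txt, ")")
  }
  read_newick_tree(text = paste0(txt, ";"))
}

DNA <- c("A", "C", "G", "T")

#' Generate a library of diverged donor paralogs
#'
#' Each donor starts as a copy of the ancestral acceptor sequence and is
#' mutated at Binomial(L, `psv_rate`) uniformly chosen positions to a
#' random different base; the mismatching positions are emitted as the
#' donor's paralogous sequence variants (PSVs), so [identify_psvs()] on
#' the output reproduces them exactly.
#'
#' @param ancestral_seq Ancestral acceptor sequence (character scalar).
#' @param n_donors Number of donors.
#' @param psv_rate Per-bp divergence in `[0, 0.2]`.
#' @param locus_start Chromosome position of base 1 (PSV coordinates).
#' @param donor_chroms Chromosomes the donor coordinates are placed on,
#'   recycled over donors (affects [classify_conversion()] only).
#' @return A list: `library` (a `seq_set`, ids `D1..`, with coordinate
#'   headers) and `psvs` (named list of `psv_set` data.frames).
#' @export
generate_donor_library <- function(ancestral_seq, n_donors, psv_rate,
                                   locus_start = 1L, donor_chroms = "chrY") {
  anc <- strsplit(toupper(ancestral_seq), "")[[1L]]
  L <- length(anc)
  chroms <- rep_len(donor_chroms, n_donors)
  seqs <- character(n_donors)
  psvs <- vector("list", n_donors)
  ids <- paste0("D", seq_len(n_donors))
  starts <- ends <- integer(n_donors)
  for (i in seq_len(n_donors)) {
    d <- anc
    k <- rbinom(1L, L, psv_rate)
    if (k > 0L) {
      at <- sample.int(L, k)
      d[at] <- vapply(
        d[at], function(b) sample(setdiff(DNA, b), 1L), ""
      )
    }
    seqs[i] <- paste(d, collapse = "")
    idx <- which(d != anc)
    psvs[[i]] <- structure(
      data.frame(
        pos = locus_start + idx - 1L,
        acceptor_base = anc[idx], donor_base = d[idx],
        stringsAsFactors = FALSE
      ),
      donor = ids[i], class = c("psv_set", "data.frame")
    )
    # arbitrary non-overlapping paralog coordinates per donor
    starts[i] <- 1000000L * i
    ends[i] <- starts[i] + L - 1L
  }
  names(psvs) <- ids
  lib <- seq_set(
    id = paste0(chroms, ":", starts, "-", ends),
    seq = seqs, chrom = chroms, start = starts, end = ends
  )
  lib$id <- ids
  list(library = lib, psvs = psvs)
}

#' Simulate a haploid panel evolving on a fixed tree with gene conversion
#'
#' The ancestral sequence evolves down the tree; on every branch the
#' simulator applies Poisson(`mut_rate`) point mutations at distinct
#' uniform positions and Poisson(`conv_rate`) conversion events, each
#' copying a tract (uniform start, geometric length with mean
#' `tract_mean`, truncated at the locus end) verbatim from a uniformly
#' chosen donor's ancestral sequence. Donor evolution is not simulated,
#' which keeps the ground truth unambiguous. Tip sequences, the variant
#' table called against the known ancestor, and a complete event ledger
#' are returned.
#'
#' @param config A [sim_config()].
#' @return An `ltr_sim` list: `config`, `tree`, `ancestor` (one-row
#'   `seq_set` with coordinates), `tips` (`seq_set`), `donors`
#'   (`seq_set`), `psvs` (list of `psv_set`), `variants`
#'   ([variant_table()]), `ref_specific`, and `truth` (data.frame with
#'   `branch`, `kind`, `start`, `end`, `donor`, `n_changed` in
#'   chromosome coordinates).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$locus_length
  tree <- if (is.null(config$tree)) {
    caterpillar_tree(config$n_tips)
  } else if (inherits(config$tree, "phylo")) {
    config$tree
  } else {
    read_newick_tree(text = config$tree)
  }
  bt <- branch_table(tree)
  ntip <- length(tree$tip.label)

  anc <- sample(DNA, L, replace = TRUE)
  lib <- generate_donor_library(
    paste(anc, collapse = ""), config$n_donors, config$psv_rate,
    locus_start = config$locus_start
  )
  donor_chars <- lapply(lib$library$seq, function(s) strsplit(s, "")[[1L]])

  node_seq <- vector("list", ntip + tree$Nnode)
  root <- tree$edge[1L, 1L]
  node_seq[[root]] <- anc
  truth <- list()
  for (e in seq_len(nrow(tree$edge))) { # cladewise: parents first
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    s <- node_seq[[p]]
    br <- bt$branch[e]
    n_mut <- rpois(1L, config$mut_rate)
    if (n_mut > 0L) {
      at <- sample.int(L, min(n_mut, L))
      for (j in at) {
        new <- sample(setdiff(DNA, s[j]), 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          branch = br, kind = "mutation",
          start = config$locus_start + j - 1L,
          end = config$locus_start + j - 1L,
          donor = NA_character_, n_changed = 1L,
          stringsAsFactors = FALSE
        )
        s[j] <- new
      }
    }
    n_conv <- rpois(1L, config$conv_rate)
    if (n_conv > 0L) {
      for (k in seq_len(n_conv)) {
        tstart <- sample.int(L, 1L)
        tlen <- 1L + rgeom(1L, 1 / config$tract_mean)
        tend <- min(L, tstart + tlen - 1L)
        di <- sample.int(config$n_donors, 1L)
        seg <- donor_chars[[di]][tstart:tend]
        truth[[length(truth) + 1L]] <- data.frame(
          branch = br, kind = "conversion",
          start = config$locus_start + tstart - 1L,
          end = config$locus_start + tend - 1L,
          donor = lib$library$id[di],
          n_changed = sum(s[tstart:tend] != seg),
          stringsAsFactors = FALSE
        )
        s[tstart:tend] <- seg
      }
    }
    node_seq[[ch]] <- s
  }

  tip_seqs <- vapply(
    seq_len(ntip),
    function(i) {
      s <- node_seq[[i]]
      if (config$error_rate > 0) {
        err <- which(runif(L) < config$error_rate)
        for (j in err) s[j] <- sample(setdiff(DNA, s[j]), 1L)
      }
      paste(s, collapse = "")
    },
    ""
  )
  tips <- seq_set(id = tree$tip.label, seq = tip_seqs)
  ancestor <- seq_set(
    id = paste0(
      config$chrom, ":", config$locus_start, "-",
      config$locus_start + L - 1L
    ),
    seq = paste(anc, collapse = ""),
    chrom = config$chrom, start = config$locus_start,
    end = config$locus_start + L - 1L
  )
  called <- call_variants(tips, ancestor)

  truth_df <- if (length(truth) == 0L) {
    data.frame(
      branch = character(0), kind = character(0), start = integer(0),
      end = integer(0), donor = character(0), n_changed = integer(0)
    )
  } else {
    do.call(rbind, truth)
  }
  structure(
    list(
      config = config, tree = tree, ancestor = ancestor, tips = tips,
      donors = lib$library, psvs = lib$psvs, variants = called$variants,
      ref_specific = called$ref_specific, truth = truth_df
    ),
    class = "ltr_sim"
  )
}

# tip labels below a named branch (the branch's child node and its clade)
tips_below <- function(tree, branch) {
  bt <- branch_table(tree)
  node <- bt$child[match(branch, bt$branch)]
  if (is.na(node)) stop("unknown branch: ", branch)
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  while (length(todo) > 0L) {
    nd <- todo[1L]; todo <- todo[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  tree$tip.label[tips]
}

#' Recovery metrics of cluster/donor detection against simulated truth
#'
#' A simulated conversion event is *detectable* when its tract covers at
#' least `min_psvs` of the chosen donor's PSVs (fewer leave too faint a
#' footprint to ever form a cluster, so such events are excluded from the
#' recall denominator). A detected cluster is a true positive when its
#' span overlaps a true conversion tract assigned to the same branch.
#'
#' * `recall`: detected fraction of detectable conversion events;
#' * `precision`: fraction of clusters with at least `min_psvs` members
#'   that overlap some true conversion tract on their branch;
#' * `tract_coverage`: among detected detectable events, the fraction
#'   whose true tract length lies within the reported
#'   `[min_tract, max_tract]` bounds (computed via [tract_bounds()] with
#'   the converted bases observed on a descendant tip).
#'
#' Metrics with an empty denominator are `NA`.
#'
#' @param sim An `ltr_sim` from [simulate_dataset()].
#' @param clusters A `snp_cluster_set` detected on the simulated data.
#' @param min_psvs Detectability threshold (default 2).
#' @return A list: `recall`, `precision`, `tract_coverage`,
#'   `n_detectable`, `n_clusters_considered`.
#' @export
truth_report <- function(sim, clusters, min_psvs = 2L) {
  stopifnot(inherits(sim, "ltr_sim"))
  conv <- sim$truth[sim$truth$kind == "conversion", , drop = FALSE]
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

  covered <- integer(nrow(conv))
  for (i in seq_len(nrow(conv))) {
    p <- sim$psvs[[conv$donor[i]]]
    covered[i] <- sum(p$pos >= conv$start[i] & p$pos <= conv$end[i])
  }
  detectable <- covered >= min_psvs

  detected <- logical(nrow(conv))
  hit_cluster <- rep(NA_integer_, nrow(conv))
  for (i in seq_len(nrow(conv))) {
    m <- which(
      clusters$branch == conv$branch[i] &
        overlaps(clusters$start, clusters$end, conv$start[i], conv$end[i])
    )
    detected[i] <- length(m) > 0L
    if (detected[i]) hit_cluster[i] <- m[1L]
  }

  considered <- which(clusters$n_members >= min_psvs)
  matched <- vapply(considered, function(ci) {
    any(
      conv$branch == clusters$branch[ci] &
        overlaps(conv$start, conv$end, clusters$start[ci], clusters$end[ci])
    )
  }, TRUE)

  idx <- which(detectable & detected)
  in_bounds <- logical(length(idx))
  for (t in seq_along(idx)) {
    i <- idx[t]
    ci <- hit_cluster[i]
    tip <- tips_below(sim$tree, conv$branch[i])[1L]
    tip_chars <- strsplit(sim$tips$seq[match(tip, sim$tips$id)], "")[[1L]]
    p <- sim$psvs[[conv$donor[i]]]
    conv_bases <- setNames(
      tip_chars[p$pos - sim$config$locus_start + 1L], as.character(p$pos)
    )
    b <- tract_bounds(clusters[ci, ], p, converted_bases = conv_bases)
    true_len <- conv$end[i] - conv$start[i] + 1L
    in_bounds[t] <- true_len >= b$min_tract &&
      (is.na(b$max_tract) || true_len <= b$max_tract)
  }

  list(
    recall = if (sum(detectable) > 0L) mean(detected[detectable]) else NA_real_,
    precision = if (length(considered) > 0L) mean(matched) else NA_real_,
    tract_coverage = if (length(idx) > 0L) mean(in_bounds) else NA_real_,
    n_detectable = sum(detectable),
    n_clusters_considered = length(considered)
  )
}

#' Write a simulated dataset to disk
#'
#' Emits the tips, ancestor and donor library as FASTA, the variant table
#' and truth ledger as TSV, and the exact configuration as YAML so a run
#' can be reproduced from its output directory alone.
#'
#' @param sim An `ltr_sim`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ltr_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_tips <- file.path(dir, "tips.fasta")
  write_fasta(sim$tips, f_tips)
  f_anc <- file.path(dir, "ancestor.fasta")
  write_fasta(sim$ancestor, f_anc)
  f_don <- file.path(dir, "donors.fasta")
  don <- sim$donors
  don$id <- paste0(don$chrom, ":", don$start, "-", don$end)
  write_fasta(don, f_don)
  f_var <- file.path(dir, "variants.tsv")
  write_variant_table(sim$variants, f_var)
  f_truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, f_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  f_cfg <- file.path(dir, "sim_config.yaml")
  cfg <- sim$config
  cfg$tree <- if (is.null(cfg$tree)) NULL else ape::write.tree(sim$tree)
  yaml::write_yaml(unclass(cfg), f_cfg)
  invisible(c(f_tips, f_anc, f_don, f_var, f_truth, f_cfg))
}
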