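# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementation.

# Minimum number of state changes over all internal-node labelings of a
# rooted tree; tips with genotype N are unconstrained (they can always
# copy their parent at zero cost).
oracle_parsimony <- function(tree, genotypes, alleles) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tip_state <- match(genotypes[tree$tip.label], alleles) # NA when N/absent
  combos <- as.matrix(expand.grid(rep(list(1:2), nint)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    st <- c(tip_state, combos[r, ])
    changes <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      cs <- st[tree$edge[e, 2L]]
      if (!is.na(cs) && st[tree$edge[e, 1L]] != cs) changes <- changes + 1L
    }
    best <- min(best, changes)
  }
  best
}

# All maximal same-branch subsets of >= 2 variants whose sorted adjacent
# gaps are all <= max_gap, by exhaustive subset enumeration (<= ~15
# variants). Returns a list of sorted index vectors.
oracle_cluster_sets <- function(pos, branch, max_gap) {
  out <- list()
  for (br in unique(branch)) {
    idx <- which(branch == br)
    if (length(idx) < 2L) next
    valid <- list()
    for (m in 2:length(idx)) {
      for (comb in utils::combn(idx, m, simplify = FALSE)) {
        p <- sort(pos[comb])
        if (all(diff(p) <= max_gap)) valid[[length(valid) + 1L]] <- sort(comb)
      }
    }
    for (v in valid) {
      is_max <- !any(vapply(
        valid,
        function(o) length(o) > length(v) && all(v %in% o),
        logical(1)
      ))
      if (is_max) out[[length(out) + 1L]] <- v
    }
  }
  unique(out)
}

# Average pairwise difference per site by direct double loop (no indel
# collapsing: panels fed to it are gap-free).
oracle_pi <- function(seqs, L = nchar(seqs[1L])) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      total <- total + sum(a != b & a != "N" & b != "N")
    }
  }
  total / choose(n, 2) / L
}

# Build a variant_table from a genotype matrix (variants x samples).
make_vt <- function(geno, pos = seq_len(nrow(geno)), chrom = "chrY") {
  stopifnot(!is.null(colnames(geno)))
  samples <- colnames(geno)
  rows <- lapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    al <- unique(g[g != "N"])
    stopifnot(length(al) == 2L)
    df <- data.frame(
      name = paste0("V", i), chrom = chrom, pos = pos[i], type = "SNP",
      indel_length = 0L, ref_allele = al[1L], alt_allele = al[2L],
      flag_missing = mean(g == "N") > 0.2, multiallelic = FALSE,
      stringsAsFactors = FALSE
    )
    for (s in samples) df[[s]] <- unname(g[s])
    df
  })
  variant_table(do.call(rbind, rows), samples)
}

# Random rooted binary tree with readable labels, via the package reader
# so internal branches are auto-named.
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  read_newick_tree(text = ape::write.tree(tr))
}
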