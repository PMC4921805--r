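#' Pipeline run configuration
#'
#' Collects inputs and tuning parameters for [run_pipeline()]. Defaults
#' reproduce the declared analysis parameters: 50 bp clustering gap,
#' 1000 permutation replicates, and a 3 bp minimum cluster span for the
#' donor search.
#'
#' @param sim An `ltr_sim` object to analyse in memory, or `NULL`.
#' @param fasta,reference Paths to an aligned panel FASTA and to the
#'   reference record (`reference` may also name a record inside
#'   `fasta`); ignored when `sim` is given.
#' @param tree Path to a Newick file (or a `"phylo"`); ignored when
#'   `sim` is given.
#' @param variants Optional path to a pre-called variant TSV, bypassing
#'   [call_variants()].
#' @param donors Optional donor-library FASTA path (headers
#'   `chrom:start-end`); the simulator's library is used automatically
#'   for `sim` input.
#' @param regions Optional data.frame (`name`, `start`, `end`, `kind`)
#'   of locus regions for per-region diversity.
#' @param out Output directory for the TSV report set.
#' @param seed Seed for the permutation null.
#' @param max_gap Clustering distance (bp).
#' @param reps Permutation replicates.
#' @param min_span Minimum cluster span (bp) for the donor search.
#' @param outgroup Optional outgroup tip for polarity tie-breaks.
#' @param variance Diversity variance formula (`"nei"` or `"none"`).
#' @param tract_mode Max-tract convention (`"between"` or `"inclusive"`).
#' @param n_variants_override Optional total variant count for the
#'   permutation null, when it should differ from the table (e.g. when
#'   indels are excluded from or added to the permuted set).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, fasta = NULL, reference = NULL,
                       tree = NULL, variants = NULL, donors = NULL,
                       regions = NULL, out = tempfile("ltrconv_report_"),
                       seed = 1L, max_gap = 50L, reps = 1000L,
                       min_span = 3L, outgroup = NULL,
                       variance = c("nei", "none"),
                       tract_mode = c("between", "inclusive"),
                       n_variants_override = NULL) {
  structure(
    list(
      sim = sim, fasta = fasta, reference = reference, tree = tree,
      variants = variants, donors = donors, regions = regions, out = out,
      seed = as.integer(seed), max_gap = as.integer(max_gap),
      reps = as.integer(reps), min_span = as.integer(min_span),
      outgroup = outgroup, variance = match.arg(variance),
      tract_mode = match.arg(tract_mode),
      n_variants_override = n_variants_override
    ),
    class = "run_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full ectopic gene-conversion analysis
#'
#' Executes variant calling (for FASTA input), polarization on the fixed
#' tree, nucleotide diversity, cluster detection, the permutation/Poisson
#' excess test, the clustered proportion, and — when a donor library is
#' available — the donor search with conversion-tract bounds. All result
#' tables are written as TSV to `config$out` along with run metadata,
#' and returned invisibly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every intermediate result:
#'   `variants`, `assignments`, `events`, `diversity`, `clusters`,
#'   `null`, `excess`, `proportion`, `donor_hits`, `report_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  ## ---- inputs ----
  if (!is.null(config$sim)) {
    sim <- config$sim
    panel <- sim$tips
    reference <- sim$ancestor
    tree <- sim$tree
    vt <- sim$variants
    donor_lib <- sim$donors
  } else {
    sim <- NULL
    tree <- with_stage("read_tree", {
      if (inherits(config$tree, "phylo")) config$tree
      else read_newick_tree(config$tree)
    })
    panel <- reference <- NULL
    if (!is.null(config$fasta)) {
      recs <- with_stage("read_fasta", read_fasta(config$fasta))
      ref_id <- config$reference
      is_ref <- if (!is.null(ref_id) && ref_id %in% recs$id) {
        recs$id == ref_id
      } else {
        !is.na(recs$start) # the record with coordinates is the reference
      }
      if (sum(is_ref) != 1L) {
        stop("pipeline stage 'read_fasta' failed: cannot identify a single ",
             "reference record", call. = FALSE)
      }
      reference <- recs[is_ref, , drop = FALSE]
      panel <- recs[!is_ref, , drop = FALSE]
    } else if (!is.null(config$reference)) {
      reference <- with_stage("read_fasta", read_fasta(config$reference))
    }
    vt <- if (!is.null(config$variants)) {
      with_stage("read_variants", read_variant_table(config$variants))
    } else {
      with_stage(
        "call_variants",
        call_variants(panel, reference)$variants
      )
    }
    donor_lib <- if (!is.null(config$donors)) {
      with_stage("read_donors", read_fasta(config$donors))
    } else {
      NULL
    }
  }

  ## ---- polarization ----
  assignments <- with_stage(
    "polarize_and_assign",
    suppressWarnings(polarize_and_assign(
      vt, tree,
      outgroup = config$outgroup, on_multiallelic = "drop"
    ))
  )
  events <- assignment_events(assignments)
  ev_summary <- count_events(assignments)

  ## ---- diversity ----
  diversity <- if (!is.null(panel)) {
    with_stage("diversity", {
      if (!is.null(config$regions)) {
        diversity_by_region(
          panel, config$regions,
          ref_start = if (!is.na(reference$start)) reference$start else 1L
        )
      } else {
        nucleotide_diversity(
          panel, region = "locus", variance = config$variance
        )
      }
    })
  } else {
    NULL
  }

  ## ---- clusters and excess test ----
  clusters <- with_stage(
    "detect_clusters", detect_clusters(events, max_gap = config$max_gap)
  )
  L <- if (!is.null(reference)) {
    nchar(gsub("-", "", reference$seq))
  } else {
    max(vt$pos) - min(vt$pos) + 1L
  }
  n_perm <- if (!is.null(config$n_variants_override)) {
    config$n_variants_override
  } else {
    nrow(vt)
  }
  null <- with_stage("permutation_null", permutation_null(
    n_variants = n_perm, L = L, n_branches = n_branches(tree),
    reps = config$reps, max_gap = config$max_gap, seed = config$seed
  ))
  proportion <- clustered_proportion(clusters, nrow(vt))
  excess <- excess_test(null, proportion$k)

  ## ---- donor search ----
  donor_hits <- NULL
  if (!is.null(donor_lib) && !is.null(reference) && nrow(clusters) > 0L) {
    donor_hits <- with_stage("donor_search", {
      cand <- filter_clusters_for_donor_search(clusters, config$min_span)
      aligned <- donor_lib
      for (i in seq_len(nrow(aligned))) {
        if (nchar(aligned$seq[i]) != nchar(reference$seq)) {
          aligned[i, ] <- align_donor(reference, aligned[i, , drop = FALSE])
        }
      }
      hits <- list()
      for (ci in seq_len(nrow(cand))) {
        cl <- cand[ci, , drop = FALSE]
        tract <- build_derived_tract(reference, cl, assignments)
        h <- match_donors(tract, cl, aligned, reference)
        if (nrow(h) == 0L) next
        for (hi in seq_len(nrow(h))) {
          psvs <- identify_psvs(
            reference, aligned[match(h$donor_id[hi], aligned$id), , drop = FALSE]
          )
          b <- tract_bounds(cl, psvs, mode = config$tract_mode)
          h$min_tract[hi] <- b$min_tract
          h$max_tract[hi] <- b$max_tract
          h$class[hi] <- classify_conversion(
            h$chrom[hi], h$start[hi], h$end[hi],
            acceptor_chrom = reference$chrom,
            element_start = reference$start, element_end = reference$end
          )
        }
        hits[[length(hits) + 1L]] <- h
      }
      if (length(hits) > 0L) do.call(rbind, hits) else NULL
    })
  }

  ## ---- report ----
  tables <- list(
    assignments = data.frame(
      assignments[
        , c("name", "chrom", "pos", "ancestral_allele", "derived_allele",
            "n_events", "homoplasic", "placement_ambiguous")
      ],
      branches = vapply(
        assignments$events, function(e) paste(e$branch, collapse = ","), ""
      )
    ),
    clusters = as.data.frame(clusters),
    null_summary = data.frame(
      n_variants = null$n_variants, L = null$L,
      n_branches = null$n_branches, max_gap = null$max_gap,
      reps = null$reps, lambda = null$lambda,
      observed_clustered = excess$observed, p = excess$p,
      log10_p = excess$log10_p
    ),
    event_summary = as.data.frame(ev_summary)
  )
  if (!is.null(diversity)) tables$diversity <- diversity
  if (!is.null(donor_hits)) tables$donor_hits <- donor_hits
  write_report(
    tables, config$out,
    metadata = list(
      seed = config$seed, max_gap = config$max_gap, reps = config$reps,
      min_span = config$min_span,
      n_variants_permuted = n_perm, n_variants_table = nrow(vt),
      variance = config$variance, tract_mode = config$tract_mode
    )
  )

  invisible(list(
    variants = vt, assignments = assignments, events = events,
    event_summary = ev_summary, diversity = diversity, clusters = clusters,
    null = null, excess = excess, proportion = proportion,
    donor_hits = donor_hits, report_dir = config$out
  ))
}
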