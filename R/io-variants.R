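#' Variant tables
#'
#' A `variant_table` is a data.frame with one row per segregating variant
#' and the columns `name`, `chrom`, `pos` (1-based), `type` (`"SNP"` or
#' `"indel"`), `indel_length` (0 for SNPs), `ref_allele`, `alt_allele`,
#' `flag_missing` (more than 20% missing genotypes), `multiallelic`,
#' followed by one haploid genotype column per sample (`N` = missing).
#' Indel genotypes use `"+"` (bases present) and `"-"` (deleted). The
#' sample-column names are stored in `attr(x, "samples")`.
#'
#' @param df A data.frame with the columns above.
#' @param samples Character vector naming the genotype columns.
#' @return A `variant_table`.
#' @export
variant_table <- function(df, samples) {
  core <- c(
    "name", "chrom", "pos", "type", "indel_length",
    "ref_allele", "alt_allele", "flag_missing", "multiallelic"
  )
  stopifnot(all(core %in% names(df)), all(samples %in% names(df)))
  if (is.unsorted(df$pos, strictly = FALSE)) df <- df[order(df$pos), ]
  if (anyDuplicated(df$name)) stop("variant names must be unique")
  rownames(df) <- NULL
  structure(df, samples = samples, class = c("variant_table", "data.frame"))
}

#' Sample names of a variant table
#' @param x A `variant_table`.
#' @return Character vector of sample (genotype column) names.
#' @export
variant_samples <- function(x) attr(x, "samples")

#' Genotype matrix of a variant table
#' @param x A `variant_table`.
#' @return Character matrix, variants in rows (named), samples in columns.
#' @export
genotype_matrix <- function(x) {
  g <- as.matrix(as.data.frame(x)[, variant_samples(x), drop = FALSE])
  rownames(g) <- x$name
  g
}

#' Call variants from an aligned haplotype panel
#'
#' Scans an equal-length alignment of haploid sample sequences column by
#' column. A column with two or more distinct non-`N` sample alleles yields
#' a SNP. Runs of consecutive gap-containing columns are collapsed into a
#' single indel variant anchored at the leftmost affected base, with
#' `indel_length` equal to the run length; indel alleles are `"+"`
#' (present) / `"-"` (deleted). Columns that are invariant among the
#' samples but differ from the reference are returned separately as
#' reference-specific positions, not as variants — they reflect mutations
#' private to the reference assembly, not polymorphism in the panel.
#'
#' Chromosome positions are mapped through the reference row:
#' `pos = reference start + ungapped offset of the column in the reference`.
#'
#' @param alignment A `seq_set` of aligned sample sequences (equal length).
#' @param reference A one-row `seq_set` aligned to the samples, with
#'   coordinates (`chrom`, `start`) so columns map to chromosome positions.
#' @return A list with `variants` (a [variant_table()]) and `ref_specific`
#'   (integer chromosome positions invariant in the panel but different
#'   from the reference).
#' @export
call_variants <- function(alignment, reference) {
  stopifnot(inherits(alignment, "seq_set"), inherits(reference, "seq_set"))
  if (nrow(reference) != 1L) stop("reference must be a single record")
  if (is.na(reference$chrom) || is.na(reference$start)) {
    stop("reference must carry coordinates (chrom:start-end header)")
  }
  lens <- nchar(alignment$seq)
  if (length(unique(c(lens, nchar(reference$seq)))) != 1L) {
    stop("alignment error: sequences differ in length")
  }
  L <- lens[1L]
  n <- nrow(alignment)
  M <- matrix(
    unlist(strsplit(alignment$seq, ""), use.names = FALSE),
    nrow = n, ncol = L, byrow = TRUE
  )
  rownames(M) <- alignment$id
  r <- strsplit(reference$seq, "")[[1L]]

  # chromosome position of each column, anchored at the previous reference
  # base when the reference is gapped
  ungapped <- cumsum(r != "-")
  pos_col <- reference$start + pmax(ungapped, 1L) - 1L

  gap_col <- r == "-" | colSums(M == "-") > 0L
  run_id <- cumsum(gap_col & !c(FALSE, gap_col[-L]))
  run_id[!gap_col] <- 0L

  rows <- list()
  ref_specific <- integer(0)

  add_row <- function(pos, type, ilen, ref_a, alt_a, geno, multi) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = NA_character_, chrom = reference$chrom, pos = pos, type = type,
      indel_length = ilen, ref_allele = ref_a, alt_allele = alt_a,
      flag_missing = mean(geno == "N") > 0.2, multiallelic = multi,
      t(geno), stringsAsFactors = FALSE, check.names = FALSE
    )
  }

  # indel runs
  for (id in setdiff(unique(run_id), 0L)) {
    cols <- which(run_id == id)
    sub <- M[, cols, drop = FALSE]
    geno <- apply(sub, 1L, function(x) {
      if (all(x == "N")) "N" else if (any(x == "-")) "-" else "+"
    })
    ref_state <- if (any(r[cols] == "-")) "-" else "+"
    states <- unique(geno[geno != "N"])
    anchor <- pos_col[cols[1L]]
    if (length(states) >= 2L) {
      add_row(
        anchor, "indel", length(cols),
        ref_state, setdiff(c("+", "-"), ref_state), geno, FALSE
      )
    } else if (length(states) == 1L && states != ref_state) {
      ref_specific <- c(ref_specific, anchor)
    }
  }

  # SNP columns
  for (j in which(!gap_col)) {
    col <- M[, j]
    tab <- sort(table(col[col != "N"]), decreasing = TRUE)
    states <- names(tab)
    if (length(states) >= 2L) {
      multi <- length(states) > 2L
      if (multi) states <- states[1:2]
      ref_a <- if (r[j] %in% states) r[j] else states[1L]
      alt_a <- setdiff(states, ref_a)[1L]
      add_row(pos_col[j], "SNP", 0L, ref_a, alt_a, col, multi)
    } else if (length(states) == 1L && r[j] %in% c("A", "C", "G", "T") &&
               states != r[j]) {
      ref_specific <- c(ref_specific, pos_col[j])
    }
  }

  if (length(rows) == 0L) {
    empty <- data.frame(
      name = character(0), chrom = character(0), pos = integer(0),
      type = character(0), indel_length = integer(0),
      ref_allele = character(0), alt_allele = character(0),
      flag_missing = logical(0), multiallelic = logical(0)
    )
    for (s in alignment$id) empty[[s]] <- character(0)
    return(list(
      variants = variant_table(empty, alignment$id),
      ref_specific = sort(ref_specific)
    ))
  }

  vt <- do.call(rbind, rows)
  vt <- vt[order(vt$pos), , drop = FALSE]
  vt$name <- paste0("V", seq_len(nrow(vt)))
  list(
    variants = variant_table(vt, alignment$id),
    ref_specific = sort(ref_specific)
  )
}

#' Write / read a variant table as TSV
#'
#' The TSV dialect has the header columns `name`, `chrom`, `pos`, `type`,
#' `indel_length`, `ref_allele`, `alt_allele`, `flag_missing`,
#' `multiallelic`, then one column per sample.
#'
#' @param x A `variant_table`.
#' @param path File path.
#' @return `path` (write) or a `variant_table` (read).
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  write.table(
    as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  core <- c(
    "name", "chrom", "pos", "type", "indel_length",
    "ref_allele", "alt_allele", "flag_missing", "multiallelic"
  )
  samples <- setdiff(names(df), core)
  for (s in samples) df[[s]] <- as.character(df[[s]])
  variant_table(df, samples)
}
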