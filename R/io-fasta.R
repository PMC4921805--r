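#' Read a FASTA file into a sequence set
#'
#' Parses a (possibly gapped) nucleotide FASTA file. Sequences are
#' upper-cased and restricted to the alphabet `A,C,G,T,N,-`; IUPAC ambiguity
#' codes other than `N` are rejected because the pipeline operates on haploid
#' data where they carry no meaning. If the first whitespace-delimited token
#' of a header has the form `chrom:start-end` (hyphen or en-dash), the
#' genomic coordinates are parsed into the `chrom`, `start` and `end`
#' columns. Coordinates are 1-based inclusive.
#'
#' @param path Path to a FASTA file.
#' @return A `seq_set`: a data.frame with columns `id`, `seq`, `chrom`,
#'   `start`, `end` (the last three `NA` when the header carries no
#'   coordinates), one row per record.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chrY:10-19", "ACGTACGTAC"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  empty <- Biostrings::width(x) == 0L
  if (any(empty)) {
    stop("FASTA record without sequence: '", names(x)[which(empty)[1L]], "'")
  }
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop(
      "sequence '", names(x)[which(bad)[1L]],
      "' contains characters outside {A,C,G,T,N,-}"
    )
  }
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  coords <- parse_coord_header(ids)
  new_seq_set(data.frame(
    id = ids, seq = unname(seqs),
    chrom = coords$chrom, start = coords$start, end = coords$end,
    stringsAsFactors = FALSE
  ))
}

# "chrom:start-end" headers; en-dash accepted because coordinate ranges
# copied from publications often carry it.
parse_coord_header <- function(ids) {
  m <- regmatches(
    ids,
    regexec("^([^:[:space:]]+):([0-9]+)[–-]([0-9]+)$", ids)
  )
  ok <- lengths(m) == 4L
  chrom <- rep(NA_character_, length(ids))
  start <- end <- rep(NA_integer_, length(ids))
  chrom[ok] <- vapply(m[ok], `[[`, character(1), 2L)
  start[ok] <- as.integer(vapply(m[ok], `[[`, character(1), 3L))
  end[ok] <- as.integer(vapply(m[ok], `[[`, character(1), 4L))
  if (any(ok & end < start)) {
    stop("coordinate header with end < start: '", ids[which(ok & end < start)[1L]], "'")
  }
  list(chrom = chrom, start = start, end = end)
}

new_seq_set <- function(df) {
  stopifnot(all(c("id", "seq", "chrom", "start", "end") %in% names(df)))
  structure(df, class = c("seq_set", "data.frame"))
}

#' Construct a sequence set from id/sequence vectors
#'
#' @param id Character vector of record ids.
#' @param seq Character vector of sequences (same length as `id`).
#' @param chrom,start,end Optional genomic coordinates (1-based inclusive).
#' @return A `seq_set` data.frame.
#' @export
seq_set <- function(id, seq, chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_) {
  new_seq_set(data.frame(
    id = id, seq = toupper(seq),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE
  ))
}

#' Write a sequence set to FASTA
#'
#' Sequences are wrapped at 60 columns. Round-tripping through
#' [read_fasta()] reproduces sequences and ids exactly.
#'
#' @param x A `seq_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
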