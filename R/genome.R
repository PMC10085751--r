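#' Genome object
#'
#' A lightweight container for a single chromosome: its identifier, the
#' uppercased sequence over `A/C/G/T/N`, a circularity flag (bacterial
#' chromosomes are circular by default) and its length.
#'
#' @param id Sequence identifier.
#' @param sequence Character scalar over `A/C/G/T/N` (case-insensitive).
#' @param circular Logical; treat the chromosome as circular.
#' @return An object of class `cdm_genome`.
#' @export
cdm_genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("illegal character '", substr(sequence, bad, bad),
         "' at position ", bad, call. = FALSE)
  if (nchar(sequence) < 3L)
    stop("genome must be at least 3 bases long", call. = FALSE)
  structure(list(id = as.character(id), sequence = sequence,
                 circular = isTRUE(circular), length = nchar(sequence)),
            class = "cdm_genome")
}

#' @export
print.cdm_genome <- function(x, ...) {
  cat(sprintf("<cdm_genome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' The first record is used; multi-record files emit a warning. Sequences
#' are uppercased on load and restricted to `A/C/G/T/N`.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical circularity flag to attach (default `TRUE`,
#'   the bacterial-chromosome convention).
#' @return A [cdm_genome()] object.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path,
                              call. = FALSE)
  if (length(set) > 1L)
    warning("FASTA file has ", length(set),
            " records; using the first record only", call. = FALSE)
  id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  cdm_genome(id, as.character(set[[1L]]), circular = circular)
}

# per-base tallies of a genome (A/C/G/T/N)
base_counts <- function(genome) {
  stopifnot(inherits(genome, "cdm_genome"))
  tab <- table(strsplit(genome$sequence, "")[[1L]])
  out <- stats::setNames(integer(5L), c(DNA_BASES, "N"))
  out[names(tab)] <- as.integer(tab)
  out
}

# GC fraction of an A/C/G/T(/N) string; N excluded from the denominator
gc_fraction <- function(seq) {
  n <- nchar(seq) - lengths(regmatches(seq, gregexpr("N", seq)))
  gc <- lengths(regmatches(seq, gregexpr("[GC]", seq)))
  ifelse(n > 0, gc / n, NA_real_)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised over its
#' input.
#'
#' @param seq Character vector over `A/C/G/T/N`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(seq[i], bad[i], bad[i]),
         "' in sequence ", i, call. = FALSE)
  }
  str_rev(chartr("ACGTN", "TGCAN", seq))
}

# substring of a circular (or linear) genome; positions may run off either
# end for circular genomes, where they wrap. Returns NA if out of range on
# a linear genome.
genome_slice <- function(genome, from, to) {
  L <- genome$length
  idx <- seq.int(from, to)
  if (genome$circular) {
    idx <- wrap_pos(idx, L)
  } else if (any(idx < 1L | idx > L)) {
    return(NA_character_)
  }
  paste0(substring(genome$sequence, idx, idx), collapse = "")
}
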