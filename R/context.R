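#' Count k-mer contexts genome-wide or per replichore
#'
#' Slides a width-`k` window (step 1) over the genome and tallies each
#' context. Windows are keyed by the coordinate of their center base (odd
#' `k`) or the base left of center (even `k`); a window belongs to a
#' replichore iff its key coordinate does. Circular genomes wrap windows
#' across the junction, so the chromosome contributes exactly `L` windows;
#' linear genomes contribute `L - k + 1`. Windows containing `N` are
#' skipped and counted in `n_skipped`. With `strand = "complement"` each
#' window is replaced by its reverse complement before tallying, i.e. the
#' counts are those of the complementary strand read 5'->3'.
#'
#' These tables are the genome-wide triplet counts (GWTC, `region =
#' "genome"`) and replichore-wide triplet counts (RWTC) used as rate
#' denominators.
#'
#' @param genome A [cdm_genome()].
#' @param frame A [replication_frame()]; may be `NULL` for
#'   `region = "genome"`.
#' @param k Context width (3, 4 or 5).
#' @param region `"genome"`, `"right_replichore"` or `"left_replichore"`.
#' @param strand `"reference"` or `"complement"`.
#' @return An object of class `cdm_context_counts`: list with `k`,
#'   `region`, `strand`, `counts` (named integer vector over the full
#'   `4^k` keyspace, lexicographic), and `n_skipped`.
#' @export
count_contexts <- function(genome, frame = NULL, k = 3L,
                           region = c("genome", "right_replichore",
                                      "left_replichore"),
                           strand = c("reference", "complement")) {
  region <- match.arg(region)
  strand <- match.arg(strand)
  k <- as.integer(k)
  L <- genome$length
  if (!k %in% c(3L, 4L, 5L)) stop("k must be 3, 4 or 5", call. = FALSE)
  if (k > L) stop("k exceeds the genome length", call. = FALSE)
  key_off <- as.integer(floor((k - 1L) / 2L))  # center (odd) / left-of-center
  if (genome$circular) {
    starts <- seq_len(L)
    ext <- paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
    key_coord <- wrap_pos(starts + key_off, L)
  } else {
    starts <- seq_len(L - k + 1L)
    ext <- genome$sequence
    key_coord <- starts + key_off
  }
  wins <- substring(ext, starts, starts + k - 1L)
  if (region != "genome") {
    if (is.null(frame))
      stop("a replication frame is required for replichore regions",
           call. = FALSE)
    want <- if (region == "right_replichore") "right" else "left"
    sel <- assign_replichore(frame, key_coord) == want
    wins <- wins[sel]
  }
  has_n <- grepl("N", wins, fixed = TRUE)
  n_skipped <- sum(has_n)
  tallied <- wins[!has_n]
  keys <- kmer_keyspace(k)
  counts <- stats::setNames(integer(length(keys)), keys)
  if (length(tallied)) {
    tab <- table(tallied)
    counts[names(tab)] <- as.integer(tab)
  }
  if (strand == "complement") {
    # counts of revcomped windows == reference counts re-keyed by revcomp
    counts <- stats::setNames(counts, reverse_complement(keys))[keys]
  }
  structure(list(k = k, region = region, strand = strand, counts = counts,
                 n_skipped = n_skipped),
            class = "cdm_context_counts")
}

#' @export
print.cdm_context_counts <- function(x, ...) {
  cat(sprintf("<cdm_context_counts> k=%d %s/%s: %d windows (%d skipped)\n",
              x$k, x$region, x$strand, sum(x$counts), x$n_skipped))
  invisible(x)
}

#' Extract the local sequence context of each variant
#'
#' Reads the 5' and 3' neighbour bases of every variant from the
#' reference strand (wrapping across the junction on circular genomes),
#' assigns each variant to its replichore, and applies the strand
#' convention: under `"lagging_template_revcomp"` the triplet, ref and alt
#' of right-replichore variants are replaced by their reverse complements
#' so both replichores are read in their synthesis orientation (the
#' reference strand is the leading-strand template on the left replichore
#' and the lagging-strand template on the right). Under `"as_reference"`
#' no transformation is applied. Variants whose context contains `N`, or
#' which sit at the ends of a linear genome, are excluded with a reason.
#'
#' @param genome A [cdm_genome()].
#' @param frame A [replication_frame()].
#' @param variants A `cdm_variants` or a data.frame of records with
#'   `position`, `ref`, `alt`.
#' @param convention `"as_reference"` or `"lagging_template_revcomp"`.
#' @return A list with `contexts` (data.frame: position, ref, alt,
#'   up_base, down_base, extended_up, extended_down, replichore,
#'   oriented_up, oriented_ref, oriented_alt, oriented_down,
#'   oriented_triplet) and `exclusion_log`.
#' @export
extract_context <- function(genome, frame, variants,
                            convention = c("lagging_template_revcomp",
                                           "as_reference")) {
  convention <- match.arg(convention)
  rec <- if (inherits(variants, "cdm_variants")) variants$records else
    variants
  L <- genome$length
  n <- nrow(rec)
  if (!n) {
    empty <- data.frame(position = integer(), ref = character(),
                        alt = character(), up_base = character(),
                        down_base = character(), extended_up = character(),
                        extended_down = character(),
                        replichore = character(),
                        oriented_up = character(),
                        oriented_ref = character(),
                        oriented_alt = character(),
                        oriented_down = character(),
                        oriented_triplet = character(),
                        stringsAsFactors = FALSE)
    return(list(contexts = empty,
                exclusion_log = data.frame(position = integer(),
                                           reason = character())))
  }
  pos <- rec$position
  at <- function(p) {
    if (genome$circular) {
      p <- wrap_pos(p, L)
      substring(genome$sequence, p, p)
    } else {
      out <- rep(NA_character_, length(p))
      ok <- p >= 1L & p <= L
      out[ok] <- substring(genome$sequence, p[ok], p[ok])
      out
    }
  }
  up1 <- at(pos - 1L); down1 <- at(pos + 1L)
  up2 <- at(pos - 2L); down2 <- at(pos + 2L)
  reason <- rep(NA_character_, n)
  terminal <- is.na(up1) | is.na(down1)
  reason[terminal] <- "terminal position on linear genome"
  ambig <- !terminal & (up1 == "N" | down1 == "N" | rec$ref == "N")
  reason[ambig] <- "ambiguous context"
  keep <- is.na(reason)

  df <- data.frame(position = pos[keep], ref = rec$ref[keep],
                   alt = rec$alt[keep], up_base = up1[keep],
                   down_base = down1[keep],
                   extended_up = paste0(ifelse(is.na(up2[keep]), "",
                                               up2[keep]), up1[keep]),
                   extended_down = paste0(down1[keep],
                                          ifelse(is.na(down2[keep]), "",
                                                 down2[keep])),
                   replichore = assign_replichore(frame, pos[keep]),
                   stringsAsFactors = FALSE)
  flip <- convention == "lagging_template_revcomp" & df$replichore == "right"
  comp <- function(x) chartr("ACGTN", "TGCAN", x)
  df$oriented_up <- ifelse(flip, comp(df$down_base), df$up_base)
  df$oriented_ref <- ifelse(flip, comp(df$ref), df$ref)
  df$oriented_alt <- ifelse(flip, comp(df$alt), df$alt)
  df$oriented_down <- ifelse(flip, comp(df$up_base), df$down_base)
  df$oriented_triplet <- paste0(df$oriented_up, df$oriented_ref,
                                df$oriented_down)
  list(contexts = df,
       exclusion_log = data.frame(position = pos[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
}

#' Tabulate codon usage over complete CDS features
#'
#' In-frame codons of each complete (non-partial) CDS are tallied;
#' minus-strand CDS are read as the reverse complement of their span(s).
#' A CDS belongs to a replichore by the replichore of its start
#' coordinate.
#'
#' @param genome A [cdm_genome()].
#' @param annotations A `cdm_annotation`.
#' @param frame A [replication_frame()] (required for replichore regions).
#' @param region `"genome"`, `"right_replichore"` or `"left_replichore"`.
#' @return An object of class `cdm_codon_usage`: list with `region` and
#'   `counts`, a named integer vector over the 64 codons.
#' @export
count_codon_usage <- function(genome, annotations, frame = NULL,
                              region = c("genome", "right_replichore",
                                         "left_replichore")) {
  region <- match.arg(region)
  cds <- usable_cds(annotations)
  counts <- stats::setNames(integer(64L), kmer_keyspace(3L))
  if (!is.null(cds) && nrow(cds)) {
    if (region != "genome") {
      if (is.null(frame))
        stop("a replication frame is required for replichore regions",
             call. = FALSE)
      want <- if (region == "right_replichore") "right" else "left"
      cds <- cds[assign_replichore(frame, cds$start) == want, ,
                 drop = FALSE]
    }
    for (i in seq_len(nrow(cds))) {
      coords <- cds_coords(cds[i, , drop = FALSE])
      b <- substring(genome$sequence, coords, coords)
      if (cds$strand[i] == "-") b <- chartr("ACGTN", "TGCAN", b)
      starts <- seq(1L, length(b) - 2L, by = 3L)
      codons <- paste0(b[starts], b[starts + 1L], b[starts + 2L])
      codons <- codons[!grepl("N", codons, fixed = TRUE)]
      if (length(codons)) {
        tab <- table(codons)
        counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      }
    }
  }
  structure(list(region = region, counts = counts),
            class = "cdm_codon_usage")
}

#' Write a context count table as CSV
#' @param counts A `cdm_context_counts`.
#' @param path Output path.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(data.frame(context = names(counts$counts),
                              count = as.integer(counts$counts)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a context count CSV written by [write_counts_csv()]
#' @param path CSV path.
#' @return Named integer vector.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$count), df$context)
}
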