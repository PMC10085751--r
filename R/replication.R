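#' Cumulative GC-skew profile of a genome
#'
#' Each counted site contributes +1 for G, -1 for C and 0 for A/T/N; the
#' running sum along the chromosome is the cumulative skew, whose global
#' minimum and maximum mark the replication origin and terminus under the
#' G-rich leading strand convention. With
#' `site_set = "synonymous_third_codon"` only third codon positions of
#' complete (non-partial, non-compound) CDS features contribute, with
#' minus-strand CDS contributing the complement base.
#'
#' @param genome A [cdm_genome()].
#' @param annotations A `cdm_annotation`, required for the
#'   `synonymous_third_codon` site set.
#' @param site_set `"all_sites"` or `"synonymous_third_codon"`.
#' @return An object of class `cdm_skew`: list with ascending `positions`,
#'   `cumulative` (same length), and `site_set`.
#' @export
cumulative_skew <- function(genome, annotations = NULL,
                            site_set = c("all_sites",
                                         "synonymous_third_codon")) {
  site_set <- match.arg(site_set)
  if (site_set == "all_sites") {
    bases <- strsplit(genome$sequence, "")[[1L]]
    contrib <- (bases == "G") - (bases == "C")
    positions <- seq_len(genome$length)
  } else {
    cds <- usable_cds(annotations)
    if (is.null(cds) || !nrow(cds))
      stop("synonymous_third_codon site set requires at least one ",
           "complete CDS", call. = FALSE)
    pos_list <- base_list <- vector("list", nrow(cds))
    for (i in seq_len(nrow(cds))) {
      coords <- cds_coords(cds[i, , drop = FALSE])
      third <- coords[seq(3L, length(coords), by = 3L)]
      b <- substring(genome$sequence, third, third)
      if (cds$strand[i] == "-") b <- chartr("ACGTN", "TGCAN", b)
      pos_list[[i]] <- third
      base_list[[i]] <- b
    }
    positions <- unlist(pos_list)
    bases <- unlist(base_list)
    o <- order(positions)
    positions <- positions[o]
    bases <- bases[o]
    contrib <- (bases == "G") - (bases == "C")
  }
  structure(list(positions = positions, cumulative = cumsum(contrib),
                 site_set = site_set), class = "cdm_skew")
}

# complete CDS usable for codon-resolved analyses
usable_cds <- function(annotations) {
  if (is.null(annotations)) return(NULL)
  cds <- annotations[annotations$kind == "CDS" & !annotations$partial, ,
                     drop = FALSE]
  cds
}

# genome coordinates of a CDS in reading order (5'->3' on its own strand)
cds_coords <- function(cds_row) {
  segs <- cds_row$segments[[1L]]
  coords <- unlist(lapply(seq_len(nrow(segs)),
                          function(j) seq.int(segs[j, 1L], segs[j, 2L])))
  if (cds_row$strand == "-") coords <- rev(coords)
  coords
}

#' Replication frame (ORI/TER landmarks)
#'
#' @param ori,ter 1-based positions of the replication origin and
#'   terminus. An `ori` of 0 is normalised to position 1 (a common way of
#'   writing "the first base" in origin coordinates).
#' @param genome_length Chromosome length in bases.
#' @param circular Logical.
#' @param source `"oriloc_like"` (skew-detected) or `"user"`.
#' @return An object of class `cdm_frame`.
#' @export
replication_frame <- function(ori, ter, genome_length, circular = TRUE,
                              source = "user") {
  ori <- as.integer(ori); ter <- as.integer(ter)
  if (ori == 0L) ori <- 1L
  if (ter == 0L) ter <- 1L
  if (ori < 1L || ori > genome_length || ter < 1L || ter > genome_length)
    stop("ORI/TER must lie in [1, genome_length]", call. = FALSE)
  if (ori == ter) stop("ORI and TER must differ", call. = FALSE)
  structure(list(ori = ori, ter = ter,
                 genome_length = as.integer(genome_length),
                 circular = isTRUE(circular), source = source),
            class = "cdm_frame")
}

#' @export
print.cdm_frame <- function(x, ...) {
  cat(sprintf("<cdm_frame> ORI=%d TER=%d L=%d (%s)\n", x$ori, x$ter,
              x$genome_length, x$source))
  invisible(x)
}

#' Detect ORI and TER from a cumulative skew profile
#'
#' ORI is placed at the global minimum of the cumulative skew and TER at
#' the global maximum (leading strand G-rich convention); `invert = TRUE`
#' swaps the two for genomes with the opposite skew polarity. Ties are
#' broken by the smallest coordinate.
#'
#' On circular genomes the cumulative sum is first detrended (the linear
#' trend from first to last counted site is subtracted), so the detected
#' extrema do not depend on where the deposited sequence happens to
#' start: rotating the genome rotates the detected landmarks with it.
#'
#' @param profile A `cdm_skew` from [cumulative_skew()].
#' @param genome_length Chromosome length.
#' @param circular Logical, attached to the returned frame.
#' @param invert Swap the min/max convention.
#' @return A [replication_frame()] with `source = "oriloc_like"`.
#' @export
detect_ori_ter <- function(profile, genome_length, circular = TRUE,
                           invert = FALSE) {
  stopifnot(inherits(profile, "cdm_skew"))
  if (!length(profile$positions))
    stop("empty skew profile", call. = FALSE)
  cum <- profile$cumulative
  if (circular) {
    n <- length(cum)
    cum <- cum - seq_len(n) * (cum[n] / n)
  }
  if (abs(max(cum) - min(cum)) < sqrt(.Machine$double.eps))
    stop("flat skew profile: cannot detect ORI/TER; supply them manually",
         call. = FALSE)
  ori <- profile$positions[which.min(cum)]   # which.min: first (smallest)
  ter <- profile$positions[which.max(cum)]
  if (invert) { tmp <- ori; ori <- ter; ter <- tmp }
  replication_frame(ori, ter, genome_length, circular = circular,
                    source = "oriloc_like")
}

#' Assign genome positions to a replichore
#'
#' The right replichore is the half-open arc from ORI toward increasing
#' coordinates (modulo the length on circular genomes) up to but excluding
#' TER; the left replichore is the complement. ORI itself is right, TER
#' itself is left, so every position belongs to exactly one replichore.
#'
#' @param frame A [replication_frame()].
#' @param position Vector of 1-based positions.
#' @return Character vector of `"right"`/`"left"`.
#' @export
assign_replichore <- function(frame, position) {
  L <- frame$genome_length
  if (any(position < 1L | position > L))
    stop("position out of range [1, ", L, "]", call. = FALSE)
  if (frame$ori < frame$ter) {
    right <- position >= frame$ori & position < frame$ter
  } else {
    right <- position >= frame$ori | position < frame$ter
  }
  ifelse(right, "right", "left")
}

#' Offset of a position from the replication origin
#'
#' `offset = (position - ori) mod L`; the ORI maps to 0. Used to rotate
#' the chromosome so spatial bins start at the origin.
#'
#' @inheritParams assign_replichore
#' @return Integer vector of 0-based offsets.
#' @export
rotate_to_ori <- function(frame, position) {
  L <- frame$genome_length
  if (any(position < 1L | position > L))
    stop("position out of range [1, ", L, "]", call. = FALSE)
  (position - frame$ori) %% L
}

# inverse of rotate_to_ori
unrotate_from_ori <- function(frame, offset) {
  wrap_pos(offset + frame$ori, frame$genome_length)
}

#' Write a skew profile as a two-column CSV
#' @param profile A `cdm_skew`.
#' @param path Output path.
#' @export
write_skew_csv <- function(profile, path) {
  utils::write.csv(data.frame(position = profile$positions,
                              cumulative = profile$cumulative),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
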