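#' Read single-nucleotide variants from a VCF or base-call file
#'
#' Two dialects are supported: standard VCF 4.x (only SNV records are
#' retained; multi-allelic ALT fields are split into one candidate per
#' alternate allele) and a minimal "base call" CSV with columns
#' `position,ref,alt` (header optional; detected by a non-numeric first
#' field). Candidates whose ref/alt are not single bases in `A/C/G/T`,
#' whose ref equals alt, whose position is out of range, or whose ref does
#' not match the genome go to the exclusion log with a reason; retained
#' plus excluded records always equals the number of candidates.
#'
#' @param path Path to the variant file.
#' @param dialect `"vcf"` or `"basecall"`.
#' @param genome A [cdm_genome()] used to range- and reference-check
#'   positions.
#' @return An object of class `cdm_variants`: a list with `records`
#'   (data.frame `position`, `ref`, `alt`, `lineage`, `source_line`),
#'   `n_excluded`, and `exclusion_log` (data.frame `source_line`,
#'   `reason`).
#' @export
read_variants <- function(path, dialect = c("vcf", "basecall"), genome) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(inherits(genome, "cdm_genome"))
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (dialect == "basecall" && length(head1) && startsWith(head1, "##"))
    stop("file looks like a VCF but dialect is 'basecall': ", path,
         call. = FALSE)
  if (dialect == "vcf" &&
      (!length(head1) || !startsWith(head1, "##fileformat=VCF")))
    stop("missing VCF header line (##fileformat=VCF...): ", path,
         call. = FALSE)
  cand <- if (dialect == "vcf") vcf_candidates(path) else
    basecall_candidates(path)
  filter_variant_candidates(cand, genome)
}

# candidate records (position/ref/alt/lineage/source_line) from a VCF,
# multi-allelic ALT split
vcf_candidates <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n_meta <- length(v@meta)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"] %||% "", ",", fixed = TRUE)[[1L]]
    if (!length(alts)) alts <- NA_character_
    data.frame(position = as.integer(unname(fix[i, "POS"])),
               ref = unname(toupper(fix[i, "REF"])),
               alt = unname(toupper(alts)),
               lineage = NA_character_,
               source_line = n_meta + 1L + i,   # after meta + #CHROM header
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(position = integer(), ref = character(), alt = character(),
               lineage = character(), source_line = integer())
}

basecall_candidates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), lineage = character(),
                      source_line = integer()))
  first_field <- sub("[,\t ].*$", "", trimws(lines[lines_keep[1L]]))
  has_header <- is.na(suppressWarnings(as.numeric(first_field)))
  if (has_header) lines_keep <- lines_keep[-1L]
  parts <- strsplit(trimws(lines[lines_keep]), "[,\t]")
  data.frame(
    position = vapply(parts, function(p)
      suppressWarnings(as.integer(p[1L])), integer(1)),
    ref = toupper(vapply(parts, function(p) trimws(p[2L] %||% NA_character_),
                         character(1))),
    alt = toupper(vapply(parts, function(p) trimws(p[3L] %||% NA_character_),
                         character(1))),
    lineage = vapply(parts, function(p)
      if (length(p) >= 4L) trimws(p[4L]) else NA_character_, character(1)),
    source_line = lines_keep,
    stringsAsFactors = FALSE)
}

# apply the SNV retention rules against a genome
filter_variant_candidates <- function(cand, genome) {
  reason <- rep(NA_character_, nrow(cand))
  is_base <- function(x) !is.na(x) & x %in% DNA_BASES
  snv <- is_base(cand$ref) & is_base(cand$alt)
  reason[!snv] <- "not a SNV"
  same <- snv & cand$ref == cand$alt
  reason[same] <- "ref equals alt"
  ok_pos <- !is.na(cand$position) & cand$position >= 1L &
    cand$position <= genome$length
  reason[is.na(reason) & !ok_pos] <- "position out of range"
  idx <- which(is.na(reason))
  if (length(idx)) {
    gbase <- substring(genome$sequence, cand$position[idx],
                       cand$position[idx])
    mm <- gbase != cand$ref[idx]
    reason[idx[mm]] <- "ref mismatches genome"
  }
  keep <- is.na(reason)
  records <- cand[keep, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(
    records = records,
    n_excluded = sum(!keep),
    exclusion_log = data.frame(source_line = cand$source_line[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)),
    class = "cdm_variants")
}

#' @export
print.cdm_variants <- function(x, ...) {
  cat(sprintf("<cdm_variants> %d retained SNVs, %d excluded\n",
              nrow(x$records), x$n_excluded))
  invisible(x)
}

#' Write variants as a minimal VCF 4.2 file
#'
#' @param records Data frame with `position`, `ref`, `alt`.
#' @param genome The [cdm_genome()] the positions refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genome$id,
                       genome$length),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(records))
    writeLines(paste(genome$id, records$position, ".", records$ref,
                     records$alt, ".", "PASS", ".", sep = "\t"), con)
  invisible(path)
}

#' Write variants in the base-call CSV dialect (position,ref,alt)
#'
#' @inheritParams write_vcf
#' @export
write_basecall <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position,ref,alt", con)
  if (nrow(records))
    writeLines(paste(records$position, records$ref, records$alt, sep = ","),
               con)
  invisible(path)
}
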