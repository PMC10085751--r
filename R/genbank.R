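#' Read CDS/gene features from a GenBank flat file
#'
#' Parses the FEATURES table of a GenBank flat file into a feature table
#' with 1-based inclusive coordinates. `complement()` sets the strand,
#' `join()` locations are captured as a single feature spanning all
#' segments (flagged `compound`, with the segment list retained), and
#' partial locations (`<`/`>`) are flagged `partial`. CDS features whose
#' total span is not divisible by 3 are also flagged `partial` so that
#' codon-level analyses skip them.
#'
#' @param path Path to a GenBank flat file.
#' @return An object of class `cdm_annotation`: a `data.frame` with columns
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `kind` (`CDS`/`gene`/`other`),
#'   `locus_tag`, `partial`, `compound`, and a `segments` list column of
#'   two-column matrices for compound features.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_len <- NA_integer_
  li <- grep("^LOCUS", lines)
  if (length(li)) {
    m <- regmatches(lines[li[1L]],
                    regexpr("[0-9]+(?=\\s+bp)", lines[li[1L]], perl = TRUE))
    if (length(m)) locus_len <- as.integer(m)
  }
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart))
    stop("GenBank file has no FEATURES table: ", path, call. = FALSE)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- fend[fend > fstart[1L]]
  fend <- if (length(fend)) fend[1L] - 1L else length(lines)
  block <- lines[(fstart[1L] + 1L):fend]

  feats <- list()
  key <- NULL; loc <- NULL; quals <- character()
  flush <- function() {
    if (is.null(key)) return()
    feats[[length(feats) + 1L]] <<- list(key = key, loc = loc, quals = quals)
  }
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {            # new feature header
      flush()
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- sub("^ {5}\\S+\\s+", "", ln)
      quals <- character()
    } else if (grepl("^ {21}/", ln)) {       # qualifier
      quals <- c(quals, sub("^ {21}", "", ln))
    } else if (grepl("^ {21}\\S", ln)) {     # location or qualifier cont.
      if (length(quals)) {
        quals[length(quals)] <- paste0(quals[length(quals)],
                                       sub("^ {21}", "", ln))
      } else {
        loc <- paste0(loc, sub("^ {21}", "", ln))
      }
    }
  }
  flush()

  rows <- lapply(feats, function(f) {
    if (f$key == "source") return(NULL)
    p <- parse_gb_location(f$loc)
    if (is.null(p)) return(NULL)
    tag <- gb_qualifier(f$quals, "locus_tag") %||%
      gb_qualifier(f$quals, "gene") %||% ""
    kind <- if (f$key %in% c("CDS", "gene")) f$key else "other"
    partial <- p$partial
    if (kind == "CDS") {
      span <- sum(p$segments[, 2L] - p$segments[, 1L] + 1L)
      if (span %% 3L != 0L) partial <- TRUE
    }
    list(start = p$start, end = p$end, strand = p$strand, kind = kind,
         locus_tag = tag, partial = partial,
         compound = nrow(p$segments) > 1L, segments = p$segments)
  })
  rows <- Filter(Negate(is.null), rows)
  ann <- data.frame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    locus_tag = vapply(rows, `[[`, character(1), "locus_tag"),
    partial = vapply(rows, `[[`, logical(1), "partial"),
    compound = vapply(rows, `[[`, logical(1), "compound"),
    stringsAsFactors = FALSE)
  ann$segments <- lapply(rows, `[[`, "segments")
  if (!is.na(locus_len) && nrow(ann) &&
      any(ann$end > locus_len | ann$start < 1L))
    stop("feature coordinates exceed the LOCUS length (", locus_len, ")",
         call. = FALSE)
  class(ann) <- c("cdm_annotation", "data.frame")
  ann
}

# parse a GenBank location string; returns start/end/strand/partial and an
# n x 2 matrix of segments, or NULL for locations we do not model (e.g.
# remote accessions)
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl(":", loc, fixed = TRUE)) return(NULL)
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  segs <- t(vapply(parts, function(p) {
    xs <- strsplit(p, "\\.\\.")[[1L]]
    if (length(xs) == 1L) xs <- c(xs, xs)   # single-base location
    as.integer(xs)
  }, integer(2)))
  dimnames(segs) <- NULL
  if (any(is.na(segs)) || any(segs[, 2L] < segs[, 1L])) return(NULL)
  list(start = min(segs), end = max(segs), strand = strand,
       partial = partial, segments = segs)
}

gb_qualifier <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (!length(hit)) return(NULL)
  gsub("^/[^=]+=|\"", "", hit[1L])
}

#' Write a feature table and genome to a GenBank flat file
#'
#' Emits a minimal but standard-conforming flat file (LOCUS, FEATURES,
#' ORIGIN) that [read_genbank()] round-trips. Used by the synthetic
#' fixture generator.
#'
#' @param genome A [cdm_genome()].
#' @param annotations A `cdm_annotation` feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     BCT",
                     genome$id, genome$length, topo), con)
  writeLines(sprintf("DEFINITION  %s synthetic sequence.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", genome$length), con)
  if (nrow(annotations)) for (i in seq_len(nrow(annotations))) {
    segs <- annotations$segments[[i]]
    loc <- paste(sprintf("%d..%d", segs[, 1L], segs[, 2L]), collapse = ",")
    if (nrow(segs) > 1L) loc <- sprintf("join(%s)", loc)
    if (annotations$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", annotations$kind[i], loc), con)
    if (nzchar(annotations$locus_tag[i]))
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         annotations$locus_tag[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
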