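#' Bin mutations along the ORI-rotated chromosome
#'
#' Each variant is mapped to its 0-based offset from the replication
#' origin, `(position - ori) mod L`, and then to bin
#' `floor(offset * n_bins / L) + 1`, so bin 1 starts exactly at the ORI
#' and a terminus at `L/2` of a 25-bin layout falls in bin 13. Bin
#' boundaries tile `[0, L)` exactly with widths differing by at most one
#' base.
#'
#' @param variants A `cdm_variants` or a data.frame with `position`,
#'   `ref`, `alt`.
#' @param frame A [replication_frame()].
#' @param n_bins Number of bins; 25, 50 and 75 are the conventional
#'   choices (other values are allowed with a warning).
#' @param params A [run_parameters()] (G and N for the per-site rates).
#' @return An object of class `cdm_bins`: data.frame with columns
#'   `index`, `start_offset`, `end_offset` (0-based half-open offsets
#'   from the ORI), `mutation_count`, `mutation_rate_per_site`, plus the
#'   12 `ref>alt` substitution-type columns; attributes `n_bins`,
#'   `genome_length`, `generations`, `lineages`.
#' @export
bin_mutations <- function(variants, frame, n_bins = 25L, params) {
  rec <- if (inherits(variants, "cdm_variants")) variants$records else
    variants
  n_bins <- as.integer(n_bins)
  L <- frame$genome_length
  if (!n_bins %in% c(25L, 50L, 75L))
    warning("unconventional bin count ", n_bins,
            " (25/50/75 are the standard layouts)", call. = FALSE)
  if (L < n_bins) stop("more bins than bases", call. = FALSE)
  idx_all <- seq_len(n_bins)
  start_offset <- ceiling((idx_all - 1) * L / n_bins)
  end_offset <- ceiling(idx_all * L / n_bins)
  width <- end_offset - start_offset

  types <- as.vector(outer(DNA_BASES, DNA_BASES, paste, sep = ">"))
  types <- types[substr(types, 1, 1) != substr(types, 3, 3)]
  type_mat <- matrix(0L, n_bins, length(types),
                     dimnames = list(NULL, types))
  countv <- integer(n_bins)
  if (nrow(rec)) {
    offset <- rotate_to_ori(frame, rec$position)
    bin <- as.integer(floor(offset * n_bins / L)) + 1L
    tb <- table(bin)
    countv[as.integer(names(tb))] <- as.integer(tb)
    ty <- paste0(rec$ref, ">", rec$alt)
    for (t in unique(ty)) {
      tt <- table(bin[ty == t])
      type_mat[as.integer(names(tt)), t] <- as.integer(tt)
    }
  }
  G <- params$generations; N <- params$lineages
  df <- data.frame(index = idx_all, start_offset = start_offset,
                   end_offset = end_offset, mutation_count = countv,
                   mutation_rate_per_site = countv / (width * G * N))
  df <- cbind(df, as.data.frame(type_mat))
  structure(df, class = c("cdm_bins", "data.frame"), n_bins = n_bins,
            genome_length = L, generations = G, lineages = N)
}

#' Export runs as a circular-visualization JSON document
#'
#' A frozen, versioned schema: `{"schema": "circular-mutation-viz/1", "organisms":
#' [{id, genome_length, ori, ter, n_bins, bins: [...], triplet_rates:
#' {64 keys}, conditional_rates: {64 keys}}]}`. Key order is
#' deterministic and the document is written compactly so that
#' write -> read -> write is byte-identical.
#'
#' @param runs List of runs, each a list with `run_id`, `frame`
#'   (a [replication_frame()]), `bins` (a `cdm_bins`), `rates`
#'   (a `cdm_rates`), and `conditional` (from [conditional_rates()]).
#' @param path Output path (`NULL` returns the JSON string).
#' @return The JSON string, invisibly when written to a file.
#' @export
export_circular_viz_json <- function(runs, path = NULL) {
  stopifnot(length(runs) >= 1L)
  nb <- unique(vapply(runs, function(r) attr(r$bins, "n_bins"),
                      integer(1)))
  if (length(nb) != 1L)
    stop("all runs must use the same number of bins for stacked display",
         call. = FALSE)
  orgs <- lapply(runs, function(r) {
    agg <- aggregate_to_triplets(r$rates)
    trip <- as.list(stats::setNames(as.numeric(agg$rate_total),
                                    agg$triplet))
    cond <- as.list(stats::setNames(
      as.numeric(r$conditional$conditional_rate), r$conditional$triplet))
    bins <- lapply(seq_len(nrow(r$bins)), function(i) list(
      index = as.numeric(r$bins$index[i]),
      start_offset = as.numeric(r$bins$start_offset[i]),
      end_offset = as.numeric(r$bins$end_offset[i]),
      mutation_count = as.numeric(r$bins$mutation_count[i]),
      mutation_rate_per_site =
        as.numeric(r$bins$mutation_rate_per_site[i])))
    list(id = r$run_id,
         genome_length = as.numeric(r$frame$genome_length),
         ori = as.numeric(r$frame$ori), ter = as.numeric(r$frame$ter),
         n_bins = as.numeric(nb), bins = bins, triplet_rates = trip,
         conditional_rates = cond)
  })
  doc <- list(schema = "circular-mutation-viz/1", organisms = orgs)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, sep = "\n")
  invisible(as.character(json))
}

#' Read and validate a circular-visualization JSON document
#'
#' The inverse of [export_circular_viz_json()]: returns the document as nested
#' lists, after checking the schema tag, the per-organism key set and
#' that bin counts re-sum to a consistent total.
#'
#' @param path JSON path.
#' @return Nested list mirroring the exported document.
#' @export
read_circular_viz_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "circular-mutation-viz/1"))
    stop("not a circular-mutation-viz/1 document", call. = FALSE)
  need <- c("id", "genome_length", "ori", "ter", "n_bins", "bins",
            "triplet_rates", "conditional_rates")
  for (org in doc$organisms) {
    if (!all(need %in% names(org)))
      stop("organism entry missing keys: ",
           paste(setdiff(need, names(org)), collapse = ", "),
           call. = FALSE)
    if (length(org$triplet_rates) != 64L)
      stop("triplet_rates must have 64 keys", call. = FALSE)
  }
  doc
}

# re-serialize a parsed document; byte-identical to the original export
circular_viz_json_string <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Write a bin table as CSV
#' @param bins A `cdm_bins`.
#' @param path Output path.
#' @export
write_bins_csv <- function(bins, path) {
  df <- as.data.frame(bins)
  df$mutation_rate_per_site <- sprintf("%.17g", df$mutation_rate_per_site)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
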