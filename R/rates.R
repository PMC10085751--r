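#' Run parameters for a mutation accumulation analysis
#'
#' @param generations Generations elapsed per lineage (G), positive real.
#' @param lineages Number of lineages (N), positive integer.
#' @param scaling_mode `"default_1e-8"` (display rates in units of
#'   1e-8 per site per generation), `"mean_scaled"` (divide by the mean
#'   of non-missing rates) or `"custom"`.
#' @param custom_factor Positive real divisor, required iff
#'   `scaling_mode == "custom"`.
#' @param ori_override,ter_override Optional 1-based ORI/TER positions;
#'   an ORI of 0 is normalised to 1.
#' @return An object of class `cdm_params`.
#' @export
run_parameters <- function(generations, lineages,
                           scaling_mode = c("default_1e-8", "mean_scaled",
                                            "custom"),
                           custom_factor = NULL, ori_override = NULL,
                           ter_override = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  generations <- as.numeric(generations)
  lineages <- as.integer(lineages)
  if (!is.finite(generations) || generations <= 0)
    stop("generations must be > 0", call. = FALSE)
  if (is.na(lineages) || lineages < 1L)
    stop("lineages must be >= 1", call. = FALSE)
  if (scaling_mode == "custom") {
    if (is.null(custom_factor) || !is.finite(custom_factor) ||
        custom_factor <= 0)
      stop("custom scaling requires a positive custom_factor",
           call. = FALSE)
  } else custom_factor <- NULL
  structure(list(generations = generations, lineages = lineages,
                 scaling_mode = scaling_mode,
                 custom_factor = custom_factor,
                 ori_override = ori_override,
                 ter_override = ter_override),
            class = "cdm_params")
}

#' Context-dependent mutation rates per (5' base, ref->alt, 3' base)
#'
#' Tallies the oriented variants into the 192-class keyspace
#' (4 upstream x 4 reference x 3 alternate x 4 downstream) and divides
#' each mutation count M by the matching triplet occurrence count times
#' G times N:
#'
#'   rate = M / (count(up.ref.down) * G * N)
#'
#' With the genome-wide triplet counts (GWTC) as denominator this is the
#' chromosome rate; with replichore-wide counts (RWTC) the replichore
#' rate. Entries whose triplet never occurs (denominator 0) have a
#' missing rate; a missing denominator with observed mutations is flagged
#' inconsistent and warned about, which indicates a convention mismatch
#' between the counts and the oriented variants.
#'
#' @param contexts Data frame of oriented variant contexts from
#'   [extract_context()] (already filtered to the region and oriented
#'   under the same strand convention as `counts`).
#' @param counts A `cdm_context_counts` with `k = 3` for the same region
#'   and strand convention.
#' @param params A [run_parameters()].
#' @param region Region label stored on the result.
#' @return An object of class `cdm_rates`: data.frame with 192 rows and
#'   columns `up`, `ref`, `alt`, `down`, `M`, `denominator`, `rate`,
#'   `scaled_rate`, `inconsistent`; attributes `region`, `strand`,
#'   `generations`, `lineages`, `scale_applied`.
#' @export
compute_rates <- function(contexts, counts, params, region = NULL) {
  stopifnot(inherits(counts, "cdm_context_counts"),
            inherits(params, "cdm_params"))
  if (counts$k != 3L)
    stop("rates require a k=3 context count table", call. = FALSE)
  region <- region %||% counts$region
  ks <- context_keyspace()
  key <- paste(ks$up, ks$ref, ks$alt, ks$down)
  M <- stats::setNames(integer(nrow(ks)), key)
  if (nrow(contexts)) {
    obs <- paste(contexts$oriented_up, contexts$oriented_ref,
                 contexts$oriented_alt, contexts$oriented_down)
    tab <- table(obs)
    unknown <- setdiff(names(tab), key)
    if (length(unknown))
      stop("oriented contexts outside the A/C/G/T keyspace: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    M[names(tab)] <- as.integer(tab)
  }
  trip <- paste0(ks$up, ks$ref, ks$down)
  den <- as.numeric(counts$counts[trip])
  G <- params$generations; N <- params$lineages
  rate <- ifelse(den > 0, M / (den * G * N), NA_real_)
  inconsistent <- den == 0 & M > 0
  if (any(inconsistent))
    warning(sum(inconsistent), " context class(es) observed with a zero ",
            "denominator; flagged inconsistent", call. = FALSE)
  out <- data.frame(ks, M = as.integer(M), denominator = den, rate = rate,
                    scaled_rate = NA_real_, inconsistent = inconsistent,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cdm_rates", "data.frame"), region = region,
            strand = counts$strand, generations = G, lineages = N,
            scale_applied = NA_real_)
}

#' Aggregate a 192-class rate matrix to the 64 triplets
#'
#' Sums mutation counts and rates over the three alternate bases of each
#' triplet; triplets with a zero denominator (all three entries missing)
#' keep a missing rate.
#'
#' @param matrix A `cdm_rates`.
#' @return Data frame with 64 rows: `triplet`, `M_total`, `rate_total`.
#' @export
aggregate_to_triplets <- function(matrix) {
  stopifnot(inherits(matrix, "cdm_rates"))
  trip <- paste0(matrix$up, matrix$ref, matrix$down)
  keys <- kmer_keyspace(3L)
  M_total <- as.integer(rowsum(matrix$M, trip)[keys, 1L])
  rate_total <- vapply(keys, function(t) {
    r <- matrix$rate[trip == t]
    if (all(is.na(r))) NA_real_ else sum(r, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(triplet = keys, M_total = M_total, rate_total = rate_total,
             stringsAsFactors = FALSE)
}

#' Conditional mutation rates per triplet
#'
#' Normalises each triplet's mutation count to the genome-wide content of
#' its mutable (center) nucleotide rather than to the triplet occurrence
#' count: `M_total(t) / (count(center base) * G * N)`.
#'
#' @param matrix A `cdm_rates`.
#' @param genome_base_counts Named per-base totals (as from the genome or
#'   region the matrix was computed on).
#' @return Data frame with 64 rows: `triplet`, `M_total`,
#'   `conditional_rate`.
#' @export
conditional_rates <- function(matrix, genome_base_counts) {
  agg <- aggregate_to_triplets(matrix)
  center <- substr(agg$triplet, 2L, 2L)
  nb <- as.numeric(genome_base_counts[center])
  nb[is.na(nb)] <- 0
  G <- attr(matrix, "generations"); N <- attr(matrix, "lineages")
  agg$conditional_rate <- ifelse(nb > 0, agg$M_total / (nb * G * N),
                                 NA_real_)
  agg[, c("triplet", "M_total", "conditional_rate")]
}

#' Scale rates for display
#'
#' Fills the `scaled_rate` column: the default mode divides by 1e-8 (so a
#' rate of 3e-8 displays as 3.0), `mean_scaled` divides by the mean of
#' non-missing rates, `custom` divides by `params$custom_factor`. The
#' unscaled rates are retained.
#'
#' @param matrix A `cdm_rates`.
#' @param params A [run_parameters()] carrying the scaling mode.
#' @return The matrix with `scaled_rate` filled and `scale_applied` set.
#' @export
apply_scaling <- function(matrix, params) {
  stopifnot(inherits(matrix, "cdm_rates"), inherits(params, "cdm_params"))
  factor <- switch(params$scaling_mode,
    "default_1e-8" = 1e-8,
    "mean_scaled" = {
      m <- mean(matrix$rate, na.rm = TRUE)
      if (!is.finite(m) || m == 0)
        stop("mean of rates is zero; cannot mean-scale", call. = FALSE)
      m
    },
    "custom" = params$custom_factor)
  matrix$scaled_rate <- matrix$rate / factor
  attr(matrix, "scale_applied") <- factor
  matrix
}

#' Write a rate matrix as CSV
#'
#' Columns `up,ref,alt,down,region,M,denominator,rate,scaled_rate`, 192
#' data rows, full precision.
#'
#' @param matrix A `cdm_rates`.
#' @param path Output path.
#' @export
write_rates_csv <- function(matrix, path) {
  df <- data.frame(up = matrix$up, ref = matrix$ref, alt = matrix$alt,
                   down = matrix$down,
                   region = attr(matrix, "region") %||% "genome",
                   M = matrix$M, denominator = matrix$denominator,
                   rate = sprintf("%.17g", matrix$rate),
                   scaled_rate = sprintf("%.17g", matrix$scaled_rate),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rate matrix CSV written by [write_rates_csv()]
#' @param path CSV path.
#' @return Data frame with numeric `rate`/`scaled_rate` columns.
#' @export
read_rates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "nan"))
  df$rate <- as.numeric(df$rate)
  df$scaled_rate <- as.numeric(df$scaled_rate)
  df
}
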