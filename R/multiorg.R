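#' GC content of the coding fraction of a genome
#'
#' GC fraction over the union of CDS spans (plus-strand reading; GC
#' content is strand-invariant). With no CDS the genome-wide GC is
#' returned with a warning.
#'
#' @param genome A [cdm_genome()].
#' @param annotations A `cdm_annotation` (or `NULL`).
#' @return Fraction in `[0, 1]`.
#' @export
coding_gc <- function(genome, annotations = NULL) {
  L <- genome$length
  cds <- if (is.null(annotations)) NULL else
    annotations[annotations$kind == "CDS", , drop = FALSE]
  if (is.null(cds) || !nrow(cds)) {
    warning("no CDS features; falling back to genome-wide GC",
            call. = FALSE)
    return(gc_fraction(genome$sequence))
  }
  covered <- logical(L)
  for (i in seq_len(nrow(cds))) {
    segs <- cds$segments[[i]]
    for (j in seq_len(nrow(segs)))
      covered[segs[j, 1L]:segs[j, 2L]] <- TRUE
  }
  bases <- substring(genome$sequence, which(covered), which(covered))
  n <- sum(bases != "N")
  if (!n) return(NA_real_)
  sum(bases %in% c("G", "C")) / n
}

#' Per-run summary used for cross-organism comparison
#'
#' @param run_id Run identifier.
#' @param rate_vector Numeric 192-vector of unscaled rates in canonical
#'   lexicographic `(up, ref, alt, down)` order (names optional).
#' @param gc_content_coding,gc_content_genome GC fractions.
#' @param basis Which rate vector this is (`"chromosome"`, `"strand"`,
#'   `"replichore"` or similar); vectors are only comparable within one
#'   basis. Concatenated bases (e.g. both replichores) may exceed 192
#'   entries.
#' @param strand_convention Convention tag carried for compatibility
#'   checks.
#' @return An object of class `cdm_run_summary`.
#' @export
organism_summary <- function(run_id, rate_vector, gc_content_coding,
                             gc_content_genome = NA_real_,
                             basis = "chromosome",
                             strand_convention = "lagging_template_revcomp") {
  stopifnot(is.numeric(rate_vector))
  structure(list(run_id = as.character(run_id),
                 rate_vector = as.numeric(rate_vector),
                 gc_content_coding = as.numeric(gc_content_coding),
                 gc_content_genome = as.numeric(gc_content_genome),
                 basis = basis, strand_convention = strand_convention),
            class = "cdm_run_summary")
}

# Pearson r on pairwise-complete entries; NA if < 3 complete pairs or a
# constant vector
pairwise_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, n = n))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("constant rate vector: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = n))
  }
  list(r = stats::cor(x[ok], y[ok]), n = n)
}

#' One-to-many Pearson correlation of rate spectra
#'
#' Correlates the focal organism's unscaled 192-entry rate vector with
#' each other organism's (and with itself), on pairwise-complete entries.
#'
#' @param focal A [organism_summary()].
#' @param others List of [organism_summary()] objects.
#' @return An object of class `cdm_correlation`: list with `pairs`
#'   (data.frame `run_a`, `run_b`, `r`, `n_complete`), `row_order`,
#'   `col_order` (unsorted until [order_by_gc()]).
#' @export
one_to_many_correlation <- function(focal, others) {
  stopifnot(inherits(focal, "cdm_run_summary"), length(others) >= 1L)
  all_runs <- c(list(focal), others)
  bases <- vapply(all_runs, `[[`, character(1), "basis")
  if (length(unique(bases)) != 1L)
    stop("all runs must share the same comparison basis", call. = FALSE)
  lens <- vapply(all_runs, function(s) length(s$rate_vector), integer(1))
  if (length(unique(lens)) != 1L)
    stop("rate vectors differ in length", call. = FALSE)
  rows <- lapply(all_runs, function(s) {
    p <- pairwise_pearson(focal$rate_vector, s$rate_vector)
    data.frame(run_a = focal$run_id, run_b = s$run_id, r = p$r,
               n_complete = p$n, stringsAsFactors = FALSE)
  })
  ids <- vapply(all_runs, `[[`, character(1), "run_id")
  structure(list(pairs = do.call(rbind, rows), row_order = ids,
                 col_order = ids), class = "cdm_correlation")
}

#' All-pairs Pearson correlation table across runs
#'
#' @param summaries List of [organism_summary()] objects (>= 2).
#' @return A `cdm_correlation` with a full symmetric `pairs` table.
#' @export
pairwise_correlations <- function(summaries) {
  stopifnot(length(summaries) >= 2L)
  ids <- vapply(summaries, `[[`, character(1), "run_id")
  rows <- list()
  for (i in seq_along(summaries)) for (j in seq_along(summaries)) {
    p <- pairwise_pearson(summaries[[i]]$rate_vector,
                          summaries[[j]]$rate_vector)
    rows[[length(rows) + 1L]] <-
      data.frame(run_a = ids[i], run_b = ids[j], r = p$r,
                 n_complete = p$n, stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, rows), row_order = ids,
                 col_order = ids), class = "cdm_correlation")
}

#' Order a correlation table by GC content
#'
#' Rows are ordered from AT-rich (lowest GC) to GC-rich; columns from
#' GC-rich to AT-rich, matching the usual display of cross-taxon
#' mutation-spectrum heatmaps. Ties break lexicographically by run id,
#' so the output is invariant to the input order of the runs.
#'
#' @param table A `cdm_correlation`.
#' @param summaries List of [organism_summary()] covering every run id in
#'   the table.
#' @return The table with `row_order`/`col_order` set.
#' @export
order_by_gc <- function(table, summaries) {
  stopifnot(inherits(table, "cdm_correlation"))
  ids <- vapply(summaries, `[[`, character(1), "run_id")
  gc <- vapply(summaries, `[[`, numeric(1), "gc_content_coding")
  need <- unique(c(table$pairs$run_a, table$pairs$run_b))
  if (!all(need %in% ids))
    stop("GC content unknown for runs: ",
         paste(setdiff(need, ids), collapse = ", "), call. = FALSE)
  keep <- ids %in% need
  ids <- ids[keep]; gc <- gc[keep]
  table$row_order <- ids[order(gc, ids)]
  table$col_order <- ids[order(-gc, ids)]
  table
}

# correlation table as an r matrix in row_order x col_order
correlation_matrix <- function(table) {
  m <- matrix(NA_real_, length(table$row_order), length(table$col_order),
              dimnames = list(table$row_order, table$col_order))
  for (i in seq_len(nrow(table$pairs))) {
    a <- table$pairs$run_a[i]; b <- table$pairs$run_b[i]
    if (a %in% rownames(m) && b %in% colnames(m))
      m[a, b] <- table$pairs$r[i]
    if (b %in% rownames(m) && a %in% colnames(m))
      m[b, a] <- table$pairs$r[i]
  }
  m
}

#' Write a correlation table as CSV (pairs + ordered matrix)
#' @param table A `cdm_correlation`.
#' @param pairs_path,matrix_path Output paths (`NULL` to skip either).
#' @export
write_correlation_csv <- function(table, pairs_path = NULL,
                                  matrix_path = NULL) {
  if (!is.null(pairs_path)) {
    df <- table$pairs
    df$r <- sprintf("%.17g", df$r)
    utils::write.csv(df, pairs_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(matrix_path)) {
    m <- correlation_matrix(table)
    out <- data.frame(run = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, matrix_path, row.names = FALSE)
  }
  invisible(NULL)
}
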