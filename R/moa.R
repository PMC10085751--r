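#' Run the multi-organism comparison over completed single-organism runs
#'
#' Discovers completed run directories (those containing
#' `run_meta.json`) under `root`, loads each run's unscaled rate vector
#' on the requested basis, computes all-pairs Pearson correlations on
#' pairwise-complete entries, orders rows and columns by coding-region
#' GC content, and writes the pair table, the ordered matrix and a
#' heatmap under `root/moa/`.
#'
#' @param root Output root holding >= 2 completed runs.
#' @param basis `"chromosome"` (genome-wide matrix),
#'   `"strand"` (reference + complement readings concatenated) or
#'   `"replichore"` (left + right matrices concatenated).
#' @param figures Render the heatmap.
#' @return An ordered `cdm_correlation`, invisibly; outputs under
#'   `root/moa/`.
#' @export
run_moa <- function(root, basis = c("chromosome", "strand", "replichore"),
                    figures = TRUE) {
  basis <- match.arg(basis)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  metas <- file.path(dirs, "run_meta.json")
  metas <- metas[file.exists(metas)]
  if (length(metas) < 2L)
    stop("multi-organism analysis needs at least 2 completed runs under ",
         root, " (found ", length(metas), ")", call. = FALSE)
  summaries <- lapply(metas, function(m) load_run_summary(dirname(m),
                                                          basis))
  summaries <- summaries[order(vapply(summaries, `[[`, character(1),
                                      "run_id"))]
  table <- pairwise_correlations(summaries)
  table <- order_by_gc(table, summaries)
  moa_dir <- file.path(root, "moa")
  dir.create(moa_dir, recursive = TRUE, showWarnings = FALSE)
  write_correlation_csv(table,
                        pairs_path = file.path(moa_dir,
                                               "correlation_pairs.csv"),
                        matrix_path = file.path(moa_dir,
                                                "correlation_matrix.csv"))
  if (figures)
    render_correlation_heatmap(
      table, figure_spec("correlation_heatmap",
                         file.path(moa_dir, "correlation_heatmap.png")))
  invisible(table)
}

# build an organism summary from a written run directory
load_run_summary <- function(run_dir, basis = "chromosome") {
  meta <- jsonlite::fromJSON(file.path(run_dir, "run_meta.json"))
  vec_of <- function(file) {
    df <- read_rates_csv(file.path(run_dir, "rates", file))
    df$rate
  }
  rate_vector <- switch(basis,
    chromosome = vec_of("rates_genome.csv"),
    strand = c(vec_of("rates_genome.csv"),
               vec_of("rates_genome_complement.csv")),
    replichore = c(vec_of("rates_left_replichore.csv"),
                   vec_of("rates_right_replichore.csv")))
  organism_summary(meta$run_id, rate_vector,
                   gc_content_coding = meta$gc_content_coding,
                   gc_content_genome = meta$gc_content_genome,
                   basis = basis,
                   strand_convention = meta$convention)
}
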