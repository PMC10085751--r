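#' Build and validate a single-organism run configuration
#'
#' @param fasta,genbank,variants Input file paths (must exist).
#' @param dialect Variant dialect, `"vcf"` or `"basecall"`.
#' @param generations,lineages MA experiment parameters G and N.
#' @param scaling Scaling mode: `"default_1e-8"`, `"mean_scaled"`,
#'   `"custom"`, or the numeric codes `0`/`1`/`2` in that order.
#' @param scale_factor Custom scaling divisor (mode `"custom"` only).
#' @param ori,ter Manual ORI/TER (1-based; 0 normalised to 1). Both
#'   `NULL` means automatic skew-based detection.
#' @param convention Strand convention for replichore rates.
#' @param k_set Context widths to tabulate (3 always included).
#' @param n_bins Spatial bin count.
#' @param out Output root directory.
#' @param run_id Filesystem-safe run identifier.
#' @param circular Treat the genome as circular.
#' @param overwrite Allow overwriting an existing run directory.
#' @param figures Render figures.
#' @return An object of class `cdm_config`.
#' @export
soa_config <- function(fasta, genbank, variants,
                       dialect = c("vcf", "basecall"),
                       generations, lineages, scaling = "default_1e-8",
                       scale_factor = NULL, ori = NULL, ter = NULL,
                       convention = c("lagging_template_revcomp",
                                      "as_reference"),
                       k_set = c(3L), n_bins = 25L, out = "cdm_output",
                       run_id = "run1", circular = TRUE,
                       overwrite = FALSE, figures = TRUE) {
  dialect <- match.arg(dialect)
  convention <- match.arg(convention)
  scaling <- as.character(scaling)
  mode <- switch(scaling, "0" = "default_1e-8", "1" = "mean_scaled",
                 "2" = "custom", scaling)
  for (p in c(fasta, genbank, variants))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  if (grepl("[^A-Za-z0-9._-]", run_id))
    stop("run_id must be filesystem-safe ([A-Za-z0-9._-])", call. = FALSE)
  if (xor(is.null(ori), is.null(ter)))
    stop("supply both ORI and TER, or neither (automatic detection)",
         call. = FALSE)
  params <- run_parameters(generations, lineages, scaling_mode = mode,
                           custom_factor = scale_factor,
                           ori_override = if (!is.null(ori))
                             as.integer(ori),
                           ter_override = if (!is.null(ter))
                             as.integer(ter))
  k_set <- sort(unique(as.integer(c(3L, k_set))))
  structure(list(fasta = fasta, genbank = genbank, variants = variants,
                 dialect = dialect, params = params,
                 convention = convention, k_set = k_set,
                 n_bins = as.integer(n_bins), out = out, run_id = run_id,
                 circular = isTRUE(circular), overwrite = overwrite,
                 figures = isTRUE(figures)),
            class = "cdm_config")
}

#' Build a run configuration from interactive-style answers
#'
#' Maps the prompt dialogue (output name; vcf/basecall; FASTA, GenBank
#' and variant paths; generations; lineages; scaling code 0/1/2; manual
#' ORI/TER yes/no; ORI; TER) onto [soa_config()], with a "0" ORI
#' normalised to position 1. Answer order matches the prompt transcript,
#' so scripted and interactive use produce identical configurations.
#'
#' @param answers Character vector of answers in prompt order.
#' @param out Output root directory.
#' @return A `cdm_config`.
#' @export
soa_config_from_answers <- function(answers, out = "cdm_output") {
  a <- as.character(answers)
  if (length(a) < 9L) stop("expected at least 9 answers", call. = FALSE)
  manual <- tolower(a[9L]) %in% c("yes", "y", "true")
  ori <- ter <- NULL
  if (manual) {
    if (length(a) < 11L)
      stop("manual ORI/TER requested but not supplied", call. = FALSE)
    ori <- as.integer(a[10L]); ter <- as.integer(a[11L])
    if (ori == 0L) ori <- 1L
    if (ter == 0L) ter <- 1L
  }
  soa_config(fasta = a[3L], genbank = a[4L], variants = a[5L],
             dialect = a[2L], generations = as.numeric(a[6L]),
             lineages = as.integer(a[7L]), scaling = a[8L],
             ori = ori, ter = ter, out = out, run_id = a[1L])
}

#' Run the single-organism analysis pipeline
#'
#' Reads the genome, annotation and variants; determines ORI/TER (manual
#' override or cumulative-skew detection); partitions the chromosome into
#' replichores; tabulates context occurrence counts for the chromosome
#' and both replichores on both strands; orients each variant's local
#' context; computes chromosome-wide, per-replichore and conditional
#' context-dependent mutation rates; scales them for display; bins
#' mutations from the ORI; and writes CSVs, JSON and figures into a
#' per-run output tree. A machine-readable run log records the record
#' counts at every filtering step.
#'
#' @param config A [soa_config()].
#' @return An object of class `cdm_run` (invisibly contains all result
#'   tables and the output directory).
#' @export
run_soa <- function(config) {
  stopifnot(inherits(config, "cdm_config"))
  params <- config$params
  log <- list()
  genome <- read_fasta(config$fasta, circular = config$circular)
  annotations <- read_genbank(config$genbank)
  variants <- read_variants(config$variants, config$dialect, genome)
  log$n_candidates <- nrow(variants$records) + variants$n_excluded
  log$n_retained <- nrow(variants$records)
  log$n_excluded_load <- variants$n_excluded

  skew <- NULL
  if (!is.null(params$ori_override)) {
    frame <- replication_frame(params$ori_override, params$ter_override,
                               genome$length, circular = genome$circular,
                               source = "user")
  } else {
    has_cds <- !is.null(usable_cds(annotations)) &&
      nrow(usable_cds(annotations)) > 0L
    skew <- cumulative_skew(genome, annotations,
                            site_set = if (has_cds)
                              "synonymous_third_codon" else "all_sites")
    frame <- detect_ori_ter(skew, genome$length,
                            circular = genome$circular)
  }

  counts <- list()
  for (k in config$k_set)
    for (region in c("genome", "right_replichore", "left_replichore"))
      for (strand in c("reference", "complement"))
        counts[[sprintf("k%d_%s_%s", k, region, strand)]] <-
          count_contexts(genome, frame, k, region, strand)

  ctx_ref <- extract_context(genome, frame, variants,
                             convention = "as_reference")
  ctx_conv <- if (config$convention == "as_reference") ctx_ref else
    extract_context(genome, frame, variants, convention = config$convention)
  log$n_context_excluded <- nrow(ctx_conv$exclusion_log)
  log$n_oriented <- nrow(ctx_conv$contexts)

  cc <- ctx_conv$contexts
  right_strand <- if (config$convention == "lagging_template_revcomp")
    "complement" else "reference"
  # complement-strand reading of the whole chromosome: every context
  # reverse-complemented, denominators from the complement-strand GWTC
  comp_all <- extract_all_revcomp(ctx_ref$contexts)
  rates <- list(
    genome = compute_rates(ctx_ref$contexts,
                           counts[["k3_genome_reference"]], params),
    genome_complement = compute_rates(
      comp_all, counts[["k3_genome_complement"]], params),
    left_replichore = compute_rates(
      cc[cc$replichore == "left", , drop = FALSE],
      counts[["k3_left_replichore_reference"]], params),
    right_replichore = compute_rates(
      cc[cc$replichore == "right", , drop = FALSE],
      counts[[sprintf("k3_right_replichore_%s", right_strand)]], params))
  rates <- lapply(rates, apply_scaling, params = params)
  conditional <- conditional_rates(rates$genome, base_counts(genome))
  bins <- bin_mutations(variants, frame, config$n_bins, params)
  codon_usage <- list(
    genome = count_codon_usage(genome, annotations, frame, "genome"),
    right_replichore = count_codon_usage(genome, annotations, frame,
                                         "right_replichore"),
    left_replichore = count_codon_usage(genome, annotations, frame,
                                        "left_replichore"))
  gc_coding <- tryCatch(coding_gc(genome, annotations),
                        warning = function(w) gc_fraction(genome$sequence))
  log$generations <- params$generations
  log$lineages <- params$lineages
  log$scaling_mode <- params$scaling_mode
  log$ori <- frame$ori; log$ter <- frame$ter
  log$frame_source <- frame$source

  run <- structure(list(
    run_id = config$run_id, config = config, genome = genome,
    annotations = annotations, variants = variants, frame = frame,
    skew = skew, counts = counts, contexts = ctx_conv$contexts,
    contexts_reference = ctx_ref$contexts, rates = rates,
    conditional = conditional, bins = bins, codon_usage = codon_usage,
    gc_content_coding = gc_coding,
    gc_content_genome = gc_fraction(genome$sequence), log = log),
    class = "cdm_run")
  run$out_dir <- write_outputs(run, config$out,
                               overwrite = config$overwrite,
                               figures = config$figures)
  invisible(run)
}

# revcomp every context row (complement-strand reading of the chromosome)
extract_all_revcomp <- function(contexts) {
  comp <- function(x) chartr("ACGTN", "TGCAN", x)
  out <- contexts
  out$oriented_up <- comp(contexts$down_base)
  out$oriented_ref <- comp(contexts$ref)
  out$oriented_alt <- comp(contexts$alt)
  out$oriented_down <- comp(contexts$up_base)
  out$oriented_triplet <- paste0(out$oriented_up, out$oriented_ref,
                                 out$oriented_down)
  out
}

#' Write the output tree of a completed run
#'
#' Deterministic layout
#' `<out>/<run_id>/{counts,rates,correlation,bins,figures}/` with
#' fixed-column CSVs that round-trip through the matching readers, a
#' circular-visualization JSON export, and machine-readable
#' `run_meta.json` / `run_log.json`. Refuses an existing run directory
#' unless `overwrite` is set.
#'
#' @param run A `cdm_run`.
#' @param out Output root.
#' @param overwrite Logical.
#' @param figures Render figures.
#' @return The run directory path.
#' @export
write_outputs <- function(run, out, overwrite = FALSE, figures = TRUE) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rd <- file.path(out, run$run_id)
  if (dir.exists(rd)) {
    if (!overwrite)
      stop("run directory exists: ", rd,
           " (set overwrite = TRUE to replace it)", call. = FALSE)
    unlink(rd, recursive = TRUE)
  }
  for (d in c("counts", "rates", "correlation", "bins", "figures"))
    dir.create(file.path(rd, d), recursive = TRUE, showWarnings = FALSE)

  for (nm in names(run$counts))
    write_counts_csv(run$counts[[nm]],
                     file.path(rd, "counts", paste0(nm, ".csv")))
  if (!is.null(run$skew))
    write_skew_csv(run$skew, file.path(rd, "counts", "skew_profile.csv"))
  for (nm in names(run$codon_usage))
    utils::write.csv(data.frame(codon = names(run$codon_usage[[nm]]$counts),
                                count = as.integer(
                                  run$codon_usage[[nm]]$counts)),
                     file.path(rd, "counts",
                               paste0("codon_usage_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  for (nm in names(run$rates))
    write_rates_csv(run$rates[[nm]],
                    file.path(rd, "rates", paste0("rates_", nm, ".csv")))
  cond <- run$conditional
  cond$conditional_rate <- sprintf("%.17g", cond$conditional_rate)
  utils::write.csv(cond, file.path(rd, "rates", "conditional_genome.csv"),
                   row.names = FALSE, quote = FALSE)
  write_bins_csv(run$bins, file.path(rd, "bins", "bins.csv"))
  export_circular_viz_json(list(list(run_id = run$run_id, frame = run$frame,
                              bins = run$bins, rates = run$rates$genome,
                              conditional = run$conditional)),
                    file.path(rd, "bins", "circular_viz.json"))

  meta <- list(run_id = run$run_id, genome_id = run$genome$id,
               genome_length = run$genome$length,
               circular = run$genome$circular, ori = run$frame$ori,
               ter = run$frame$ter, frame_source = run$frame$source,
               convention = run$config$convention,
               generations = run$config$params$generations,
               lineages = run$config$params$lineages,
               scaling_mode = run$config$params$scaling_mode,
               gc_content_coding = run$gc_content_coding,
               gc_content_genome = run$gc_content_genome,
               n_bins = attr(run$bins, "n_bins"),
               n_variants = nrow(run$variants$records),
               n_excluded = run$variants$n_excluded)
  jsonlite::write_json(meta, file.path(rd, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(run$log, file.path(rd, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (figures) {
    render_rate_heatmap(
      run$rates[c("left_replichore", "right_replichore")],
      figure_spec("rate_heatmap",
                  file.path(rd, "figures", "rate_heatmap.png")))
    if (!is.null(run$skew))
      render_skew_profile(run$skew, run$frame,
                          figure_spec("skew_profile",
                                      file.path(rd, "figures",
                                                "skew_profile.png")))
    render_bin_track(run$bins,
                     figure_spec("bin_track",
                                 file.path(rd, "figures",
                                           "bin_track.png")))
  }
  rd
}
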