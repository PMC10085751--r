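#' Generate a synthetic genome with an optional planted skew structure
#'
#' Bases are drawn i.i.d. at the requested GC content. When `skew` is
#' given, the arc from `ori_target` toward increasing coordinates up to
#' `ter_target` is enriched for G over C by `skew_strength` (and the
#' complementary arc for C over G), so the cumulative GC-skew profile has
#' its minimum near the planted origin and its maximum near the planted
#' terminus. The boundary bases are anchored so the skew flips exactly at
#' the planted switch points (C|G across the origin, G|C across the
#' terminus); with `skew_strength = 1` each arc is pure-G or pure-C among
#' its S/W draws and detection recovers the planted landmarks to within
#' one site.
#'
#' Draws use one named substream per generator stage, so adding stages
#' never perturbs earlier draws and every output is reproducible from
#' `seed` alone.
#'
#' @param length Genome length (>= 3).
#' @param gc_fraction Target GC fraction in (0, 1).
#' @param circular Logical.
#' @param skew Optional list with `ori_target`, `ter_target`,
#'   `skew_strength` in (0, 1].
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return List with `genome` (a [cdm_genome()]) and `manifest` (planted
#'   parameters plus exact per-base tallies).
#' @export
generate_genome <- function(length, gc_fraction, circular = TRUE,
                            skew = NULL, seed = 1L, id = "synth") {
  stopifnot(length >= 3L, gc_fraction > 0, gc_fraction < 1)
  L <- as.integer(length)
  if (!is.null(skew)) {
    stopifnot(all(c("ori_target", "ter_target", "skew_strength") %in%
                    names(skew)))
    if (skew$ori_target < 1L || skew$ori_target > L ||
        skew$ter_target < 1L || skew$ter_target > L ||
        skew$ori_target == skew$ter_target)
      stop("skew targets must be distinct positions in [1, length]",
           call. = FALSE)
    if (skew$skew_strength <= 0 || skew$skew_strength > 1)
      stop("skew_strength must be in (0, 1]", call. = FALSE)
  }
  bases <- with_stage_seed(seed, "genome", {
    if (is.null(skew)) {
      p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
      sample(DNA_BASES, L, replace = TRUE, prob = p[DNA_BASES])
    } else {
      s <- skew$skew_strength
      frame <- replication_frame(skew$ori_target, skew$ter_target, L,
                                 circular = circular, source = "user")
      right <- assign_replichore(frame, seq_len(L)) == "right"
      b <- character(L)
      p_right <- c(A = (1 - gc_fraction) / 2,
                   C = gc_fraction * (1 - s) / 2,
                   G = gc_fraction * (1 + s) / 2,
                   T = (1 - gc_fraction) / 2)
      p_left <- p_right[c("A", "G", "C", "T")]
      names(p_left) <- c("A", "C", "G", "T")
      b[right] <- sample(DNA_BASES, sum(right), replace = TRUE,
                         prob = p_right[DNA_BASES])
      b[!right] <- sample(DNA_BASES, sum(!right), replace = TRUE,
                          prob = p_left[DNA_BASES])
      # plant sharp switch points: the skew flips exactly across the
      # origin (…C|G…) and terminus (…G|C…) boundaries, so the profile
      # extrema are attained at the boundary bases themselves rather
      # than drifting along an A/T plateau
      b[wrap_pos(frame$ori - 1L, L)] <- "C"
      b[frame$ori] <- "G"
      b[wrap_pos(frame$ter - 1L, L)] <- "G"
      b[frame$ter] <- "C"
      b
    }
  })
  genome <- cdm_genome(id, paste0(bases, collapse = ""),
                       circular = circular)
  list(genome = genome,
       manifest = list(seed = seed, length = L,
                       gc_fraction = gc_fraction, circular = circular,
                       skew = skew,
                       base_tallies = as.list(base_counts(genome))))
}

#' Generate non-overlapping CDS annotations and a GenBank file
#'
#' Places `n_cds` non-overlapping CDS features with lengths divisible by
#' 3 on random strands, writes them as a GenBank flat file that
#' [read_genbank()] round-trips, and records exact planted codon tallies
#' (minus-strand CDS read as reverse complements).
#'
#' @param genome A [cdm_genome()].
#' @param n_cds Number of CDS features to place.
#' @param seed Integer seed.
#' @param path Optional GenBank output path.
#' @param len_range Range of CDS lengths (rounded down to a multiple
#'   of 3).
#' @return List with `annotations` (a `cdm_annotation`), `path` (or
#'   `NULL`), and `manifest` holding the planted codon tallies.
#' @export
generate_annotations <- function(genome, n_cds, seed = 1L, path = NULL,
                                 len_range = c(60L, 300L)) {
  L <- genome$length
  placed <- with_stage_seed(seed, "annotations", {
    lens <- sample(seq(len_range[1L], len_range[2L], by = 3L), n_cds,
                   replace = TRUE)
    strands <- sample(c("+", "-"), n_cds, replace = TRUE)
    taken <- logical(L)
    out <- list()
    for (i in seq_len(n_cds)) {
      ok <- FALSE
      for (try in 1:200) {
        st <- sample.int(L - lens[i], 1L)
        span <- st:(st + lens[i] - 1L)
        if (!any(taken[span])) { taken[span] <- TRUE; ok <- TRUE; break }
      }
      if (!ok) stop("cannot place ", n_cds,
                    " non-overlapping CDS on this genome", call. = FALSE)
      out[[i]] <- list(start = st, end = st + lens[i] - 1L,
                       strand = strands[i])
    }
    out
  })
  ann <- data.frame(
    start = vapply(placed, `[[`, integer(1), "start"),
    end = vapply(placed, `[[`, integer(1), "end"),
    strand = vapply(placed, `[[`, character(1), "strand"),
    kind = rep("CDS", length(placed)),
    locus_tag = sprintf("SYN_%04d", seq_along(placed)),
    partial = rep(FALSE, length(placed)),
    compound = rep(FALSE, length(placed)), stringsAsFactors = FALSE)
  ann$segments <- lapply(placed, function(p)
    matrix(c(p$start, p$end), 1L, 2L))
  ann <- ann[order(ann$start), ]
  rownames(ann) <- NULL
  ann$locus_tag <- sprintf("SYN_%04d", seq_len(nrow(ann)))
  class(ann) <- c("cdm_annotation", "data.frame")

  # independent codon bookkeeping by direct slicing
  codon_tally <- stats::setNames(integer(64L), kmer_keyspace(3L))
  for (i in seq_len(nrow(ann))) {
    s <- substr(genome$sequence, ann$start[i], ann$end[i])
    if (ann$strand[i] == "-") s <- reverse_complement(s)
    cods <- substring(s, seq(1L, nchar(s) - 2L, 3L),
                      seq(3L, nchar(s), 3L))
    tab <- table(cods)
    codon_tally[names(tab)] <- codon_tally[names(tab)] + as.integer(tab)
  }
  if (!is.null(path)) write_genbank(genome, ann, path)
  list(annotations = ann, path = path,
       manifest = list(seed = seed, n_cds = nrow(ann),
                       codon_tallies = as.list(codon_tally)))
}

#' Plant context-dependent mutations at known rates
#'
#' For each `(triplet context, alt)` pair in `u_true`, the number of
#' mutations is drawn as `Poisson(occurrences * G * N * u)` over the
#' sites whose reference-strand triplet matches the context (circular
#' wrap included), or taken as `round(...)` in exact-count mode; mutated
#' sites are sampled uniformly without replacement within each context.
#' The exact planted per-(context, alt) counts are recorded in the
#' manifest, so downstream rate recovery can be checked exactly.
#'
#' `u_true` is keyed on reference-strand contexts, e.g.
#' `list("ACG" = c(T = 2e-8))` plants `A[C->T]G` mutations.
#'
#' @param genome A [cdm_genome()].
#' @param u_true Named list: triplet -> named numeric vector of per-alt
#'   rates (per site per generation).
#' @param G,N Generations and lineage count.
#' @param seed Integer seed.
#' @param exact Logical; use deterministic expected counts instead of
#'   Poisson draws.
#' @param vcf_path,basecall_path Optional output files.
#' @return List with `variants` (a `cdm_variants`), the file paths, and
#'   `manifest` (exact planted counts, keyed `"TRIPLET>ALT"`).
#' @export
plant_mutations <- function(genome, u_true, G, N, seed = 1L,
                            exact = FALSE, vcf_path = NULL,
                            basecall_path = NULL) {
  L <- genome$length
  stopifnot(length(u_true) >= 1L)
  # site index: positions by reference triplet (center base coordinate)
  ext <- if (genome$circular)
    paste0(substr(genome$sequence, L, L), genome$sequence,
           substr(genome$sequence, 1L, 1L))
  else genome$sequence
  offs <- if (genome$circular) 1L else 0L
  centers <- if (genome$circular) seq_len(L) else 2L:(L - 1L)
  trips <- substring(ext, centers - 1L + offs, centers + 1L + offs)

  planted <- list()
  rows <- with_stage_seed(seed, "mutations", {
    out <- list()
    for (ctx in names(u_true)) {
      stopifnot(nchar(ctx) == 3L, !grepl("[^ACGT]", ctx))
      sites <- centers[trips == ctx]
      occ <- length(sites)
      alts <- u_true[[ctx]]
      stopifnot(!is.null(names(alts)),
                all(names(alts) %in% DNA_BASES),
                !substr(ctx, 2L, 2L) %in% names(alts))
      m_alt <- vapply(names(alts), function(a) {
        lambda <- occ * G * N * alts[[a]]
        if (exact) as.integer(round(lambda)) else
          stats::rpois(1L, lambda)
      }, integer(1))
      if (sum(m_alt) > occ)
        stop("planted mutations for context ", ctx,
             " exceed its ", occ, " matching sites", call. = FALSE)
      chosen <- if (sum(m_alt) > 0)
        sample(sites, sum(m_alt), replace = FALSE) else integer()
      alt_vec <- rep(names(alts), m_alt)
      for (a in names(alts))
        planted[[paste0(ctx, ">", a)]] <- unname(m_alt[a])
      if (length(chosen))
        out[[length(out) + 1L]] <- data.frame(
          position = chosen, ref = substr(ctx, 2L, 2L), alt = alt_vec,
          stringsAsFactors = FALSE)
    }
    out
  })
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  rec <- rec[order(rec$position, rec$alt), , drop = FALSE]
  rec$lineage <- rep(NA_character_, nrow(rec))
  rec$source_line <- seq_len(nrow(rec)) + 3L  # after the VCF header lines
  rownames(rec) <- NULL
  variants <- structure(list(records = rec, n_excluded = 0L,
                             exclusion_log = data.frame(
                               source_line = integer(),
                               reason = character())),
                        class = "cdm_variants")
  if (!is.null(vcf_path)) write_vcf(rec, genome, vcf_path)
  if (!is.null(basecall_path)) write_basecall(rec, basecall_path)
  list(variants = variants, vcf_path = vcf_path,
       basecall_path = basecall_path,
       manifest = list(seed = seed, G = G, N = N, exact = exact,
                       u_true = u_true, planted_counts = planted,
                       n_variants = nrow(rec)))
}

#' Generate a complete synthetic study (genome + annotation + variants)
#'
#' Convenience wrapper bundling the three fixture stages into one
#' organism-like input set with a single manifest, writing FASTA,
#' GenBank, VCF and base-call files to a directory.
#'
#' The default genome is i.i.d. (no planted skew), matching the
#' manual-ORI/TER analysis route; pass a `skew` list to plant
#' skew-switch landmarks instead. Note that a maximal `skew_strength`
#' suppresses triplets mixing G and C, so skewed genomes suit
#' origin-detection checks while i.i.d. genomes suit rate recovery.
#'
#' @param dir Output directory (created).
#' @param length,gc_fraction,skew,n_cds Generator settings.
#' @param u_true,G,N,exact Mutation-planting settings.
#' @param seed Integer seed.
#' @param id Organism id.
#' @return List with the in-memory objects, file paths, and `manifest`.
#' @export
generate_study <- function(dir, length = 10000L, gc_fraction = 0.45,
                           skew = NULL, n_cds = 10L, u_true, G, N,
                           exact = FALSE, seed = 1L, id = "synth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(skew) && is.null(skew$ter_target))
    skew$ter_target <- as.integer(length / 2) + 1L
  g <- generate_genome(length, gc_fraction, circular = TRUE, skew = skew,
                       seed = seed, id = id)
  fasta <- file.path(dir, paste0(id, ".fasta"))
  writeLines(c(paste0(">", id), g$genome$sequence), fasta)
  a <- generate_annotations(g$genome, n_cds, seed = seed,
                            path = file.path(dir, paste0(id, ".gbk")))
  m <- plant_mutations(g$genome, u_true, G, N, seed = seed, exact = exact,
                       vcf_path = file.path(dir, paste0(id, ".vcf")),
                       basecall_path = file.path(dir,
                                                 paste0(id, ".csv")))
  manifest <- list(genome = g$manifest, annotations = a$manifest,
                   mutations = m$manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(genome = g$genome, annotations = a$annotations,
       variants = m$variants, fasta = fasta, genbank = a$path,
       vcf = m$vcf_path, basecall = m$basecall_path, manifest = manifest)
}
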