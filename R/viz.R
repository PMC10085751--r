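#' Figure specification
#'
#' @param kind One of `rate_heatmap`, `correlation_heatmap`,
#'   `triplet_stack`, `skew_profile`, `bin_track`.
#' @param path Output image path.
#' @param dpi Resolution.
#' @param zlim Optional numeric color-scale bounds (finite).
#' @return An object of class `cdm_figure_spec`.
#' @export
figure_spec <- function(kind = c("rate_heatmap", "correlation_heatmap",
                                 "triplet_stack", "skew_profile",
                                 "bin_track"),
                        path, dpi = 150, zlim = NULL) {
  kind <- match.arg(kind)
  if (!is.null(zlim) && (length(zlim) != 2L || any(!is.finite(zlim))))
    stop("zlim must be two finite numbers", call. = FALSE)
  structure(list(kind = kind, path = path, dpi = dpi, zlim = zlim),
            class = "cdm_figure_spec")
}

#' Value grid for a context rate heatmap
#'
#' 16 rows (the 5' x 3' flank pairs, lexicographic) by 4 columns (the
#' reference base), holding aggregated triplet rates (scaled when
#' available). Missing rates stay `NA`, distinct from true zeros.
#'
#' @param matrix A `cdm_rates`.
#' @param use_scaled Use `scaled_rate` when filled.
#' @return 16 x 4 numeric matrix, dimnames `c("flanks", "ref")`.
#' @export
build_rate_grid <- function(matrix, use_scaled = TRUE) {
  vals <- if (use_scaled && !all(is.na(matrix$scaled_rate)))
    matrix$scaled_rate else matrix$rate
  trip <- paste0(matrix$up, matrix$ref, matrix$down)
  agg_keys <- kmer_keyspace(3L)
  agg <- vapply(agg_keys, function(t) {
    r <- vals[trip == t]
    if (all(is.na(r))) NA_real_ else sum(r, na.rm = TRUE)
  }, numeric(1))
  flanks <- as.vector(t(outer(DNA_BASES, DNA_BASES,
                              function(u, d) paste0(u, "_", d))))
  grid <- matrix(NA_real_, 16L, 4L,
                 dimnames = list(flanks = sort(flanks), ref = DNA_BASES))
  for (t in agg_keys) {
    fl <- paste0(substr(t, 1, 1), "_", substr(t, 3, 3))
    grid[fl, substr(t, 2, 2)] <- agg[[t]]
  }
  grid
}

#' Render per-replichore context rate heatmaps
#'
#' One panel per region; missing rates are painted in a distinct
#' off-palette color.
#'
#' @param matrices Named list of `cdm_rates` (e.g. left/right
#'   replichore).
#' @param spec A [figure_spec()].
#' @return The list of value grids, invisibly; the image is written to
#'   `spec$path`.
#' @export
render_rate_heatmap <- function(matrices, spec) {
  grids <- lapply(matrices, build_rate_grid)
  if (all(vapply(grids, function(g) all(is.na(g)), logical(1))))
    stop("all rates missing; nothing to render", call. = FALSE)
  grDevices::png(spec$path, width = 6 * length(grids), height = 6,
                 units = "in", res = spec$dpi)
  op <- graphics::par(mfrow = c(1, length(grids)), mar = c(4, 6, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  zlim <- spec$zlim %||% range(unlist(grids), na.rm = TRUE)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  for (nm in names(grids)) {
    g <- grids[[nm]]
    graphics::image(x = seq_len(ncol(g)), y = seq_len(nrow(g)),
                    z = t(g), zlim = zlim, col = pal, axes = FALSE,
                    xlab = "reference base", ylab = "", main = nm,
                    useRaster = FALSE)
    na_cells <- which(is.na(g), arr.ind = TRUE)
    if (nrow(na_cells))
      graphics::points(na_cells[, 2], na_cells[, 1], pch = 4,
                       col = "grey60")
    graphics::axis(1, at = seq_len(ncol(g)), labels = colnames(g))
    graphics::axis(2, at = seq_len(nrow(g)), labels = rownames(g),
                   las = 2, cex.axis = 0.6)
  }
  invisible(grids)
}

#' Value grid for a correlation heatmap (rows/cols in GC order)
#' @param table An ordered `cdm_correlation`.
#' @return Numeric matrix `row_order x col_order`.
#' @export
build_correlation_grid <- function(table) correlation_matrix(table)

#' Render a cross-organism correlation heatmap
#' @param table An ordered `cdm_correlation`.
#' @param spec A [figure_spec()].
#' @return The value grid, invisibly.
#' @export
render_correlation_heatmap <- function(table, spec) {
  g <- build_correlation_grid(table)
  grDevices::png(spec$path, width = 6, height = 6, units = "in",
                 res = spec$dpi)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  zlim <- spec$zlim %||% range(g, na.rm = TRUE)
  if (!all(is.finite(zlim)) || zlim[1] == zlim[2])
    zlim <- c(min(zlim[1], 0, na.rm = TRUE) - 0.1, zlim[2] + 0.1)
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  # image() draws row 1 at the bottom; flip so row_order reads top-down
  graphics::image(x = seq_len(ncol(g)), y = seq_len(nrow(g)),
                  z = t(g[rev(seq_len(nrow(g))), , drop = FALSE]),
                  zlim = zlim, col = pal, axes = FALSE, xlab = "",
                  ylab = "", main = "Pearson r (GC-ordered)")
  graphics::axis(1, at = seq_len(ncol(g)), labels = colnames(g), las = 2)
  graphics::axis(2, at = seq_len(nrow(g)), labels = rev(rownames(g)),
                 las = 2)
  invisible(g)
}

#' Value grid for a stacked 64-triplet comparison
#'
#' @param runs Named list; each element a data.frame from
#'   [aggregate_to_triplets()] or [conditional_rates()] and, for
#'   `mode = "raw_counts"`, the `M_total` column.
#' @param mode `"rate"`, `"raw_counts"` or `"conditional"`.
#' @return Matrix `n_runs x 64`.
#' @export
build_triplet_stack_grid <- function(runs,
                                     mode = c("rate", "raw_counts",
                                              "conditional")) {
  mode <- match.arg(mode)
  keys <- kmer_keyspace(3L)
  col <- switch(mode, rate = "rate_total", raw_counts = "M_total",
                conditional = "conditional_rate")
  grid <- t(vapply(runs, function(df) {
    if (!all(keys %in% df$triplet))
      stop("run table does not cover the 64 triplets", call. = FALSE)
    v <- df[[col]]
    if (is.null(v)) stop("mode '", mode, "' column missing", call. = FALSE)
    stats::setNames(v, df$triplet)[keys]
  }, numeric(64L)))
  rownames(grid) <- names(runs)
  grid
}

#' Render a stacked per-triplet bar chart across runs
#' @param runs As in [build_triplet_stack_grid()].
#' @param spec A [figure_spec()].
#' @param mode Plotted quantity.
#' @return The value grid, invisibly.
#' @export
render_triplet_stack <- function(runs, spec,
                                 mode = c("rate", "raw_counts",
                                          "conditional")) {
  mode <- match.arg(mode)
  g <- build_triplet_stack_grid(runs, mode)
  grDevices::png(spec$path, width = 12, height = 5, units = "in",
                 res = spec$dpi)
  op <- graphics::par(mar = c(6, 5, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  gz <- g; gz[is.na(gz)] <- 0
  graphics::barplot(gz, beside = FALSE, las = 2, cex.names = 0.5,
                    col = grDevices::hcl.colors(max(nrow(g), 2),
                                                "Dark 3"),
                    ylab = mode, main = "64-triplet comparison",
                    legend.text = rownames(g))
  invisible(g)
}

#' Render a cumulative skew profile with ORI/TER marks
#' @param profile A `cdm_skew`.
#' @param frame Optional [replication_frame()] to mark.
#' @param spec A [figure_spec()].
#' @export
render_skew_profile <- function(profile, frame = NULL, spec) {
  grDevices::png(spec$path, width = 8, height = 4, units = "in",
                 res = spec$dpi)
  on.exit(grDevices::dev.off())
  graphics::plot(profile$positions, profile$cumulative, type = "l",
                 xlab = "position (bp)", ylab = "cumulative GC skew",
                 main = paste("cumulative skew,", profile$site_set))
  if (!is.null(frame)) {
    graphics::abline(v = frame$ori, col = "blue", lty = 2)
    graphics::abline(v = frame$ter, col = "red", lty = 2)
    graphics::legend("topleft", legend = c("ORI", "TER"),
                     col = c("blue", "red"), lty = 2, bty = "n")
  }
  invisible(NULL)
}

#' Render the binned mutation track
#' @param bins A `cdm_bins`.
#' @param spec A [figure_spec()].
#' @export
render_bin_track <- function(bins, spec) {
  grDevices::png(spec$path, width = 8, height = 4, units = "in",
                 res = spec$dpi)
  on.exit(grDevices::dev.off())
  graphics::barplot(bins$mutation_count, names.arg = bins$index,
                    xlab = "bin (1 = ORI)", ylab = "mutations",
                    main = sprintf("%d-bin mutation density",
                                   attr(bins, "n_bins")))
  invisible(NULL)
}
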