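## Figures: hyperbolic disc scatter, flag plot, S(k) curve, stacked degree
## histogram. Every plot function only writes a file (PNG or SVG, from the
## extension) plus a JSON sidecar with glyph counts so tests can assert on
## content without reading pixels.

default_palette <- function(labels) {
  cols <- grDevices::hcl.colors(max(length(labels), 3L), "Dark 3")
  stats::setNames(cols[seq_along(labels)], labels)
}

open_device <- function(path, width = 7, height = 7) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
}

#' Plot an embedding as a hyperbolic disc scatter
#'
#' Polar scatter with radius r and angle theta. Voxels carrying a highlighted
#' label (or listed in a highlight node set) are coloured; the rest are pale
#' grey. With \code{log_radial = TRUE} the radial axis is rendered as
#' log(1 + r).
#'
#' @param e a \code{hyper_embedding}.
#' @param path output image path (.png or .svg).
#' @param highlight character vector of labels (needs \code{labels}) or an
#'   integer vector of voxel ids.
#' @param labels optional \code{\link{label_map}} used to resolve label
#'   highlights.
#' @param palette named label -> colour vector; defaults to a builtin palette.
#' @param log_radial render radius on a log scale (default FALSE).
#' @return the image path, invisibly; a \code{<path>.json} sidecar records
#'   glyph counts.
#' @export
plot_disc <- function(e, path, highlight = NULL, labels = NULL, palette = NULL,
                      log_radial = FALSE) {
  r <- if (log_radial) log1p(e$r) else e$r
  x <- r * cos(e$theta); y <- r * sin(e$theta)
  col <- rep("grey80", e$n)
  n_high <- 0L
  if (!is.null(highlight)) {
    if (is.character(highlight)) {
      if (is.null(labels)) stop_hc("label highlight requires a label_map")
      unknown <- setdiff(highlight, labels$label_order)
      if (length(unknown)) stop_hc("unknown highlight labels: ",
                                   paste(unknown, collapse = ", "))
      palette <- palette %||% default_palette(highlight)
      for (lab in highlight) {
        hit <- vapply(e$voxel_id, function(v) lab %in% labels_of(labels, v),
                      logical(1))
        col[hit] <- palette[[lab]]
        n_high <- n_high + sum(hit)
      }
    } else {
      hit <- e$voxel_id %in% highlight
      col[hit] <- "firebrick"
      n_high <- sum(hit)
    }
  }
  open_device(path)
  on.exit(grDevices::dev.off())
  lim <- max(r) * 1.05
  graphics::plot(x, y, pch = 21, bg = col, col = "grey40", asp = 1,
                 xlim = c(-lim, lim), ylim = c(-lim, lim), xlab = "", ylab = "",
                 axes = FALSE, main = "Hyperbolic disc embedding")
  graphics::symbols(0, 0, circles = max(r), inches = FALSE, add = TRUE,
                    fg = "grey60")
  write_sidecar(path, list(kind = "disc", n_glyphs = e$n,
                           n_highlighted = n_high))
  invisible(path)
}

#' Flag plot of coreness by label
#'
#' One horizontal bar per (voxel, label) record, grouped by label and sorted
#' within label by descending coreness; bar length is the voxel's maximum
#' coreness.
#'
#' @param records a \code{\link{flag_data}} data frame.
#' @param path output image path.
#' @param palette named label -> colour vector.
#' @return the path, invisibly (sidecar: record and label counts).
#' @export
plot_flag <- function(records, path, palette = NULL) {
  if (!nrow(records)) stop_hc("no records")
  labs <- unique(records$label)
  palette <- palette %||% default_palette(labs)
  open_device(path, width = 6, height = 8)
  on.exit(grDevices::dev.off())
  graphics::barplot(rev(records$coreness), horiz = TRUE, border = NA,
                    col = rev(palette[records$label]), space = 0,
                    xlab = "coreness k", main = "k-core flag plot")
  write_sidecar(path, list(kind = "flag", n_records = nrow(records),
                           n_labels = length(labs)))
  invisible(path)
}

#' Plot the core-size curve S(k)
#'
#' Step plot of the k-core size against k with detected abrupt drops marked.
#'
#' @param S core-size series from \code{\link{core_size_curve}}.
#' @param path output image path.
#' @param drops k values to mark; defaults to
#'   \code{\link{detect_abrupt_drops}} of S.
#' @return the path, invisibly (sidecar: number of points and drops).
#' @export
plot_sk_curve <- function(S, path, drops = NULL) {
  drops <- drops %||% detect_abrupt_drops(S)
  ks <- as.integer(names(S))
  open_device(path)
  on.exit(grDevices::dev.off())
  graphics::plot(ks, S, type = "s", xlab = "k", ylab = "S(k)",
                 main = "k-core percolation")
  if (length(drops)) graphics::abline(v = drops, col = "firebrick", lty = 2)
  write_sidecar(path, list(kind = "sk_curve", n_points = length(S),
                           drops = as.list(drops)))
  invisible(path)
}

#' Stacked histogram of k_max-core voxel degrees by category
#'
#' @param records data frame from \code{\link{kmaxcore_degree_histogram}}.
#' @param path output image path.
#' @param n_bins number of degree bins (default 15).
#' @param palette named category -> colour vector.
#' @return the path, invisibly (sidecar: record, category and bin counts).
#' @export
plot_degree_histogram <- function(records, path, n_bins = 15, palette = NULL) {
  if (!nrow(records)) stop_hc("no records")
  cats <- unique(records$category)
  palette <- palette %||% default_palette(cats)
  br <- pretty(records$degree, n = n_bins)
  bin <- cut(records$degree, br, include.lowest = TRUE)
  tab <- table(factor(records$category, levels = cats), bin)
  open_device(path)
  on.exit(grDevices::dev.off())
  graphics::barplot(tab, col = palette[cats], border = NA, las = 2,
                    xlab = "degree in original graph", ylab = "voxels",
                    main = "k_max-core degree distribution",
                    legend.text = cats)
  write_sidecar(path, list(kind = "stacked_hist", n_records = nrow(records),
                           n_categories = length(cats),
                           n_bins = ncol(tab)))
  invisible(path)
}

## internal scatter used by plot.hyper_embedding (draws to current device)
disc_scatter <- function(e, highlight = NULL, labels = NULL, ...) {
  x <- e$r * cos(e$theta); y <- e$r * sin(e$theta)
  col <- rep("grey70", e$n)
  if (!is.null(highlight) && !is.character(highlight))
    col[e$voxel_id %in% highlight] <- "firebrick"
  graphics::plot(x, y, pch = 20, col = col, asp = 1, xlab = "", ylab = "",
                 axes = FALSE, ...)
  graphics::symbols(0, 0, circles = max(e$r), inches = FALSE, add = TRUE,
                    fg = "grey60")
}
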