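# Plot-data transformations and exports: heat-map transforms, de
# Finetti network plot data, landscape elevations.  Every display has a
# machine-readable TSV twin; image rendering (ggplot2) is optional.

#' Heat-map transforms of a probability matrix
#'
#' Elementwise `neglog`: `p -> -log_base(p)` mapping \[0,1\] to
#' \[0, Inf\]; or `logit`: `p -> log_base(p / (1 - p))` mapping \[0,1\]
#' to \[-Inf, Inf\].  Endpoint infinities are kept as `Inf` / `-Inf`
#' sentinels (exported, not dropped) so heat maps can render them in a
#' reserved color.
#'
#' @param m A `transition_matrix`, bare matrix or sparse `Matrix` with
#'   entries in \[0, 1\].
#' @param kind `"neglog"` or `"logit"`.
#' @param base Logarithm base (default 10).
#' @return Dense numeric matrix of transformed values.
#' @export
transform_matrix <- function(m, kind = c("neglog", "logit"), base = 10) {
  kind <- match.arg(kind)
  P <- as.matrix(tm_storage(m))
  if (min(P) < 0 || max(P) > 1)
    stop("entries must lie in [0, 1]")
  switch(kind,
         neglog = -log(P, base = base),
         logit = log(P / (1 - P), base = base))
}

inverse_transform <- function(x, kind = c("neglog", "logit"), base = 10) {
  kind <- match.arg(kind)
  switch(kind,
         neglog = base^(-x),
         logit = base^x / (1 + base^x))
}

#' Landscape elevations of the expected one-step dynamics
#'
#' For each state the distance `d` to its most probable neighbour is
#' measured in genotype-frequency space,
#' `d = sqrt(d_aa^2 + d_aA^2 + d_AA^2)`, and converted to an elevation
#' `h = d^2 * 0.05` (equating potential and kinetic energy over one
#' time step with gravitational acceleration approximated by 10).
#' Rolling "downhill" on the resulting surface over the de Finetti
#' triangle follows the expected dynamics of the chain; `h = 0` exactly
#' where a state is its own most probable successor.
#'
#' @param m A `transition_matrix` bound to a `state_space` (e.g. from
#'   [build_transition_matrix()]).
#' @param rescale Constant factor applied to `h` for display (default
#'   1).
#' @return Data frame: `state`, de Finetti `x`, `y`, neighbour index,
#'   `d`, `h`.
#' @export
landscape_heights <- function(m, rescale = 1) {
  space <- tm_space(m)
  if (is.null(space))
    stop("landscape_heights needs a matrix bound to a state_space")
  P <- tm_storage(m)
  n <- ncol(P)
  freqs <- space$states / space$N
  nb <- integer(n)
  for (j in seq_len(n)) {
    col <- as.numeric(P[, j])
    nb[j] <- which(col == max(col))[1]   # ties: smallest index
  }
  d <- sqrt(rowSums((freqs[nb, , drop = FALSE] - freqs)^2))
  xy <- definetti_coords(space)
  data.frame(state = seq_len(n), x = xy[, 1], y = xy[, 2],
             neighbor = nb, d = d, h = d^2 * 0.05 * rescale)
}

#' Export a de Finetti network plot (TSV twin plus optional figure)
#'
#' Nodes are placed at their de Finetti coordinates (the layout is data,
#' not force-directed), colored by a chosen per-state statistic; edges
#' come from a network-module selection (e.g.
#' [most_probable_neighbors()] or [filter_edges()]).  Always writes TSV
#' twins (`<out>_nodes.tsv`, `<out>_edges.tsv`); a PNG is drawn when
#' `png = TRUE` and ggplot2 is installed.
#'
#' @param m A `transition_matrix` bound to a `state_space`.
#' @param node_stat Name of the statistic to color nodes by (a column
#'   of [node_probability_summary()], or `"in_degree"`,
#'   `"betweenness"`, `"fis"`, `"first_passage"`).
#' @param edges Data frame `from`, `to`, `probability` (optional).
#' @param out Output path stem (without extension).
#' @param v Optional `limiting_distribution` (needed for `p_in_inf` /
#'   `p_inf`).
#' @param targets Target states for `"first_passage"`.
#' @param png Also render a PNG via ggplot2 if available.
#' @return Invisible list with the node and edge data frames and the
#'   files written.
#' @export
export_network_plot <- function(m, node_stat = "p_stay", edges = NULL,
                                out = "network", v = NULL, targets = NULL,
                                png = FALSE) {
  space <- tm_space(m)
  if (is.null(space))
    stop("export_network_plot needs a matrix bound to a state_space")
  xy <- definetti_coords(space)
  base_stats <- node_probability_summary(m, v = v)
  nodes <- data.frame(state = base_stats$state,
                      x = xy[, 1], y = xy[, 2], base_stats[-1])
  nodes$fis <- fis(space)
  available <- c(setdiff(names(nodes), c("state", "x", "y")),
                 "in_degree", "betweenness", "first_passage")
  if (!node_stat %in% available)
    stop("unknown statistic '", node_stat, "'; available: ",
         paste(available, collapse = ", "))
  if (node_stat == "in_degree")
    nodes$in_degree <- most_probable_neighbors(m)$in_degree
  if (node_stat == "betweenness")
    nodes$betweenness <- betweenness_paths(m)
  if (node_stat == "first_passage") {
    if (is.null(targets)) stop("first_passage requires targets")
    nodes$first_passage <- first_passage_times(m, targets)
  }
  nodes_file <- paste0(out, "_nodes.tsv")
  write.table(nodes, nodes_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- nodes_file
  if (!is.null(edges)) {
    edges_file <- paste0(out, "_edges.tsv")
    write.table(edges, edges_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, edges_file)
  }
  if (png && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
    if (!is.null(edges))
      gg <- gg + ggplot2::geom_segment(
        data = data.frame(x = xy[edges$from, 1], y = xy[edges$from, 2],
                          xend = xy[edges$to, 1], yend = xy[edges$to, 2]),
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        color = "grey60", linewidth = 0.2)
    gg <- gg +
      ggplot2::geom_point(ggplot2::aes(color = .data[[node_stat]]),
                          size = 2) +
      ggplot2::coord_equal() + ggplot2::theme_minimal() +
      ggplot2::labs(title = paste("de Finetti network:", node_stat))
    png_file <- paste0(out, ".png")
    ggplot2::ggsave(png_file, gg, width = 7, height = 6, dpi = 150)
    files <- c(files, png_file)
  }
  invisible(list(nodes = nodes, edges = edges, files = files))
}

#' Export a (transformed) heat map of the matrix as TSV
#'
#' Long-format TSV twin of a transition-matrix heat map: `from`, `to`,
#' `probability` and optionally the transformed value.  Infinities from
#' the transforms are written as `Inf`/`-Inf` sentinels.
#'
#' @inheritParams transform_matrix
#' @param out Output TSV path.
#' @param transform `"none"`, `"neglog"` or `"logit"`.
#' @return Invisible data frame written.
#' @export
export_heatmap <- function(m, out, transform = c("none", "neglog", "logit"),
                           base = 10) {
  transform <- match.arg(transform)
  P <- as.matrix(tm_storage(m))
  n <- nrow(P)
  df <- data.frame(from = rep(seq_len(n), each = n),
                   to = rep.int(seq_len(n), n),
                   probability = as.numeric(P))
  if (transform != "none")
    df$transformed <- as.numeric(transform_matrix(P, transform, base))
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
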