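#' @import ggplot2
NULL

save_plot <- function(p, out_path, width = 8, height = 5) {
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    grDevices::svg(out_path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  } else {
    ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  }
  invisible(out_path)
}

rescale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Render VIP heat plots
#'
#' Draws the position x allele importance grid for one or more alleles,
#' one panel per principal component, with cells above the relevance
#' threshold (VIP > 1 by convention) marked. Three coloring schemes are
#' supported: \code{global_uniform} colors every cell on one scale
#' spanning all alleles, positions and components;
#' \code{column_relative} normalizes colors within each binding-domain
#' position (per component) across alleles; \code{within_allele}
#' normalizes within each allele (per component) across positions. The
#' numeric VIP values are never modified by the coloring: they are
#' written unchanged to a sidecar TSV next to the image.
#'
#' @param vips a \code{vip_matrix} or list of them (same geometry).
#' @param out_path image path (.png, .pdf or .svg); the sidecar TSV gets
#'   the same name with extension .tsv.
#' @param scaling coloring scheme (see above).
#' @param component "all" (default) or one of "PC1", "PC2", "PC3".
#' @param threshold_marker cells above this VIP get a marker (default 1;
#'   NA disables).
#' @return invisibly, a list with the long-format plot data and the
#'   sidecar path.
#' @export
render_vip_heatmap <- function(vips, out_path,
                               scaling = c("global_uniform",
                                           "column_relative",
                                           "within_allele"),
                               component = "all", threshold_marker = 1) {
  scaling <- match.arg(scaling)
  if (inherits(vips, "vip_matrix")) vips <- list(vips)
  geom <- lapply(vips, function(v) dim(v$values))
  if (length(unique(vapply(geom, paste, character(1), collapse = "x"))) != 1L) {
    stop("all VIP matrices must share the same geometry")
  }
  pos_levels <- rownames(vips[[1]]$values)
  long <- do.call(rbind, lapply(vips, function(v) {
    g <- v$values
    data.frame(allele = v$allele,
               position = factor(rep(rownames(g), ncol(g)),
                                 levels = pos_levels),
               component = rep(colnames(g), each = nrow(g)),
               vip = as.vector(g), stringsAsFactors = FALSE)
  }))
  if (component != "all") {
    if (!component %in% long$component) stop("unknown component: ", component)
    long <- long[long$component == component, ]
  }
  long$fill <- switch(scaling,
    global_uniform = long$vip,
    column_relative = stats::ave(long$vip,
                                 long$component, long$position,
                                 FUN = rescale01),
    within_allele = stats::ave(long$vip,
                               long$component, long$allele,
                               FUN = rescale01))
  fill_name <- if (scaling == "global_uniform") "VIP" else "relative\nVIP"
  p <- ggplot(long, aes(x = .data$position, y = .data$allele,
                        fill = .data$fill)) +
    geom_tile(color = "grey40") +
    facet_wrap(~component, ncol = 1) +
    scale_fill_viridis_c(name = fill_name) +
    labs(x = "binding-domain position", y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  if (!is.na(threshold_marker)) {
    marked <- long[long$vip > threshold_marker, ]
    if (nrow(marked)) {
      p <- p + geom_point(data = marked, shape = 8, size = 1.5,
                          color = "white")
    }
  }
  save_plot(p, out_path, width = 8,
            height = 1.5 + 0.8 * length(vips) *
              length(unique(long$component)))
  sidecar <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  write_vip_table(vips, sidecar)
  invisible(list(data = long, sidecar = sidecar))
}

#' Histogram of ln(ic50) with normal overlay and spike detection
#'
#' Mirrors the diagnostic view of benchmark affinity data: a histogram of
#' ln(ic50) with a normal density fitted from the sample mean and SD, and
#' bins holding more than \code{spike_threshold} of all observations
#' highlighted — such spikes indicate repeated identical measurements at
#' assay limits.
#'
#' @param ds a \code{\link{binding_dataset}} (>= 10 records).
#' @param bins number of histogram bins (default 30).
#' @param out_path image path.
#' @param spike_threshold fraction of all observations above which a bin
#'   is highlighted (default 0.2).
#' @return invisibly, a data frame of bins (mid, count, spike flag).
#' @export
render_affinity_histogram <- function(ds, bins = 30, out_path,
                                      spike_threshold = 0.2) {
  x <- ds$ln_ic50
  n <- length(x)
  if (n < 10) stop("need at least 10 records, got ", n)
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  bw <- diff(h$breaks)[1]
  bdf <- data.frame(mid = h$mids, count = h$counts,
                    spike = h$counts > spike_threshold * n)
  curve_df <- data.frame(x = seq(min(x), max(x), length.out = 200))
  curve_df$y <- stats::dnorm(curve_df$x, mean(x), sd(x)) * n * bw
  p <- ggplot(bdf, aes(x = .data$mid, y = .data$count,
                       fill = .data$spike)) +
    geom_col(width = bw, color = "grey30", show.legend = FALSE) +
    scale_fill_manual(values = c(`FALSE` = "grey80", `TRUE` = "grey20")) +
    geom_line(data = curve_df, aes(x = .data$x, y = .data$y),
              inherit.aes = FALSE, color = "steelblue", linewidth = 0.8) +
    labs(x = "ln(ic50)", y = "count") +
    theme_minimal()
  save_plot(p, out_path, width = 6, height = 4)
  invisible(bdf)
}

#' Two-descriptor response surface of a fitted model
#'
#' Predicted ln(ic50) over a grid spanning the observed training range of
#' two chosen (position, component) descriptors, all other descriptors
#' held at their training means. For a linear PLS model the surface is a
#' plane; for perceptron models it shows the fitted nonlinearity. The
#' numeric grid is exported as a TSV (rows = axis a, columns = axis b)
#' alongside a filled-contour rendering.
#'
#' @param model a \code{pls_model} or \code{perceptron_model} (must carry
#'   \code{position_labels} / geometry and \code{x_range}).
#' @param position_a,position_b groove position labels (e.g. "P9",
#'   "C+1"); must differ from each other as (position, component) pairs.
#' @param component_a,component_b principal component, 1-3 (or "PC1"...).
#' @param grid grid resolution per axis (default 25).
#' @param out_path image path; the TSV sidecar gets extension .tsv.
#' @return invisibly, the numeric grid matrix with axis values as
#'   dimnames.
#' @export
render_response_surface <- function(model, position_a, component_a,
                                    position_b, component_b,
                                    grid = 25, out_path) {
  pos_labels <- if (inherits(model, "pls_model")) model$position_labels
                else attr(model, "position_labels")
  if (is.null(pos_labels)) {
    K <- if (inherits(model, "pls_model")) length(model$coefficients)
         else model$n_inputs
    L <- K %/% 3L
    pos_labels <- if (L == 9L) position_labels(9L, "I")
                  else if (L == 15L) position_labels(15L, "II")
                  else paste0("pos", seq_len(L))
  }
  comp_idx <- function(comp) {
    if (is.character(comp)) comp <- as.integer(sub("^PC", "", comp))
    stopifnot(comp %in% 1:3)
    comp
  }
  slot <- function(pos, comp) {
    i <- match(pos, pos_labels)
    if (is.na(i)) stop("unknown position label: ", pos)
    3L * (i - 1L) + comp_idx(comp)
  }
  ia <- slot(position_a, component_a)
  ib <- slot(position_b, component_b)
  if (ia == ib) stop("the two axes must be distinct descriptors")
  xr <- model$x_range
  va <- seq(xr[1, ia], xr[2, ia], length.out = grid)
  vb <- seq(xr[1, ib], xr[2, ib], length.out = grid)
  X <- matrix(rep(model$x_center, each = grid * grid),
              nrow = grid * grid)
  gg <- expand.grid(a = va, b = vb)
  X[, ia] <- gg$a
  X[, ib] <- gg$b
  z <- predict(model, X)
  zmat <- matrix(z, nrow = grid, ncol = grid,
                 dimnames = list(signif(va, 6), signif(vb, 6)))
  df <- data.frame(a = gg$a, b = gg$b, z = z)
  lab_a <- sprintf("%s PC%d", position_a, comp_idx(component_a))
  lab_b <- sprintf("%s PC%d", position_b, comp_idx(component_b))
  p <- ggplot(df, aes(x = .data$a, y = .data$b, z = .data$z)) +
    geom_contour_filled() +
    labs(x = lab_a, y = lab_b, fill = "predicted\nln(ic50)") +
    theme_minimal()
  save_plot(p, out_path, width = 6.5, height = 5)
  sidecar <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  write.table(data.frame(a_value = rownames(zmat), zmat,
                         check.names = FALSE),
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(zmat)
}
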