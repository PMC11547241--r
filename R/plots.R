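#' 2D droplet dot plot
#'
#' The standard two-channel dot plot used for manual gating, optionally
#' overlaying the polygon gates defined on that plane. Requires ggplot2.
#'
#' @param ds A `droplet_set`.
#' @param gates Optional `gate_set`; gates on the requested plane are
#'   drawn.
#' @param plane Character vector of two channel names.
#' @return A ggplot object.
#' @export
plot_droplets <- function(ds, gates = NULL, plane = c("FAM", "Cy5")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .stopf("plot_droplets requires the ggplot2 package")
  }
  stopifnot(inherits(ds, "droplet_set"), length(plane) == 2L)
  df <- data.frame(x = ds[[plane[1]]], y = ds[[plane[2]]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = paste(plane[1], "intensity (a.u.)"),
                  y = paste(plane[2], "intensity (a.u.)")) +
    ggplot2::theme_minimal()
  if (!is.null(gates)) {
    polys <- list()
    for (g in gates$gates) {
      if (!identical(sort(g$plane), sort(plane))) next
      xy <- g$polygon[, plane, drop = FALSE]
      polys[[g$name]] <- data.frame(gate = g$name, x = xy[, 1], y = xy[, 2])
    }
    if (length(polys)) {
      pd <- do.call(rbind, polys)
      p <- p + ggplot2::geom_polygon(
        data = pd,
        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$gate),
        fill = NA, linewidth = 0.4)
    }
  }
  p
}
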