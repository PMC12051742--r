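# ggplot2 visualisations for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

ternary_xy <- function(w1, w2, w3) {
  list(x = w2 + w3 / 2, y = sqrt(3) / 2 * w3)
}

#' @describeIn ternary_bin Ternary heat map of a binned weight grid.
#' @param object A `ternary_grid`.
#' @param ... Unused.
#' @export
autoplot.ternary_grid <- function(object, ...) {
  k <- attr(object, "k")
  polys <- lapply(seq_len(nrow(object)), function(i) {
    a <- object$a[i]; b <- object$b[i]
    if (object$orient[i] == "up") {
      cc <- k - 1 - a - b
      v <- rbind(c(a + 1, b, cc), c(a, b + 1, cc), c(a, b, cc + 1))
    } else {
      cc <- k - 2 - a - b
      v <- rbind(c(a + 1, b + 1, cc), c(a + 1, b, cc + 1),
                 c(a, b + 1, cc + 1))
    }
    xy <- ternary_xy(v[, 1] / k, v[, 2] / k, v[, 3] / k)
    tibble::tibble(cell = object$cell[i], x = xy$x, y = xy$y,
                   count = object$count[i])
  })
  df <- dplyr::bind_rows(polys)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                   fill = .data$count)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_viridis_c(trans = "log1p") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "blocks")
}

#' @describeIn profile_likelihood Profile-likelihood curve with maximiser.
#' @param object A `profile_lik` tibble.
#' @param ... Unused.
#' @export
autoplot.profile_lik <- function(object, ...) {
  ggplot2::ggplot(object[is.finite(object$log10_lik), ],
                  ggplot2::aes(.data$value, .data$log10_lik)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "maximiser"),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = attr(object, "free"),
                  y = "log10 composite likelihood")
}

#' @describeIn folded_jsfs Heat map of a folded joint SFS.
#' @export
autoplot.jsfs <- function(object, ...) {
  df <- tidy.jsfs(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$iA, .data$iB,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(object$pops[1], " minor count"),
                  y = paste0(object$pops[2], " minor count"),
                  fill = "log10(1+n)")
}

#' Facetted plot of windowed statistics
#'
#' @param ws Long tibble from [window_stats()].
#' @param stats Which statistics to show.
#' @return A ggplot.
#' @export
plot_window_stats <- function(ws, stats = c("pi", "dxy", "fst", "da")) {
  df <- ws[ws$stat %in% stats, , drop = FALSE]
  df$panel <- ifelse(is.na(df$pop_b), paste0(df$stat, " ", df$pop_a),
                     paste0(df$stat, " ", df$pop_a, "-", df$pop_b))
  ggplot2::ggplot(df, ggplot2::aes(.data$start / 1e6, .data$value,
                                   colour = .data$contig)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_grid(panel ~ contig, scales = "free",
                        switch = "y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
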