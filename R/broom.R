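#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classification result
#'
#' @param x A [classify()] result.
#' @param ... Unused.
#' @return A plain tibble with one row per segment.
#' @method tidy tube_classification
#' @export
tidy.tube_classification <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tube_classification")
  out
}

#' One-row summary of a classification result
#'
#' @param x A [classify()] result.
#' @param ... Unused.
#' @return A one-row tibble: segment and reference counts, score and
#'   margin summaries, and the modal wrapping with its fraction.
#' @method glance tube_classification
#' @export
glance.tube_classification <- function(x, ...) {
  top <- summarize_assignments(x)$lattice[1, ]
  tibble(
    n_segments = nrow(x),
    n_references = length(attr(x, "bank_keys")),
    mean_score = mean(x$score),
    mean_margin = mean(x$margin),
    top_n1 = top$n1, top_n2 = top$n2, top_fraction = top$fraction
  )
}

#' Plot classification summaries
#'
#' `type = "lattice"` maps the assignment fractions onto the 2D lattice
#' (one tile per wrapping index); `type = "flattening"` draws per-wrapping
#' histograms of the assigned flattening scale.
#'
#' @param object A [summarize_assignments()] result (or a [classify()]
#'   result, which is summarized first).
#' @param type `"lattice"` or `"flattening"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tube_class_summary
#' @export
autoplot.tube_class_summary <- function(object, type = c("lattice", "flattening"),
                                        ...) {
  type <- match.arg(type)
  if (type == "lattice") {
    ggplot2::ggplot(object$lattice,
                    ggplot2::aes(x = .data$n1, y = .data$n2,
                                 fill = .data$fraction)) +
      ggplot2::geom_tile(color = "grey30") +
      ggplot2::scale_fill_viridis_c(option = "inferno") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "n1", y = "n2", fill = "fraction",
                    title = "Polymorph distribution on the 2D lattice")
  } else {
    df <- object$flattening |>
      dplyr::mutate(wrapping = sprintf("(%d,%d)", .data$n1, .data$n2),
                    percent_flat = round(100 * (.data$scale - 1)))
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$percent_flat),
                                     y = .data$fraction)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~wrapping) +
      ggplot2::labs(x = "flattening (%)", y = "fraction of segments",
                    title = "Tube flattening by polymorph")
  }
}

#' @rdname autoplot.tube_class_summary
#' @method autoplot tube_classification
#' @export
autoplot.tube_classification <- function(object,
                                         type = c("lattice", "flattening"),
                                         ...) {
  autoplot(summarize_assignments(object), type = match.arg(type), ...)
}

#' Plot an image or power spectrum as a raster
#'
#' @param object A [tw_image()].
#' @param trans Value transform, e.g. `"sqrt"` or `"log1p"`, applied for
#'   display only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tw_image
#' @export
autoplot.tw_image <- function(object, trans = "identity", ...) {
  m <- object$data
  f <- switch(trans, identity = identity, sqrt = function(v) sqrt(pmax(v, 0)),
              log1p = function(v) log1p(pmax(v, 0)),
              abort("unknown `trans`."))
  df <- tidyr::expand_grid(j = seq_len(ncol(m)), i = seq_len(nrow(m)))
  df$value <- f(as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
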