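# ggplot2 quick-look helpers.  These are convenience surfaces for inspecting
# geometries and solutions; figure aesthetics are not a package contract.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

boundary_tbl <- function(domain, n = 200) {
  z <- c(domain$dense_polygon, domain$dense_polygon[1])
  tibble::tibble(X = Re(z), Y = Im(z))
}

#' Plot a bifurcation domain
#'
#' Boundary walls, openings, corners and (optionally) the particle circle.
#'
#' @param object A `bif_domain`.
#' @param poles Optional complex vector of pole locations to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bif_domain
#' @export
autoplot.bif_domain <- function(object, poles = NULL, ...) {
  bt <- boundary_tbl(object)
  p <- ggplot2::ggplot(bt, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "X", y = "Y")
  if (!is.null(object$particle)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble::tibble(
      X = Re(object$particle$centre) + object$particle$R * cos(th),
      Y = Im(object$particle$centre) + object$particle$R * sin(th))
    p <- p + ggplot2::geom_path(data = circ, linetype = "dashed")
  }
  if (!is.null(poles)) {
    pt <- tibble::tibble(X = Re(poles), Y = Im(poles))
    p <- p + ggplot2::geom_point(data = pt, colour = "red", size = 0.3)
  }
  p
}

#' Velocity-magnitude map of a solved flow
#'
#' Evaluates the fields on a regular grid clipped to the domain and draws the
#' speed as a filled raster with the boundary overlaid.
#'
#' @param solution A [solve_stokes()] solution.
#' @param nx,ny Grid resolution.
#' @return A ggplot object.
#' @export
plot_speed <- function(solution, nx = 120, ny = 120) {
  dom <- solution$system$domain
  bb <- dom$dense_polygon
  pts <- expand.grid(X = seq(min(Re(bb)), max(Re(bb)), length.out = nx),
                     Y = seq(min(Im(bb)), max(Im(bb)), length.out = ny))
  f <- evaluate_fields(solution, pts)
  f$speed <- sqrt(f$U^2 + f$V^2)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed)) +
    ggplot2::geom_path(data = boundary_tbl(dom), linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "|u|")
}

#' Plot a streamline
#'
#' @param object A [trace_streamline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot streamline
#' @export
autoplot.streamline <- function(object, ...) {
  ggplot2::ggplot(tidy.streamline(object),
                  ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_path(colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Predicted-versus-simulated plot for a surrogate
#'
#' @param object A [train_surrogate()] model.
#' @param dataset The dataset used for training/validation.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surrogate_model
#' @export
autoplot.surrogate_model <- function(object, dataset, ...) {
  d <- tibble::tibble(simulated = dataset[[object$target]],
                      predicted = predict_conductance(object, dataset),
                      split = dataset$split)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$simulated, y = .data$predicted,
                                  colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = paste("simulated", object$target),
                  y = paste("predicted", object$target))
}
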