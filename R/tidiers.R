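# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conductance set
#'
#' @param x A [conductance_tensor()] result.
#' @param reference Optional reference (from [poiseuille_reference()] or
#'   [area_preserved_reference()]); adds `G_ref` and `rel_pct` columns.
#' @param ... Unused.
#' @return A tibble with one row per channel.
#' @method tidy conductance_set
#' @export
tidy.conductance_set <- function(x, reference = NULL, ...) {
  out <- tibble::tibble(channel = c("parent", "child1", "child2"),
                        G = unname(x$triple))
  if (!is.null(reference)) {
    rd <- relative_differences(x, reference)
    out$G_ref <- rd$G_ref
    out$rel_pct <- rd$rel_pct
  }
  out
}

#' One-row summary of a conductance set
#'
#' @param x A [conductance_tensor()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance conductance_set
#' @export
glance.conductance_set <- function(x, ...) {
  tibble::tibble(G0 = x$triple[["G0"]], G1 = x$triple[["G1"]],
                 G2 = x$triple[["G2"]],
                 G12 = x$tensor[1, 2], G21 = x$tensor[2, 1],
                 reconstruction_error = x$reconstruction_error,
                 max_residual = max(x$residuals))
}

#' Per-vertex tidy form of a streamline
#'
#' @param x A [trace_streamline()] result.
#' @param ... Unused.
#' @return A tibble with `X`, `Y`, `psi_level`, `terminus`.
#' @method tidy streamline
#' @export
tidy.streamline <- function(x, ...) {
  tibble::tibble(X = Re(x$vertices), Y = Im(x$vertices),
                 psi_level = x$psi_level, terminus = x$terminus)
}

#' One-row summary of a trained surrogate
#'
#' @param x A [train_surrogate()] model.
#' @param ... Unused.
#' @return A one-row tibble with training and validation MSE (conductance
#'   scale), sample counts and optimiser iterations.
#' @method glance surrogate_model
#' @export
glance.surrogate_model <- function(x, ...) {
  tibble::tibble(target = x$target, space = x$space %||% NA_character_,
                 mse_train = x$report$mse_train,
                 mse_validation = x$report$mse_validation,
                 n_train = x$report$n_train,
                 n_validation = x$report$n_validation,
                 iterations = x$report$iterations)
}
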