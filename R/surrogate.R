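# Neural-network surrogates of the conductance components: datasets of solved
# random geometries, and small rectified-linear feedforward regressors
# trained by full-batch quasi-Newton optimisation.

#' Options used for bulk conductance sweeps
#'
#' A reduced-resolution [solver_options()] preset used when many geometries
#' are solved in sequence (parameter sweeps, surrogate training data).  At
#' this resolution conductances are converged to well below 1e-4 relative,
#' ample for regression targets, at a few tenths of a second per geometry.
#'
#' @param ... Overrides passed to [solver_options()].
#' @return A [solver_options()] object.
#' @export
sweep_options <- function(...) {
  defaults <- list(poly_degree = 16, poles_per_corner = 24,
                   opening_corner_poles = 8, n_uniform_wall = 10,
                   opening_points = 36, residual_warn = 1e-4,
                   residual_check = "solve_grid")
  args <- utils::modifyList(defaults, list(...))
  do.call(solver_options, args)
}

# feature columns per sampling space
space_features <- function(space) {
  switch(space,
         straight = c("D1", "D2", "alpha", "beta"),
         bezier = c("D1", "D2", "alpha", "beta"),
         particle = c("X0", "Y0", "R"),
         stop("unknown space: ", space))
}

#' Generate a surrogate training set
#'
#' Rejection-samples uniform geometry parameters from the requested space,
#' discarding invalid geometries, solves the Stokes problem for each
#' accepted row and records the conductance triple.  Spaces: `"straight"`
#' (`D1, D2 ~ U[0.5, 1]`, `alpha, beta ~ U[0, pi/2]`, straight walls),
#' `"bezier"` (same parameters, Bezier walls), `"particle"` (symmetric
#' bifurcation `D1 = D2 = 1`, `alpha = beta = pi/4` with a particle at
#' `X0, Y0 ~ U[-1, 1]`, `R ~ U(0, 0.3]`).  Rows are split 80/20 into
#' training and validation sets.
#'
#' @param space `"straight"`, `"bezier"` or `"particle"`.
#' @param n Number of valid rows to generate (>= 10).
#' @param seed Integer seed controlling both sampling and split.
#' @param options Solver options (default [sweep_options()]).
#' @param L Channel length.
#' @return A tibble with the parameter columns, `G0`, `G1`, `G2`, `residual`,
#'   `flagged` and `split`; attributes `space`, `seed` and `features`.
#' @export
generate_dataset <- function(space = c("straight", "bezier", "particle"),
                             n, seed = 1, options = NULL, L = 2) {
  space <- match.arg(space)
  if (is.null(options))
    options <- if (space == "particle")
      sweep_options(poly_degree = 48, poles_per_corner = 24,
                    laurent_degree = 16) else sweep_options()
  stopifnot(n >= 10)
  set.seed(seed)
  feats <- space_features(space)
  rows <- vector("list", n)
  accepted <- 0L; attempts <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > 100 && accepted < attempts / 100)
      stop("acceptance rate below 1%: sampling space misconfigured")
    if (space %in% c("straight", "bezier")) {
      par <- list(D1 = stats::runif(1, 0.5, 1), D2 = stats::runif(1, 0.5, 1),
                  alpha = stats::runif(1, 0, pi / 2),
                  beta = stats::runif(1, 0, pi / 2))
      spec <- bif_spec(par$D1, par$D2, par$alpha, par$beta, L,
                       wall_kind = if (space == "bezier") "bezier" else "straight")
    } else {
      par <- list(X0 = stats::runif(1, -1, 1), Y0 = stats::runif(1, -1, 1),
                  R = stats::runif(1, 1e-6, 0.3))
      spec <- bif_spec(1, 1, pi / 4, pi / 4, L,
                       particle = list(X0 = par$X0, Y0 = par$Y0, R = par$R))
    }
    if (!validate_spec(spec)$ok) next
    accepted <- accepted + 1L
    rows[[accepted]] <- par
  }
  par_tbl <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))

  solve_row <- function(spec, opts) {
    cs <- conductance_tensor(build_bifurcation(spec), opts)
    c(cs$triple, residual = max(cs$residuals))
  }
  res <- purrr::pmap(par_tbl, function(...) {
    par <- list(...)
    spec <- if (space %in% c("straight", "bezier"))
      bif_spec(par$D1, par$D2, par$alpha, par$beta, L,
               wall_kind = if (space == "bezier") "bezier" else "straight")
    else
      bif_spec(1, 1, pi / 4, pi / 4, L,
               particle = list(X0 = par$X0, Y0 = par$Y0, R = par$R))
    v <- tryCatch(solve_row(spec, options), error = function(e) NULL)
    if (is.null(v)) {
      o2 <- options; o2$refine <- 2
      v <- solve_row(spec, o2)   # errors here abort generation
    }
    flagged <- FALSE
    if (v[["residual"]] > options$residual_warn) {
      o2 <- options; o2$refine <- 2
      v2 <- tryCatch(solve_row(spec, o2), error = function(e) NULL)
      if (!is.null(v2) && v2[["residual"]] < v[["residual"]]) v <- v2
      flagged <- v[["residual"]] > options$residual_warn
    }
    tibble::tibble(G0 = v[["G0"]], G1 = v[["G1"]], G2 = v[["G2"]],
                   residual = v[["residual"]], flagged = flagged)
  })
  out <- dplyr::bind_cols(par_tbl, dplyr::bind_rows(res))
  n_val <- max(1L, round(0.2 * n))
  val_idx <- sample.int(n, n_val)
  out$split <- ifelse(seq_len(n) %in% val_idx, "validation", "train")
  attr(out, "space") <- space
  attr(out, "seed") <- seed
  attr(out, "features") <- feats
  out
}

## ---- multilayer perceptron internals --------------------------------------

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1)) {
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                  sd = sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1])
    b[[i]] <- rep(0, sizes[i + 1])
  }
  list(W = W, b = b)
}

mlp_pack <- function(wb) unlist(c(lapply(wb$W, as.numeric), wb$b))

mlp_unpack <- function(theta, sizes) {
  W <- list(); b <- list(); pos <- 0L
  for (i in seq_len(length(sizes) - 1)) {
    k <- sizes[i] * sizes[i + 1]
    W[[i]] <- matrix(theta[pos + seq_len(k)], sizes[i], sizes[i + 1])
    pos <- pos + k
  }
  for (i in seq_len(length(sizes) - 1)) {
    k <- sizes[i + 1]
    b[[i]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  list(W = W, b = b)
}

mlp_forward <- function(wb, X, keep = FALSE) {
  L <- length(wb$W)
  A <- X
  acts <- if (keep) list(A) else NULL
  for (i in seq_len(L)) {
    Z <- sweep(A %*% wb$W[[i]], 2, wb$b[[i]], "+")
    A <- if (i < L) pmax(Z, 0) else Z
    if (keep) acts[[i + 1]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# loss 0.5*mean((yhat-y)^2) and gradient via backprop
mlp_loss_grad <- function(theta, sizes, X, y) {
  wb <- mlp_unpack(theta, sizes)
  L <- length(wb$W)
  fw <- mlp_forward(wb, X, keep = TRUE)
  n <- nrow(X)
  r <- fw$out - y
  loss <- 0.5 * mean(r^2)
  delta <- r / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(fw$acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) delta <- (delta %*% t(wb$W[[i]])) * (fw$acts[[i]] > 0)
  }
  list(loss = loss, grad = unlist(c(lapply(gW, as.numeric), gb)))
}

#' Train a conductance surrogate
#'
#' Fits a fixed `[n_features, 20, 20, 20, 1]` rectified-linear feedforward
#' regressor to one conductance component by full-batch limited-memory
#' quasi-Newton minimisation of the mean squared error, with z-scored inputs
#' (and an internally unit-variance-scaled target for optimiser
#' conditioning; reported errors are on the raw conductance scale).
#'
#' @param dataset A [generate_dataset()] tibble (must contain a `split`
#'   column).
#' @param target `"G0"`, `"G1"` or `"G2"`.
#' @param seed Training seed (weight initialisation).
#' @param hidden Hidden layer sizes.
#' @param maxit Maximum optimiser iterations.
#' @return An object of class `surrogate_model` with the weights,
#'   standardisation parameters and a `report` (mse_train, mse_validation on
#'   the conductance scale, counts, iterations).
#' @export
train_surrogate <- function(dataset, target = "G1", seed = 1,
                            hidden = c(20, 20, 20), maxit = 5000) {
  feats <- attr(dataset, "features") %||%
    intersect(c("D1", "D2", "alpha", "beta", "X0", "Y0", "R"), names(dataset))
  stopifnot(target %in% names(dataset), "split" %in% names(dataset))
  tr <- dataset[dataset$split == "train", , drop = FALSE]
  va <- dataset[dataset$split == "validation", , drop = FALSE]
  Xtr <- as.matrix(tr[feats]); ytr <- tr[[target]]
  ctr <- colMeans(Xtr); str_ <- apply(Xtr, 2, stats::sd)
  str_[str_ < 1e-12] <- 1
  ysc <- stats::sd(ytr); if (!is.finite(ysc) || ysc < 1e-300) ysc <- 1
  ymu <- mean(ytr)
  Xs <- sweep(sweep(Xtr, 2, ctr), 2, str_, "/")
  ys <- (ytr - ymu) / ysc

  sizes <- c(length(feats), hidden, 1L)
  if (stats::sd(ytr) < 1e-14 * (abs(ymu) + 1)) {
    # degenerate constant target: the least-squares optimum is the constant
    wb0 <- mlp_unpack(numeric(length(mlp_pack(mlp_init(sizes, seed)))), sizes)
    model <- structure(list(weights = wb0, sizes = sizes, features = feats,
                            x_center = ctr, x_scale = str_,
                            y_center = ymu, y_scale = 1,
                            target = target, seed = seed,
                            space = attr(dataset, "space"),
                            ranges = apply(as.matrix(dataset[feats]), 2, range)),
                       class = "surrogate_model")
    model$report <- list(mse_train = 0,
                         mse_validation = mean((va[[target]] - ymu)^2),
                         n_train = nrow(tr), n_validation = nrow(va),
                         iterations = 0L, convergence = 0L)
    return(model)
  }
  theta0 <- mlp_pack(mlp_init(sizes, seed))
  fit <- stats::optim(theta0,
                      fn = function(th) mlp_loss_grad(th, sizes, Xs, ys)$loss,
                      gr = function(th) mlp_loss_grad(th, sizes, Xs, ys)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10, pgtol = 1e-12))
  if (!is.finite(fit$value)) stop("non-finite training loss")
  wb <- mlp_unpack(fit$par, sizes)

  model <- structure(list(weights = wb, sizes = sizes, features = feats,
                          x_center = ctr, x_scale = str_,
                          y_center = ymu, y_scale = ysc,
                          target = target, seed = seed,
                          space = attr(dataset, "space"),
                          ranges = apply(as.matrix(dataset[feats]), 2, range)),
                     class = "surrogate_model")
  pr_tr <- predict_conductance(model, tr)
  pr_va <- predict_conductance(model, va)
  model$report <- list(
    mse_train = mean((pr_tr - tr[[target]])^2),
    mse_validation = mean((pr_va - va[[target]])^2),
    n_train = nrow(tr), n_validation = nrow(va),
    iterations = fit$counts[["function"]], convergence = fit$convergence)
  model
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> %s ~ mlp(%s) on [%s]; val MSE %.3g (n=%d)\n",
              x$target, paste(x$sizes, collapse = ","),
              paste(x$features, collapse = ", "),
              x$report$mse_validation, x$report$n_validation))
  invisible(x)
}

#' Predict a conductance component from geometry parameters
#'
#' Deterministic forward pass of a trained surrogate, vectorised over rows.
#' Parameters outside the training hypercube trigger an extrapolation
#' warning.
#'
#' @param model A [train_surrogate()] model.
#' @param newdata Data frame (or named numeric vector) with the model's
#'   feature columns.
#' @return Numeric vector of predictions on the conductance scale.
#' @export
predict_conductance <- function(model, newdata) {
  if (is.numeric(newdata) && !is.matrix(newdata))
    newdata <- tibble::as_tibble(as.list(newdata))
  missing <- setdiff(model$features, names(newdata))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[model$features])
  lo <- model$ranges[1, ]; hi <- model$ranges[2, ]
  slack <- 1e-10 * (abs(hi - lo) + 1)   # tolerate serialisation round-off
  outside <- sweep(X, 2, lo - slack, "<") | sweep(X, 2, hi + slack, ">")
  if (any(outside))
    warning(sprintf("%d row(s) outside the training hypercube: extrapolating",
                    sum(rowSums(outside) > 0)))
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  drop(mlp_forward(model$weights, Xs)) * model$y_scale + model$y_center
}

#' Serialise a surrogate model to JSON
#'
#' @param model A [train_surrogate()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  obj <- list(sizes = model$sizes, features = model$features,
              target = model$target, seed = model$seed,
              space = model$space,
              x_center = as.list(model$x_center),
              x_scale = as.list(model$x_scale),
              y_center = model$y_center, y_scale = model$y_scale,
              ranges = model$ranges,
              W = lapply(model$weights$W, identity),
              b = model$weights$b,
              report = model$report)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a surrogate model from JSON
#'
#' @param path File written by [write_surrogate()].
#' @return A `surrogate_model`.
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = list(W = lapply(obj$W, function(m) matrix(unlist(m), nrow = nrow(m))),
                                b = lapply(obj$b, as.numeric)),
                 sizes = as.integer(obj$sizes),
                 features = obj$features,
                 x_center = stats::setNames(unlist(obj$x_center), obj$features),
                 x_scale = stats::setNames(unlist(obj$x_scale), obj$features),
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 target = obj$target, seed = obj$seed, space = obj$space,
                 ranges = obj$ranges, report = obj$report),
            class = "surrogate_model")
}
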