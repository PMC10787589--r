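# Coordinate-based MLP with sinusoidal activations representing the
# displacement field u(x) over the normalized fixed-image cube, so that
# Phi(x) = x + u(x) maps fixed coordinates to moving coordinates. Forward
# pass, exact spatial Jacobians (forward-mode chain rule through every
# layer) and reverse-mode weight gradients -- including the second-order
# path through the Jacobian needed by the determinant regularizer -- are
# implemented directly with dense matrix algebra; correctness is pinned to
# finite-difference oracles in the test suite.

#' Architecture of the displacement network
#'
#' @param n_hidden_layers number of hidden (sine) layers.
#' @param units_per_layer units in each hidden layer.
#' @param omega angular frequency of the sinusoidal activations,
#'   `sin(omega * (W x + b))`, applied in every sine layer including the
#'   first.
#' @param seed integer seed for weight initialization; `NULL` draws from
#'   the current RNG stream (used inside [register()] so one global seed
#'   governs initialization and sampling).
#' @param final_init_scale half-width of the uniform initialization of the
#'   final linear layer; small so optimization starts near the identity
#'   transform.
#' @return a `network_arch` list.
#' @export
network_arch <- function(n_hidden_layers = 6L, units_per_layer = 300L,
                         omega = 30, seed = 1L, final_init_scale = 1e-4) {
  n_hidden_layers <- as.integer(n_hidden_layers)
  units_per_layer <- as.integer(units_per_layer)
  if (n_hidden_layers < 1L || units_per_layer < 1L) {
    stop("need at least one hidden layer and one unit", call. = FALSE)
  }
  if (!is.numeric(omega) || omega <= 0) stop("`omega` must be > 0",
                                             call. = FALSE)
  structure(list(n_hidden_layers = n_hidden_layers,
                 units_per_layer = units_per_layer, omega = omega,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 final_init_scale = final_init_scale),
            class = "network_arch")
}

#' Initialize a displacement network
#'
#' Sine layers use the standard sinusoidal-network initialization: first
#' layer uniform in `+-1/fan_in`, deeper sine layers uniform in
#' `+-sqrt(6/fan_in)/omega`; biases uniform in `+-1/sqrt(fan_in)`. The
#' final linear layer is drawn uniform in `+-final_init_scale` with zero
#' bias, so the initial displacement is near zero and the initial
#' transformation is close to the identity.
#'
#' @param arch a [network_arch].
#' @return an object of class `displacement_model`.
#' @export
init_network <- function(arch = network_arch()) {
  stopifnot(inherits(arch, "network_arch"))
  if (!is.null(arch$seed)) set.seed(arch$seed)
  h <- arch$units_per_layer
  H <- arch$n_hidden_layers
  runifm <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)
  W <- vector("list", H)
  b <- vector("list", H)
  W[[1]] <- runifm(h, 3L, 1 / 3)
  b[[1]] <- stats::runif(h, -1 / sqrt(3), 1 / sqrt(3))
  if (H > 1L) {
    bound <- sqrt(6 / h) / arch$omega
    for (l in 2:H) {
      W[[l]] <- runifm(h, h, bound)
      b[[l]] <- stats::runif(h, -1 / sqrt(h), 1 / sqrt(h))
    }
  }
  Wo <- runifm(3L, h, arch$final_init_scale)
  bo <- numeric(3L)
  structure(list(arch = arch, W = W, b = b, Wo = Wo, bo = bo,
                 training_state = list(stage = NA_integer_,
                                       iteration = 0L)),
            class = "displacement_model")
}

#' @export
print.displacement_model <- function(x, ...) {
  cat(sprintf(
    "<displacement_model> %d sine layer(s) x %d units, omega = %g, %d parameters\n",
    x$arch$n_hidden_layers, x$arch$units_per_layer, x$arch$omega,
    n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Depends on the architecture only, never on the registered volume size:
#' the network represents the field continuously over the domain with a
#' fixed parameter budget.
#'
#' @param model a `displacement_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$W, length, numeric(1))) +
    sum(vapply(model$b, length, numeric(1))) +
    length(model$Wo) + length(model$bo)
}

check_coords_finite <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (any(!is.finite(coords))) {
    stop("non-finite coordinates passed to the displacement network",
         call. = FALSE)
  }
  coords
}

# forward pass; want_tangent additionally propagates d(.)/dx for the three
# input directions (the ingredients of the spatial Jacobian)
net_forward <- function(model, X, want_tangent = FALSE) {
  omega <- model$arch$omega
  H <- model$arch$n_hidden_layers
  N <- nrow(X)
  Z <- vector("list", H)      # sin activations
  C <- vector("list", H)      # cos(omega * a)
  S <- if (want_tangent) vector("list", H) else NULL  # pre-activation tangents
  Tt <- if (want_tangent) vector("list", H) else NULL # activation tangents
  Zprev <- X
  for (l in seq_len(H)) {
    A <- tcrossprod(Zprev, model$W[[l]])
    A <- A + rep(model$b[[l]], each = N)   # column-wise bias add
    A <- omega * A
    Z[[l]] <- sin(A)
    C[[l]] <- cos(A)
    if (want_tangent) {
      Sl <- vector("list", 3L)
      Tl <- vector("list", 3L)
      for (k in 1:3) {
        Sl[[k]] <- if (l == 1L) {
          matrix(model$W[[1]][, k], N, nrow(model$W[[1]]), byrow = TRUE)
        } else {
          tcrossprod(Tt[[l - 1L]][[k]], model$W[[l]])
        }
        Tl[[k]] <- (omega * C[[l]]) * Sl[[k]]
      }
      S[[l]] <- Sl
      Tt[[l]] <- Tl
    }
    Zprev <- Z[[l]]
  }
  u <- tcrossprod(Zprev, model$Wo)
  u <- u + rep(model$bo, each = N)
  out <- list(u = u, X = X, Z = Z, C = C)
  if (want_tangent) {
    out$S <- S
    out$Tt <- Tt
    Ju <- array(0, dim = c(N, 3L, 3L))
    for (k in 1:3) Ju[, , k] <- tcrossprod(Tt[[H]][[k]], model$Wo)
    out$Ju <- Ju
  }
  out
}

# reverse-mode gradients of a scalar loss wrt all weights, given the
# adjoints of the outputs: Ubar = dL/du (N x 3) and optionally
# Jbar = dL/dJu (N x 3 x 3, Ju = du/dx). The Jbar path backpropagates
# through the forward-mode tangent computation (second-order terms).
net_backward <- function(model, cache, Ubar, Jbar = NULL) {
  omega <- model$arch$omega
  H <- model$arch$n_hidden_layers
  want_t <- !is.null(Jbar)
  gW <- vector("list", H)
  gb <- vector("list", H)
  ZH <- cache$Z[[H]]
  gWo <- crossprod(Ubar, ZH)
  if (want_t) {
    for (k in 1:3) gWo <- gWo + crossprod(Jbar[, , k], cache$Tt[[H]][[k]])
  }
  gbo <- colSums(Ubar)
  Zbar <- Ubar %*% model$Wo
  Tbar <- if (want_t) lapply(1:3, function(k) Jbar[, , k] %*% model$Wo)
          else NULL
  for (l in H:1) {
    Cl <- cache$C[[l]]
    Zl <- cache$Z[[l]]
    abar <- (omega * Cl) * Zbar
    if (want_t) {
      acc <- Tbar[[1]] * cache$S[[l]][[1]] +
             Tbar[[2]] * cache$S[[l]][[2]] +
             Tbar[[3]] * cache$S[[l]][[3]]
      abar <- abar - (omega^2 * Zl) * acc
      Sbar <- lapply(1:3, function(k) (omega * Cl) * Tbar[[k]])
    }
    Zprev <- if (l > 1L) cache$Z[[l - 1L]] else cache$X
    gW[[l]] <- crossprod(abar, Zprev)
    gb[[l]] <- colSums(abar)
    if (want_t) {
      if (l > 1L) {
        for (k in 1:3) {
          gW[[l]] <- gW[[l]] + crossprod(Sbar[[k]], cache$Tt[[l - 1L]][[k]])
        }
      } else {
        for (k in 1:3) gW[[1]][, k] <- gW[[1]][, k] + colSums(Sbar[[k]])
      }
    }
    if (l > 1L) {
      Zbar <- abar %*% model$W[[l]]
      if (want_t) {
        Tbar <- lapply(1:3, function(k) Sbar[[k]] %*% model$W[[l]])
      }
    }
  }
  list(W = gW, b = gb, Wo = gWo, bo = gbo)
}

#' Evaluate the displacement field
#'
#' @param model a `displacement_model`.
#' @param coords N x 3 matrix of normalized coordinates (finite).
#' @return N x 3 matrix of displacements `u(coords)`.
#' @export
displace <- function(model, coords) {
  stopifnot(inherits(model, "displacement_model"))
  X <- check_coords_finite(coords)
  net_forward(model, X)$u
}

#' Evaluate the transformation Phi(x) = x + u(x)
#'
#' @inheritParams displace
#' @return N x 3 matrix of transformed coordinates.
#' @export
transform_coords <- function(model, coords) {
  X <- check_coords_finite(coords)
  X + displace(model, X)
}

#' Spatial Jacobian of the transformation
#'
#' `J_Phi(x) = I + du/dx`, computed exactly by forward-mode differentiation
#' through the network (no finite differences).
#'
#' @inheritParams displace
#' @return N x 3 x 3 array; `[n, i, k]` is `d Phi_i / d x_k` at point n.
#' @export
jacobian <- function(model, coords) {
  stopifnot(inherits(model, "displacement_model"))
  X <- check_coords_finite(coords)
  J <- net_forward(model, X, want_tangent = TRUE)$Ju
  for (i in 1:3) J[, i, i] <- J[, i, i] + 1
  J
}

#' Save / load a displacement model checkpoint
#'
#' A single uncompressed RDS file holding architecture, weights, training
#' state and an optional configuration hash; writing is deterministic, so
#' identical models give byte-identical checkpoints.
#'
#' @param model a `displacement_model`.
#' @param path checkpoint file.
#' @param config_hash optional hash string stored alongside the weights.
#' @export
save_model <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "displacement_model"))
  obj <- list(arch = model$arch, W = model$W, b = model$b, Wo = model$Wo,
              bo = model$bo, training_state = model$training_state,
              config_hash = config_hash)
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `displacement_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(arch = obj$arch, W = obj$W, b = obj$b, Wo = obj$Wo,
                 bo = obj$bo, training_state = obj$training_state,
                 config_hash = obj$config_hash),
            class = "displacement_model")
}

#' Export the displacement field on a grid as a 3-channel volume
#'
#' Evaluates u(x) at every voxel of `grid` and writes a 4D NIfTI-like
#' stack as three scalar NIfTI volumes (one per component), returned as a
#' list of [pa_volume]s; use [write_volume()] on each, or
#' `write_displacement_field()` to write `<prefix>_u{x,y,z}.nii`.
#'
#' @param model a `displacement_model`.
#' @param grid a [pa_volume] defining the evaluation grid.
#' @param chunk evaluation chunk size (points per forward pass).
#' @return list of three [pa_volume]s (displacement in normalized units).
#' @export
displacement_field <- function(model, grid, chunk = 100000L) {
  stopifnot(inherits(model, "displacement_model"), is_pa_volume(grid))
  idx <- grid_voxel_coords(grid$shape)
  U <- matrix(0, nrow(idx), 3L)
  xn <- voxel_to_normalized(grid, idx)
  for (start in seq(1L, nrow(xn), by = chunk)) {
    end <- min(start + chunk - 1L, nrow(xn))
    U[start:end, ] <- displace(model, xn[start:end, , drop = FALSE])
  }
  lapply(1:3, function(k) {
    pa_volume(array(U[, k], dim = grid$shape), spacing = grid$spacing,
              frame_tag = sprintf("u%s", c("x", "y", "z")[k]))
  })
}

#' @rdname displacement_field
#' @param prefix output path prefix.
#' @export
write_displacement_field <- function(model, grid, prefix) {
  comps <- displacement_field(model, grid)
  paths <- sprintf("%s_u%s.nii", prefix, c("x", "y", "z"))
  for (k in 1:3) write_volume(comps[[k]], paths[k])
  invisible(paths)
}

# all 0-based voxel index triples of a grid, in column-major order
grid_voxel_coords <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1, times = shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}
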