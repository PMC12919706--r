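# ------------------------------------------------------------------
# Adam optimizer over a named list of arrays, and direct (network-free)
# optimization of a gridded displacement field against an image pair.
# ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(state, params, grads, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

#' Optimize a gridded displacement field directly
#'
#' Gradient-based (Adam) minimization of image MSE plus bending energy
#' over the control-point displacements, with no network involved. This
#' is the classical free-form-deformation route and doubles as a
#' solvability check for synthetic pairs.
#'
#' @param fixed,moving `image_volume`s or arrays of identical shape
#' @param grid_size control-grid size (default 5^3)
#' @param upsampler an `upsampler_config`
#' @param lambda3 bending-energy weight
#' @param iters gradient steps
#' @param lr Adam learning rate (voxel units per step scale)
#' @param init optional `(3, gw, gh, gd)` starting field
#' @return list: `gdf` (`gridded_field`), `loss` trace, `mse` final
#'   image MSE
#' @export
fit_gdf <- function(fixed, moving, grid_size = c(5L, 5L, 5L),
                    upsampler = upsampler_config(), lambda3 = 0.02,
                    iters = 500L, lr = 0.2, init = NULL) {
  fx <- as_arr(fixed); mv <- as_arr(moving)
  shp <- dim(fx)
  grid <- make_control_grid(shp, grid_size)
  v <- if (is.null(init)) array(0, c(3, grid$size)) else init
  st <- adam_state(list(v = v))
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    tp <- ad_tape()
    vn <- ad_param(tp, v)
    dense <- upsample(vn, shp, upsampler)
    warped <- ad_warp(mv, dense)
    loss <- ad_add(similarity_image(warped, fx),
                   ad_scale(bending_energy(dense), lambda3))
    trace[it] <- val(loss)
    if (!is.finite(trace[it])) stop("non-finite loss at iteration ", it)
    ad_backward(tp, loss)
    up <- adam_update(st, list(v = v), list(v = vn$grad), lr)
    st <- up$state
    v <- up$params$v
  }
  dense <- upsample(v, shp, upsampler)
  list(gdf = gridded_field(grid, v), loss = trace,
       mse = similarity_image(warp_fw(mv, dense, 0L), fx))
}
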