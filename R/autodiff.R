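#' @useDynLib gridreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ------------------------------------------------------------------
# A compact reverse-mode automatic differentiation tape.
#
# Nodes are environments holding a value (numeric array), an accumulated
# gradient, references to parent nodes and a backward closure. Operations
# accept plain numeric arrays (treated as constants) or nodes, so loss
# functions run unchanged on raw arrays and on the tape. Granularity is
# one node per layer-level operation, so interpreter overhead is
# negligible next to the array work.
# ------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

is_node <- function(x) inherits(x, "ad_node")

val <- function(x) if (is_node(x)) x$value else x

new_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "ad_node"
  nd
}

#' Create a leaf (parameter) node on a tape
#'
#' Parameters are the nodes whose gradients are collected after
#' [ad_backward()]; constants never need wrapping, any plain array passed
#' to an op is treated as constant.
#'
#' @param tape a tape from `ad_tape()`
#' @param value numeric array
#' @return an `ad_node`
#' @keywords internal
ad_param <- function(tape, value) {
  nd <- new_node(tape, value)
  nd$tape <- tape
  nd
}

acc_grad <- function(p, g) {
  if (is_node(p)) p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation from a scalar node
#'
#' @param tape the tape the graph lives on
#' @param loss scalar output node
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd) && !is.null(nd$grad) && !is.null(nd$backfn))
      nd$backfn(nd$grad)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Each node remembers its tape so ops can find it.
node_on <- function(tape, value, parents, backfn) {
  nd <- new_node(tape, value, parents, backfn)
  nd$tape <- tape
  nd
}

find_tape <- function(...) {
  for (x in list(...)) if (is_node(x)) return(x$tape)
  stop("no node argument")
}

ad_add <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(a + b)
  tp <- find_tape(a, b)
  node_on(tp, val(a) + val(b), list(a, b), function(g) {
    acc_grad(a, g); acc_grad(b, g)
  })
}

ad_sub <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(a - b)
  tp <- find_tape(a, b)
  node_on(tp, val(a) - val(b), list(a, b), function(g) {
    acc_grad(a, g); acc_grad(b, -g)
  })
}

ad_mul <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(a * b)
  tp <- find_tape(a, b)
  av <- val(a); bv <- val(b)
  node_on(tp, av * bv, list(a, b), function(g) {
    acc_grad(a, g * bv); acc_grad(b, g * av)
  })
}

ad_div <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(a / b)
  tp <- find_tape(a, b)
  av <- val(a); bv <- val(b)
  node_on(tp, av / bv, list(a, b), function(g) {
    acc_grad(a, g / bv); acc_grad(b, -g * av / (bv * bv))
  })
}

ad_scale <- function(a, k) {
  if (!is_node(a)) return(a * k)
  node_on(a$tape, val(a) * k, list(a), function(g) acc_grad(a, g * k))
}

ad_sum <- function(a) {
  if (!is_node(a)) return(sum(a))
  shp <- dim(val(a)) %||% length(val(a))
  node_on(a$tape, sum(val(a)), list(a), function(g) {
    ga <- array(g, dim = if (length(shp) > 1L) shp else NULL)
    if (is.null(dim(ga))) ga <- rep(g, shp)
    acc_grad(a, ga)
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(val(a)))

ad_relu <- function(a) {
  if (!is_node(a)) return(pmax(a, 0))
  av <- val(a)
  node_on(a$tape, pmax(av, 0), list(a), function(g) acc_grad(a, g * (av > 0)))
}

softplus_ <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

ad_softplus <- function(a) {
  if (!is_node(a)) return(keep_dim(a, softplus_(a)))
  av <- val(a)
  node_on(a$tape, keep_dim(av, softplus_(av)), list(a),
          function(g) acc_grad(a, g / (1 + exp(-av))))
}

keep_dim <- function(template, x) {
  if (!is.null(dim(template))) dim(x) <- dim(template)
  x
}

ad_log <- function(a) {
  if (!is_node(a)) return(log(a))
  av <- val(a)
  node_on(a$tape, log(av), list(a), function(g) acc_grad(a, g / av))
}

ad_sqrt <- function(a) {
  if (!is_node(a)) return(sqrt(a))
  sv <- sqrt(val(a))
  node_on(a$tape, sv, list(a), function(g) acc_grad(a, g / (2 * sv)))
}

# clamp from below; gradient passes only where the input is above the floor
ad_clamp_min <- function(a, lo) {
  if (!is_node(a)) return(pmax(a, lo))
  av <- val(a)
  node_on(a$tape, keep_dim(av, pmax(av, lo)), list(a),
          function(g) acc_grad(a, g * (av > lo)))
}

ad_matmul <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(a %*% b)
  tp <- find_tape(a, b)
  av <- val(a); bv <- val(b)
  node_on(tp, av %*% bv, list(a, b), function(g) {
    acc_grad(a, g %*% t(bv)); acc_grad(b, t(av) %*% g)
  })
}

# X %*% W + bias broadcast over rows
ad_linear <- function(x, w, b) {
  if (!is_node(x) && !is_node(w) && !is_node(b))
    return(sweep(x %*% w, 2, b, "+"))
  tp <- find_tape(x, w, b)
  xv <- val(x); wv <- val(w)
  node_on(tp, sweep(xv %*% wv, 2, val(b), "+"), list(x, w, b), function(g) {
    acc_grad(x, g %*% t(wv))
    acc_grad(w, t(xv) %*% g)
    acc_grad(b, colSums(g))
  })
}

ad_t <- function(a) {
  if (!is_node(a)) return(t(a))
  node_on(a$tape, t(val(a)), list(a), function(g) acc_grad(a, t(g)))
}

ad_softmax_rows <- function(a) {
  smax <- function(m) {
    e <- exp(m - apply(m, 1, max))
    e / rowSums(e)
  }
  if (!is_node(a)) return(smax(a))
  sv <- smax(val(a))
  node_on(a$tape, sv, list(a), function(g) {
    acc_grad(a, sv * (g - rowSums(g * sv)))
  })
}

ad_cols <- function(a, idx) {
  if (!is_node(a)) return(a[, idx, drop = FALSE])
  av <- val(a)
  node_on(a$tape, av[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, idx] <- g
    acc_grad(a, ga)
  })
}

ad_cbind <- function(a, b) {
  if (!is_node(a) && !is_node(b)) return(cbind(a, b))
  tp <- find_tape(a, b)
  na <- ncol(val(a))
  node_on(tp, cbind(val(a), val(b)), list(a, b), function(g) {
    acc_grad(a, g[, seq_len(na), drop = FALSE])
    acc_grad(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_reshape <- function(a, dims) {
  if (!is_node(a)) { dim(a) <- dims; return(a) }
  av <- val(a)
  old <- dim(av) %||% length(av)
  v <- av; dim(v) <- dims
  node_on(a$tape, v, list(a), function(g) {
    dim(g) <- if (length(old) > 1L) old else NULL
    acc_grad(a, g)
  })
}

ad_aperm <- function(a, perm) {
  if (!is_node(a)) return(aperm(a, perm))
  inv <- order(perm)
  node_on(a$tape, aperm(val(a), perm), list(a),
          function(g) acc_grad(a, aperm(g, inv)))
}

# ---- compiled ops ------------------------------------------------

ad_conv3d <- function(x, w, b, stride = 2L) {
  if (!is_node(x) && !is_node(w) && !is_node(b))
    return(conv3d_fw(x, w, b, as.integer(stride)))
  tp <- find_tape(x, w, b)
  xv <- val(x); wv <- val(w); bv <- val(b)
  node_on(tp, conv3d_fw(xv, wv, bv, as.integer(stride)), list(x, w, b),
          function(g) {
            gr <- conv3d_bw(xv, wv, g, as.integer(stride))
            acc_grad(x, gr$gx); acc_grad(w, gr$gw); acc_grad(b, gr$gb)
          })
}

# Apply a constant matrix along one spatial axis of a (C, nx, ny, nz) array:
# axis in 2:4, M of shape (m_out, n_axis).
axis_apply <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- M %*% matrix(a, nrow = da[1])
  dim(m) <- c(nrow(M), da[-1])
  aperm(m, order(perm))
}

# y[c, i, j, k] = sum_{a,b,c'} Mx[i,a] My[j,b] Mz[k,c'] x[c, a, b, c']
ad_axismats <- function(x, Mx, My, Mz) {
  fwd <- function(v) {
    v <- axis_apply(v, Mx, 2L)
    v <- axis_apply(v, My, 3L)
    axis_apply(v, Mz, 4L)
  }
  if (!is_node(x)) return(fwd(x))
  node_on(x$tape, fwd(val(x)), list(x), function(g) {
    g <- axis_apply(g, t(Mx), 2L)
    g <- axis_apply(g, t(My), 3L)
    acc_grad(x, axis_apply(g, t(Mz), 4L))
  })
}

# Differentiable backward warp; `moving` must be a constant volume.
ad_warp <- function(moving, ddf) {
  stopifnot(!is_node(moving))
  if (!is_node(ddf)) return(warp_fw(moving, ddf, 0L))
  dv <- val(ddf)
  node_on(ddf$tape, warp_fw(moving, dv, 0L), list(ddf),
          function(g) acc_grad(ddf, warp_bw_ddf(moving, dv, g)))
}
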