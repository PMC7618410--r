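## A small tape-based reverse-mode automatic differentiation engine over
## numeric matrices. The denoising network is written against these ops:
## with plain-matrix weights the ops fall through to base arithmetic (fast
## inference path); with parameter tensors they record a tape for backward().
##
## Supported broadcasting in elementwise ops: equal shapes, scalar (1 x 1)
## against anything, and an n x 1 column against an n x m matrix.

.ad <- new.env(parent = emptyenv())
.ad$n <- 0L
.ad$tape <- vector("list", 1024L)
.ad$tape_n <- 0L

# reset the recording tape (start of a fresh training step)
ad_tape_reset <- function() {
  .ad$tape <- vector("list", 1024L)
  .ad$tape_n <- 0L
  invisible(NULL)
}

is_tensor <- function(x) inherits(x, "adt")

# plain value of a tensor or passthrough
val <- function(x) if (is_tensor(x)) x$value else x

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) == 1L) 1L else length(x))
}

# tensor constructors ---------------------------------------------------------

ad_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value)
  e$grad <- NULL
  e$parents <- list()
  e$backward <- NULL
  e$requires <- TRUE
  e$ord <- (.ad$n <- .ad$n + 1L)
  class(e) <- "adt"
  e
}

ad_const <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value)
  e$grad <- NULL
  e$parents <- list()
  e$backward <- NULL
  e$requires <- FALSE
  e$ord <- (.ad$n <- .ad$n + 1L)
  class(e) <- "adt"
  e
}

ad_detach <- function(x) if (is_tensor(x)) val(x) else x

# build a tape node; if no parent requires grad, collapse to a plain value
mk_node <- function(value, parents, backward) {
  req <- FALSE
  for (p in parents) if (inherits(p, "adt") && p$requires) { req <- TRUE; break }
  if (!req) return(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires <- TRUE
  e$ord <- (.ad$n <- .ad$n + 1L)
  class(e) <- "adt"
  nt <- .ad$tape_n + 1L
  if (nt > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[nt]] <- e
  .ad$tape_n <- nt
  e
}

# broadcasting helpers --------------------------------------------------------

bcast_apply <- function(a, b, f) {
  da <- dim(a); db <- dim(b)
  if (identical(da, db)) return(f(a, b))
  if (length(b) == 1L) return(f(a, as.numeric(b)))
  if (length(a) == 1L) return(f(as.numeric(a), b))
  if (!is.null(da) && !is.null(db) && db[1] == da[1] && db[2] == 1L)
    return(f(a, as.vector(b)))
  if (!is.null(da) && !is.null(db) && da[1] == db[1] && da[2] == 1L)
    return(f(as.vector(a), b))
  stop("incompatible shapes for broadcast: ",
       paste(da, collapse = "x"), " vs ", paste(db, collapse = "x"))
}

reduce_to <- function(g, target_dim) {
  dg <- dim(g)
  if (identical(dg, target_dim)) return(g)
  if (all(target_dim == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  if (target_dim[1] == dg[1] && target_dim[2] == 1L)
    return(matrix(rowSums(g), ncol = 1L))
  stop("cannot reduce gradient to target shape")
}

# elementwise arithmetic ------------------------------------------------------

ad_add <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(bcast_apply(as_mat(a), as_mat(b), `+`))
  va <- as_mat(val(a)); vb <- as_mat(val(b))
  mk_node(bcast_apply(va, vb, `+`), list(a, b), function(g) {
    list(reduce_to(g, dim(va)), reduce_to(g, dim(vb)))
  })
}

ad_sub <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(bcast_apply(as_mat(a), as_mat(b), `-`))
  va <- as_mat(val(a)); vb <- as_mat(val(b))
  mk_node(bcast_apply(va, vb, `-`), list(a, b), function(g) {
    list(reduce_to(g, dim(va)), reduce_to(-g, dim(vb)))
  })
}

ad_mul <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(bcast_apply(as_mat(a), as_mat(b), `*`))
  va <- as_mat(val(a)); vb <- as_mat(val(b))
  mk_node(bcast_apply(va, vb, `*`), list(a, b), function(g) {
    list(reduce_to(bcast_apply(g, vb, `*`), dim(va)),
         reduce_to(bcast_apply(g, va, `*`), dim(vb)))
  })
}

ad_div <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(bcast_apply(as_mat(a), as_mat(b), `/`))
  va <- as_mat(val(a)); vb <- as_mat(val(b))
  out <- bcast_apply(va, vb, `/`)
  mk_node(out, list(a, b), function(g) {
    list(reduce_to(bcast_apply(g, vb, `/`), dim(va)),
         reduce_to(-bcast_apply(bcast_apply(g, out, `*`), vb, `/`), dim(vb)))
  })
}

ad_neg <- function(a) ad_mul(a, -1)

#' @export
Ops.adt <- function(e1, e2) {
  if (missing(e2)) {
    return(switch(.Generic, "-" = ad_neg(e1), "+" = e1,
                  stop("unsupported unary op for tensors: ", .Generic)))
  }
  switch(.Generic,
    "+" = ad_add(e1, e2),
    "-" = ad_sub(e1, e2),
    "*" = ad_mul(e1, e2),
    "/" = ad_div(e1, e2),
    "^" = ad_pow(e1, e2),
    stop("unsupported op for tensors: ", .Generic))
}

ad_pow <- function(a, p) {
  p <- as.numeric(val(p))
  if (!is_tensor(a)) return(as_mat(a)^p)
  va <- val(a)
  mk_node(va^p, list(a), function(g) list(g * (p * va^(p - 1))))
}

# unary math -------------------------------------------------------------------

ad_unary <- function(a, fwd, grad_fn) {
  if (!is_tensor(a)) return(fwd(as_mat(a)))
  va <- val(a)
  out <- fwd(va)
  mk_node(out, list(a), function(g) list(g * grad_fn(va, out)))
}

ad_exp <- function(a) ad_unary(a, exp, function(x, y) y)
ad_log <- function(a) ad_unary(a, log, function(x, y) 1 / x)
ad_sqrt <- function(a) ad_unary(a, sqrt, function(x, y) 0.5 / y)
ad_tanh <- function(a) ad_unary(a, tanh, function(x, y) 1 - y^2)
ad_sigmoid <- function(a)
  ad_unary(a, function(x) 1 / (1 + exp(-x)), function(x, y) y * (1 - y))
ad_gelu <- function(a)
  ad_unary(a, function(x) x * stats::pnorm(x),
           function(x, y) stats::pnorm(x) + x * stats::dnorm(x))

#' @export
Math.adt <- function(x, ...) {
  switch(.Generic,
    exp = ad_exp(x), log = ad_log(x), sqrt = ad_sqrt(x), tanh = ad_tanh(x),
    abs = ad_unary(x, abs, function(v, y) sign(v)),
    stop("unsupported math function for tensors: ", .Generic))
}

# clip values to [lo, hi]; gradient is zero outside the interval
ad_clip <- function(a, lo, hi) {
  if (!is_tensor(a)) return(pmin(pmax(as_mat(a), lo), hi))
  va <- val(a)
  out <- pmin(pmax(va, lo), hi)
  mk_node(out, list(a), function(g) list(g * ((va >= lo) & (va <= hi))))
}

ad_pmax <- function(a, lo) {
  if (!is_tensor(a)) return(pmax(as_mat(a), lo))
  va <- val(a)
  mk_node(pmax(va, lo), list(a), function(g) list(g * (va >= lo)))
}

# matrix product ---------------------------------------------------------------

ad_matmul <- function(a, b) {
  if (!is_tensor(a) && !is_tensor(b)) return(a %*% b)
  va <- val(a); vb <- val(b)
  mk_node(va %*% vb, list(a, b), function(g) {
    list(g %*% t(vb), t(va) %*% g)
  })
}

`%mm%` <- function(a, b) ad_matmul(a, b)

# reductions -------------------------------------------------------------------

ad_sum <- function(a) {
  if (!is_tensor(a)) return(matrix(sum(a), 1L, 1L))
  va <- val(a)
  mk_node(matrix(sum(va), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(va), ncol(va)))
  })
}

ad_mean <- function(a) {
  n <- length(val(a))
  ad_mul(ad_sum(a), 1 / n)
}

ad_rowsums <- function(a) {
  if (!is_tensor(a)) return(matrix(rowSums(as_mat(a)), ncol = 1L))
  va <- val(a)
  mk_node(matrix(rowSums(va), ncol = 1L), list(a), function(g) {
    list(matrix(as.vector(g), nrow(va), ncol(va)))
  })
}

# structure ops ----------------------------------------------------------------

ad_gather_rows <- function(a, idx) {
  idx <- as.integer(idx)
  if (!is_tensor(a)) return(as_mat(a)[idx, , drop = FALSE])
  va <- val(a)
  mk_node(va[idx, , drop = FALSE], list(a), function(g) {
    acc <- matrix(0, nrow(va), ncol(va))
    rs <- rowsum(g, idx)
    acc[as.integer(rownames(rs)), ] <- rs
    list(acc)
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  if (!any(vapply(args, is_tensor, logical(1))))
    return(do.call(cbind, lapply(args, as_mat)))
  vals <- lapply(args, function(x) as_mat(val(x)))
  widths <- vapply(vals, ncol, integer(1))
  mk_node(do.call(cbind, vals), args, function(g) {
    out <- vector("list", length(args))
    at <- 0L
    for (i in seq_along(args)) {
      out[[i]] <- g[, (at + 1L):(at + widths[i]), drop = FALSE]
      at <- at + widths[i]
    }
    out
  })
}

ad_cols <- function(a, j) {
  j <- as.integer(j)
  if (!is_tensor(a)) return(as_mat(a)[, j, drop = FALSE])
  va <- val(a)
  mk_node(va[, j, drop = FALSE], list(a), function(g) {
    acc <- matrix(0, nrow(va), ncol(va))
    # j may contain repeats in principle; accumulate column-wise
    for (k in seq_along(j)) acc[, j[k]] <- acc[, j[k]] + g[, k]
    list(acc)
  })
}

# masked row-softmax; rows with no valid entry get all-zero weights
ad_softmax_rows <- function(a, mask = NULL) {
  va <- val(a)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(va), ncol(va))
  shifted_max <- apply(ifelse(mask, va, -Inf), 1, max)
  shifted_max[!is.finite(shifted_max)] <- 0
  z <- ad_sub(a, matrix(shifted_max, ncol = 1L))
  w <- ad_mul(ad_exp(z), mask * 1)
  denom <- ad_add(ad_rowsums(w), 1e-30)
  ad_div(w, denom)
}

# layer norm over columns of each row
ad_layernorm <- function(a, gain = NULL, bias = NULL, eps = 1e-5) {
  m <- ncol(as_mat(val(a)))
  mu <- ad_mul(ad_rowsums(a), 1 / m)
  centred <- ad_sub(a, mu)
  var_ <- ad_mul(ad_rowsums(ad_mul(centred, centred)), 1 / m)
  out <- ad_div(centred, ad_sqrt(ad_add(var_, eps)))
  if (!is.null(gain)) out <- ad_mul(out, t_row(gain, nrow(as_mat(val(a)))))
  if (!is.null(bias)) out <- ad_add(out, t_row(bias, nrow(as_mat(val(a)))))
  out
}

# broadcast a 1 x m row parameter across n rows (via matmul with ones)
t_row <- function(row, n) ad_matmul(matrix(1, n, 1L), row)

# backward pass ----------------------------------------------------------------

# reverse sweep over the recording tape: node creation order is a valid
# topological order (parents are always created before children)
ad_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(val(loss)) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  tape <- .ad$tape
  for (i in seq.int(.ad$tape_n, 1L)) {
    node <- tape[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node$grad)
    parents <- node$parents
    for (k in seq_along(parents)) {
      p <- parents[[k]]
      if (inherits(p, "adt") && p$requires && !is.null(grads[[k]])) {
        p$grad <- if (is.null(p$grad)) grads[[k]] else p$grad + grads[[k]]
      }
    }
    node$grad <- NULL
  }
  invisible(loss)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
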