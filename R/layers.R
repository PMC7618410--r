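## Neural layer toolkit on top of the autodiff ops: a lazily-populated
## parameter store with deterministic per-name initialization, linear /
## GeGLU / layer-norm layers, per-residue rotation algebra on N x 9 rotation
## matrices, and grouped reshape/pool primitives used by sparse attention.

## grouped reshape/pool primitives --------------------------------------------

# (N*K) x 1 slot-major column -> N x K matrix
ad_group_mat <- function(v, n, k) {
  if (!is_tensor(v)) return(t(matrix(as.vector(v), k, n)))
  vv <- val(v)
  mk_node(t(matrix(as.vector(vv), k, n)), list(v), function(g) {
    list(matrix(as.vector(t(g)), ncol = 1L))
  })
}

# N x K matrix -> (N*K) x 1 slot-major column
ad_flat_col <- function(m) {
  if (!is_tensor(m)) return(matrix(as.vector(t(m)), ncol = 1L))
  vm <- val(m)
  mk_node(matrix(as.vector(t(vm)), ncol = 1L), list(m), function(g) {
    list(t(matrix(as.vector(g), ncol(vm), nrow(vm))))
  })
}

# sum rows of x by integer group (1..n_groups, all present)
ad_pool_rows <- function(x, groups, n_groups) {
  groups <- as.integer(groups)
  if (!is_tensor(x)) return(rowsum(as_mat(x), groups))
  vx <- val(x)
  mk_node(rowsum(vx, groups), list(x), function(g) {
    list(g[groups, , drop = FALSE])
  })
}

## parameter store -------------------------------------------------------------

str_hash <- function(s) {
  h <- 17
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Create a parameter store
#'
#' Parameters are created lazily on first request with a deterministic
#' per-name initialization stream derived from the store seed, so a model's
#' weights are reproducible given its seed regardless of call order.
#'
#' @param seed integer seed.
#' @return an environment of class \code{"ParamStore"}.
#' @export
paramStore <- function(seed = 1L) {
  ps <- new.env(parent = emptyenv())
  ps$values <- list()
  ps$tensors <- NULL
  ps$seed <- as.integer(seed)
  class(ps) <- "ParamStore"
  ps
}

init_weight <- function(shape, init, seed, name) {
  with_seed((seed + str_hash(name)) %% 2147483647L, {
    n <- prod(shape)
    v <- switch(init,
      glorot = stats::rnorm(n, sd = sqrt(2 / (shape[1] + shape[2]))),
      normal = stats::rnorm(n, sd = 0.02),
      zeros = rep(0, n),
      ones = rep(1, n),
      stop("unknown initializer ", init))
    matrix(v, shape[1], shape[2])
  })
}

ps_get <- function(ps, name, shape, init = "glorot") {
  if (is.null(ps$values[[name]]))
    ps$values[[name]] <- init_weight(shape, init, ps$seed, name)
  if (!is.null(ps$tensors)) {
    if (is.null(ps$tensors[[name]]))
      ps$tensors[[name]] <- ad_param(ps$values[[name]])
    return(ps$tensors[[name]])
  }
  ps$values[[name]]
}

# enter training mode: subsequent ps_get calls return shared grad tensors;
# the recording tape restarts so each step's backward sweep is linear in the
# step's own graph
ps_train <- function(ps) {
  ps$tensors <- list()
  ad_tape_reset()
  invisible(ps)
}

# leave training mode, copying trained tensor values back into the store
ps_freeze <- function(ps) {
  if (!is.null(ps$tensors)) {
    for (name in names(ps$tensors)) ps$values[[name]] <- ps$tensors[[name]]$value
    ps$tensors <- NULL
  }
  invisible(ps)
}

ps_params <- function(ps) ps$tensors

#' @export
print.ParamStore <- function(x, ...) {
  n_par <- sum(vapply(x$values, length, numeric(1)))
  cat(sprintf("ParamStore: %d tensors, %s parameters (seed %d)\n",
              length(x$values), format(n_par, big.mark = ","), x$seed))
  invisible(x)
}

## layers ----------------------------------------------------------------------

linear <- function(ps, name, x, out_dim, init = "glorot", bias = TRUE) {
  in_dim <- ncol(as_mat(val(x)))
  W <- ps_get(ps, paste0(name, "/w"), c(in_dim, out_dim), init)
  out <- ad_matmul(x, W)
  if (bias) {
    b <- ps_get(ps, paste0(name, "/b"), c(1L, out_dim), "zeros")
    out <- ad_add(out, t_row(b, nrow(as_mat(val(x)))))
  }
  out
}

# GeGLU feed-forward: value branch gated by a GELU branch
geglu <- function(ps, name, x, hidden_dim, out_dim, out_init = "glorot") {
  a <- linear(ps, paste0(name, "/value"), x, hidden_dim)
  g <- linear(ps, paste0(name, "/gate"), x, hidden_dim)
  h <- ad_mul(a, ad_gelu(g))
  linear(ps, paste0(name, "/out"), h, out_dim, init = out_init)
}

layernorm <- function(ps, name, x) {
  m <- ncol(as_mat(val(x)))
  gain <- ps_get(ps, paste0(name, "/gain"), c(1L, m), "ones")
  bias <- ps_get(ps, paste0(name, "/bias"), c(1L, m), "zeros")
  ad_layernorm(x, gain, bias)
}

## 3-vector and rotation algebra on row-stacked matrices -----------------------

v3_dot <- function(a, b) ad_rowsums(ad_mul(a, b))

v3_normalize <- function(a, eps = 1e-8) {
  ad_div(a, ad_sqrt(ad_add(v3_dot(a, a), eps)))
}

v3_cross <- function(a, b) {
  a1 <- ad_cols(a, 1L); a2 <- ad_cols(a, 2L); a3 <- ad_cols(a, 3L)
  b1 <- ad_cols(b, 1L); b2 <- ad_cols(b, 2L); b3 <- ad_cols(b, 3L)
  ad_cbind(ad_sub(ad_mul(a2, b3), ad_mul(a3, b2)),
           ad_sub(ad_mul(a3, b1), ad_mul(a1, b3)),
           ad_sub(ad_mul(a1, b2), ad_mul(a2, b1)))
}

# rotations stored as N x 9 with column (j-1)*3 + i holding R[i, j]
rot_col <- function(rot9, i, j) ad_cols(rot9, (j - 1L) * 3L + i)

# frames from N/CA/C coordinate blocks (each N x 3): Gram-Schmidt with the
# local x-axis along CA->C and N in the local xy-plane
frames_differentiable <- function(n_xyz, ca_xyz, c_xyz) {
  e1 <- v3_normalize(ad_sub(c_xyz, ca_xyz))
  u <- ad_sub(n_xyz, ca_xyz)
  e2 <- v3_normalize(ad_sub(u, ad_mul(e1, v3_dot(u, e1))))
  e3 <- v3_cross(e1, e2)
  list(rot9 = ad_cbind(e1, e2, e3), trans = ca_xyz)
}

# global = R %*% p_local (+ trans if given)
rot_apply <- function(rot9, p, trans = NULL) {
  p1 <- ad_cols(p, 1L); p2 <- ad_cols(p, 2L); p3 <- ad_cols(p, 3L)
  comp <- function(i) {
    ad_add(ad_add(ad_mul(rot_col(rot9, i, 1L), p1),
                  ad_mul(rot_col(rot9, i, 2L), p2)),
           ad_mul(rot_col(rot9, i, 3L), p3))
  }
  out <- ad_cbind(comp(1L), comp(2L), comp(3L))
  if (!is.null(trans)) out <- ad_add(out, trans)
  out
}

# local = R^T %*% (x - trans)
rot_invapply <- function(rot9, x, trans = NULL) {
  if (!is.null(trans)) x <- ad_sub(x, trans)
  x1 <- ad_cols(x, 1L); x2 <- ad_cols(x, 2L); x3 <- ad_cols(x, 3L)
  comp <- function(j) {
    ad_add(ad_add(ad_mul(rot_col(rot9, 1L, j), x1),
                  ad_mul(rot_col(rot9, 2L, j), x2)),
           ad_mul(rot_col(rot9, 3L, j), x3))
  }
  ad_cbind(comp(1L), comp(2L), comp(3L))
}

# relative rotation R_a^T R_b as N x 9 (both inputs row-aligned): the
# column-major rot9 layout makes R_b's columns three interleaved xyz points,
# so this is an inverse rotation of those points
rot_relative <- function(rot9_a, rot9_b) {
  rot_invapply_points(rot9_a, rot9_b)
}

# apply rotations to P points stored as N x (3P), returning the same layout.
# Vectorized over points: component planes are extracted with strided column
# slices and recombined with a single column permutation.
rot_apply_points <- function(rot9, pts, trans = NULL) {
  P <- ncol(as_mat(val(pts))) / 3L
  if (P == 1L) return(rot_apply(rot9, pts, trans))
  px <- ad_cols(pts, seq(1L, 3L * P, 3L))
  py <- ad_cols(pts, seq(2L, 3L * P, 3L))
  pz <- ad_cols(pts, seq(3L, 3L * P, 3L))
  comp <- function(i) {
    out <- ad_add(ad_add(ad_mul(px, rot_col(rot9, i, 1L)),
                         ad_mul(py, rot_col(rot9, i, 2L))),
                  ad_mul(pz, rot_col(rot9, i, 3L)))
    if (!is.null(trans)) out <- ad_add(out, ad_cols(trans, i))
    out
  }
  stacked <- ad_cbind(comp(1L), comp(2L), comp(3L))
  ad_cols(stacked, as.vector(rbind(seq_len(P), P + seq_len(P), 2L * P + seq_len(P))))
}

rot_invapply_points <- function(rot9, pts, trans = NULL) {
  P <- ncol(as_mat(val(pts))) / 3L
  if (P == 1L) return(rot_invapply(rot9, pts, trans))
  px <- ad_cols(pts, seq(1L, 3L * P, 3L))
  py <- ad_cols(pts, seq(2L, 3L * P, 3L))
  pz <- ad_cols(pts, seq(3L, 3L * P, 3L))
  if (!is.null(trans)) {
    px <- ad_sub(px, ad_cols(trans, 1L))
    py <- ad_sub(py, ad_cols(trans, 2L))
    pz <- ad_sub(pz, ad_cols(trans, 3L))
  }
  comp <- function(j) {
    ad_add(ad_add(ad_mul(px, rot_col(rot9, 1L, j)),
                  ad_mul(py, rot_col(rot9, 2L, j))),
           ad_mul(pz, rot_col(rot9, 3L, j)))
  }
  stacked <- ad_cbind(comp(1L), comp(2L), comp(3L))
  ad_cols(stacked, as.vector(rbind(seq_len(P), P + seq_len(P), 2L * P + seq_len(P))))
}

# constant grouping matrix summing interleaved xyz columns per point:
# (3P columns) -> (P columns)
point_group_matrix <- function(P) {
  G <- matrix(0, 3L * P, P)
  for (p in seq_len(P)) G[(3L * p - 2L):(3L * p), p] <- 1
  G
}

# per-point squared norms of N x (3P) interleaved coordinates -> N x P
point_sq_norms <- function(pts) {
  P <- ncol(as_mat(val(pts))) / 3L
  ad_matmul(ad_mul(pts, pts), point_group_matrix(P))
}

# Fourier features of a scalar (diffusion time): [sin, cos](2^j * pi * t)
fourier_time_embedding <- function(t, n_freq = 8L) {
  freq <- 2^(seq_len(n_freq) - 1L)
  c(sin(pi * freq * t), cos(pi * freq * t))
}
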