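# Shared test helpers: rigid-transform utilities and independent brute-force
# oracles (dense IPA, dense FAPE) coded with explicit loops, deliberately not
# sharing code with the package's vectorized implementations.

random_proper_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_xmat <- function(xmat, Q, tv) {
  out <- xmat
  n_atoms <- ncol(xmat) / 3
  for (a in seq_len(n_atoms)) {
    cols <- (3 * a - 2):(3 * a)
    out[, cols] <- xmat[, cols] %*% t(Q) +
      matrix(tv, nrow(xmat), 3, byrow = TRUE)
  }
  out
}

frames_plain <- function(backbone) {
  fs <- buildFrames(backbone)
  n <- dim(fs@rotations)[1]
  rot9 <- matrix(0, n, 9)
  for (j in 1:3) for (i in 1:3) rot9[, (j - 1) * 3 + i] <- fs@rotations[, i, j]
  list(rot9 = rot9, trans = fs@translations, set = fs)
}

softplus_plain <- function(x) log1p(exp(x))

# brute-force dense invariant point attention with explicit loops over
# residues, neighbours, heads and points; reads the same weight store
dense_ipa_oracle <- function(ps_values, name, local, rot, trans, pair_array,
                             config) {
  n <- nrow(local)
  H <- config$n_heads; dq <- config$scalar_qk_dim
  Pq <- config$point_qk; Pv <- config$point_v
  D <- config$local_size
  w_l <- sqrt(1 / 3); w_c <- sqrt(2 / (9 * Pq))
  W <- function(nm) ps_values[[paste0(name, "/", nm, "/w")]]
  q <- local %*% W("q"); k <- local %*% W("k"); v <- local %*% W("v")
  qp <- local %*% W("qp"); kp <- local %*% W("kp"); vp <- local %*% W("vp")
  gamma <- softplus_plain(ps_values[[paste0(name, "/gamma")]])
  Wb <- W("pair_bias")
  # rot: list of 3x3 matrices per residue; global points in the network's
  # 10 A coordinate unit (translations scaled by 1/position_scale)
  unit <- 1 / config$position_scale
  to_global <- function(pts_local, i) {
    P <- length(pts_local) / 3
    out <- numeric(3 * P)
    for (p in seq_len(P)) {
      lp <- pts_local[(3 * p - 2):(3 * p)]
      out[(3 * p - 2):(3 * p)] <- rot[[i]] %*% lp + unit * trans[i, ]
    }
    out
  }
  qg <- t(sapply(seq_len(n), function(i) to_global(qp[i, ], i)))
  kg <- t(sapply(seq_len(n), function(i) to_global(kp[i, ], i)))
  vg <- t(sapply(seq_len(n), function(i) to_global(vp[i, ], i)))
  concat <- matrix(0, n, H * (dq + 3 * Pv + Pv + config$pair_size))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    per_head <- list()
    for (h in seq_len(H)) {
      sc <- (h - 1) * dq + seq_len(dq)
      logits <- sapply(others, function(j) {
        scal <- sum(q[i, sc] * k[j, sc]) / sqrt(dq)
        bias <- sum(pair_array[i, j, ] * Wb[, h])
        ptd <- 0
        for (p in seq_len(Pq)) {
          pc <- ((h - 1) * Pq + p - 1) * 3 + 1:3
          ptd <- ptd + sum((qg[i, pc] - kg[j, pc])^2)
        }
        w_l * (scal + bias - gamma[1, h] * w_c / 2 * ptd)
      })
      a <- exp(logits - max(logits)); a <- a / sum(a)
      o_scal <- colSums(a * v[others, sc, drop = FALSE])
      vc <- (h - 1) * Pv * 3 + seq_len(Pv * 3)
      o_pt_g <- colSums(a * vg[others, vc, drop = FALSE])
      o_pt_l <- numeric(3 * Pv); norms <- numeric(Pv)
      for (p in seq_len(Pv)) {
        pc <- (3 * p - 2):(3 * p)
        lp <- t(rot[[i]]) %*% (o_pt_g[pc] - unit * trans[i, ])
        o_pt_l[pc] <- lp
        norms[p] <- sqrt(sum(lp^2) + 1e-8)
      }
      o_pair <- colSums(a * t(sapply(others, function(j) pair_array[i, j, ])))
      per_head[[h]] <- c(o_scal, o_pt_l, norms, o_pair)
    }
    concat[i, ] <- unlist(per_head)
  }
  out <- concat %*% ps_values[[paste0(name, "/out/w")]]
  sweep(out, 2, -as.vector(ps_values[[paste0(name, "/out/b")]]))
}

# dense FAPE oracle: all (i, j) pairs restricted to a neighbour list, loops
dense_fape_oracle <- function(xmat_pred, backbone_pred_frames, xmat_gt,
                              backbone_gt_frames, pairs_i, pairs_j, n_atoms,
                              clip = 10) {
  total <- 0
  for (r in seq_along(pairs_i)) {
    i <- pairs_i[r]; j <- pairs_j[r]
    Rp <- backbone_pred_frames[[i]]$R; tp <- backbone_pred_frames[[i]]$t
    Rg <- backbone_gt_frames[[i]]$R; tg <- backbone_gt_frames[[i]]$t
    for (a in seq_len(n_atoms)) {
      cols <- (3 * a - 2):(3 * a)
      lp <- t(Rp) %*% (xmat_pred[j, cols] - tp)
      lg <- t(Rg) %*% (xmat_gt[j, cols] - tg)
      d <- min(sqrt(sum((lp - lg)^2) + 1e-12), clip)
      total <- total + d^2
    }
  }
  total / (length(pairs_i) * n_atoms)
}

frame_list <- function(backbone_or_xmat) {
  if (is(backbone_or_xmat, "BackboneStructure")) {
    fs <- buildFrames(backbone_or_xmat)
    lapply(seq_len(dim(fs@rotations)[1]), function(i)
      list(R = fs@rotations[i, , ], t = fs@translations[i, ]))
  } else {
    xm <- backbone_or_xmat
    lapply(seq_len(nrow(xm)), function(i) {
      e1 <- xm[i, 7:9] - xm[i, 4:6]; e1 <- e1 / sqrt(sum(e1^2))
      u <- xm[i, 1:3] - xm[i, 4:6]
      e2 <- u - sum(u * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      list(R = cbind(e1, e2, e3), t = xm[i, 4:6])
    })
  }
}

# small model shared across network tests (weights perturbed once)
toy_test_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- denoiserModel(sparsebb:::toyModelConfig(), seed = 11L)
      cache <<- perturbWeights(m, sd = 0.05, seed = 4L)
    }
    cache
  }
})
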