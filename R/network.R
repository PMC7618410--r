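## The sparse denoising network: pair featurization, sparse invariant point
## attention (SparseIPA), feature update with global pooling, equivariant
## position updates, and the Encoder / DenoisingModule / AADecoder /
## autoencoder assemblies. All layers are written against the autodiff ops,
## so the same code serves gradient-free inference (plain-matrix weights)
## and training (parameter tensors).

RBF_N <- 16L
RBF_MAX <- 22
RBF_DELTA <- RBF_MAX / RBF_N      # 1.375 A centre spacing = bandwidth
RBF_CENTRES <- (seq_len(RBF_N) - 1L) * RBF_DELTA

#' Model configuration
#'
#' @param local_size per-residue feature width (default 256; 128 mirrors the
#'   lighter published hyperparameter table).
#' @param pair_size pair feature width (default 64).
#' @param n_blocks denoising blocks (default 6).
#' @param n_pseudoatoms learned pseudoatoms per residue (default 15).
#' @param n_heads,scalar_qk_dim,point_qk,point_v IPA shape parameters.
#' @param ff_factor GeGLU hidden multiplier (default 2).
#' @param pair_variant \code{"full"} or \code{"minimal"} pair features.
#' @param position_scale unit factor of position updates in Angstrom
#'   (default 10).
#' @param time_embedding include Fourier diffusion-time features.
#' @param encoder_blocks,decoder_blocks Encoder / AADecoder depths.
#' @param encoder_k fixed nearest-CA neighbour count for Encoder/AADecoder.
#' @param distogram_bins distance bins of the distogram head (64 over
#'   [2, 22] A).
#' @param latent_size autoencoder latent width.
#' @param vq_codebook vector-quantization codebook size (default 4096).
#' @param ae_decoder_blocks autoencoder decoder depth (default 6).
#' @param motif_first run the conditioning IPA before the current-position
#'   IPA (multi-motif variant).
#' @return a classed list.
#' @export
modelConfig <- function(local_size = 256L, pair_size = 64L, n_blocks = 6L,
                        n_pseudoatoms = 15L, n_heads = 8L, scalar_qk_dim = 32L,
                        point_qk = 4L, point_v = 8L, ff_factor = 2L,
                        pair_variant = c("full", "minimal"),
                        position_scale = 10, time_embedding = TRUE,
                        encoder_blocks = 2L, decoder_blocks = 3L,
                        encoder_k = 32L, distogram_bins = 64L,
                        latent_size = 32L, vq_codebook = 4096L,
                        ae_decoder_blocks = 6L, motif_first = FALSE) {
  pair_variant <- match.arg(pair_variant)
  cfg <- list(local_size = as.integer(local_size),
              pair_size = as.integer(pair_size),
              n_blocks = as.integer(n_blocks),
              n_pseudoatoms = as.integer(n_pseudoatoms),
              n_heads = as.integer(n_heads),
              scalar_qk_dim = as.integer(scalar_qk_dim),
              point_qk = as.integer(point_qk), point_v = as.integer(point_v),
              ff_factor = as.integer(ff_factor), pair_variant = pair_variant,
              position_scale = position_scale,
              time_embedding = isTRUE(time_embedding),
              encoder_blocks = as.integer(encoder_blocks),
              decoder_blocks = as.integer(decoder_blocks),
              encoder_k = as.integer(encoder_k),
              distogram_bins = as.integer(distogram_bins),
              latent_size = as.integer(latent_size),
              vq_codebook = as.integer(vq_codebook),
              ae_decoder_blocks = as.integer(ae_decoder_blocks),
              motif_first = isTRUE(motif_first))
  stopifnot(all(vapply(cfg[c("local_size", "pair_size", "n_blocks", "n_heads",
                             "scalar_qk_dim", "point_qk", "point_v")],
                       function(x) x > 0, logical(1))),
            cfg$position_scale > 0)
  structure(cfg, class = "ModelConfig")
}

# a small configuration for desk-scale experiments and tests; the width and
# depth are the smallest found to memorize a handful of fixtures
toyModelConfig <- function(...) {
  defaults <- list(local_size = 48L, pair_size = 16L, n_blocks = 3L,
                   n_heads = 4L, scalar_qk_dim = 8L, point_qk = 4L,
                   point_v = 4L, encoder_blocks = 1L, decoder_blocks = 1L,
                   encoder_k = 12L, distogram_bins = 16L, latent_size = 16L,
                   vq_codebook = 64L, ae_decoder_blocks = 2L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(modelConfig, defaults)
}

#' Create a denoising model
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed weight-initialization seed.
#' @return list of class \code{"DenoiserModel"} with elements \code{config}
#'   and \code{ps} (the \code{\link{paramStore}}).
#' @export
denoiserModel <- function(config = modelConfig(), seed = 1L) {
  structure(list(config = config, ps = paramStore(seed)), class = "DenoiserModel")
}

#' @export
print.DenoiserModel <- function(x, ...) {
  cat(sprintf("DenoiserModel: local_size %d, pair_size %d, %d blocks (%s pair features)\n",
              x$config$local_size, x$config$pair_size, x$config$n_blocks,
              x$config$pair_variant))
  print(x$ps)
  invisible(x)
}

#' Gaussian radial basis encoding of a distance
#'
#' 16 centres uniformly spaced on [0, 22) A with spacing 22/16 = 1.375 A;
#' the bandwidth equals the spacing.
#'
#' @param distance non-negative distance(s) in Angstrom.
#' @return matrix with one row per distance and 16 columns.
#' @export
rbfEncode <- function(distance) {
  if (any(distance < 0)) stop("distances must be non-negative")
  d <- matrix(distance, ncol = 1L)
  exp(-sweep(matrix(rep(d, RBF_N), ncol = RBF_N), 2, RBF_CENTRES)^2 /
        (2 * RBF_DELTA^2))
}

# autodiff RBF primitive: an n x m matrix of distances is encoded columnwise
# into n x (16 m), with 16-column blocks per input column
ad_rbf <- function(d) {
  rbf_fwd <- function(vd) {
    vd <- as_mat(vd)
    m <- ncol(vd)
    D <- vd[, rep(seq_len(m), each = RBF_N), drop = FALSE]
    C <- matrix(RBF_CENTRES, nrow(vd), RBF_N * m, byrow = TRUE)
    list(out = exp(-(D - C)^2 / (2 * RBF_DELTA^2)), D = D, C = C)
  }
  if (!is_tensor(d)) return(rbf_fwd(d)$out)
  vd <- as_mat(val(d))
  fw <- rbf_fwd(vd)
  mk_node(fw$out, list(d), function(g) {
    contrib <- g * fw$out * (-(fw$D - fw$C) / RBF_DELTA^2)
    m <- ncol(vd)
    gd <- matrix(0, nrow(vd), m)
    for (c in seq_len(m))
      gd[, c] <- rowSums(contrib[, (c - 1L) * RBF_N + seq_len(RBF_N), drop = FALSE])
    list(gd)
  })
}

#' Randomly perturb a model's weights
#'
#' Runs a forward pass to materialize all parameters, then adds Gaussian
#' noise to every weight (including the zero-initialized output layers, which
#' make an untrained model exactly the identity). Intended for random-weight
#' property testing of a non-trivial network.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param n_residues size of the probe structure used to materialize weights.
#' @param sd perturbation standard deviation.
#' @param seed RNG seed.
#' @return the model (parameter store modified in place).
#' @export
perturbWeights <- function(model, n_residues = 16L, sd = 0.05, seed = 1L) {
  probe <- makeFixture("mixed", length = n_residues, seed = 1L)
  aug <- encodeStructure(model, probe)
  invisible(denoiseStructure(model, aug, time = 0.5, seed = 1L))
  invisible(decodeAminoAcids(model, aug, matrix(0, n_residues,
                                                model$config$local_size)))
  with_seed(seed, {
    for (name in names(model$ps$values)) {
      v <- model$ps$values[[name]]
      model$ps$values[[name]] <- v + stats::rnorm(length(v), sd = sd)
    }
  })
  invisible(model)
}

## neighbour context -----------------------------------------------------------

nbr_ctx <- function(nbr) {
  idx <- nbr@indices
  valid <- nbr@valid
  # drop slot columns that are invalid for every residue (short chains)
  keep <- which(colSums(valid) > 0L)
  if (length(keep) == 0L) keep <- 1L
  idx <- idx[, keep, drop = FALSE]
  valid <- valid[, keep, drop = FALSE]
  n <- nrow(idx); k <- ncol(idx)
  idxf <- as.vector(t(idx))
  maskf <- as.vector(t(valid))
  idxf[!maskf] <- 1L
  list(n = n, k = k, idxf = idxf, rep_idx = rep(seq_len(n), each = k),
       maskf = matrix(as.numeric(maskf), ncol = 1L), valid = valid)
}

## pair features ---------------------------------------------------------------

# pair features for residue i against its neighbour slots (rows N*K,
# slot-major). Full variant: RBF-encoded distances between all pairs of the
# 5 physical atoms, CA->neighbour direction in the query local frame,
# relative rotation, and both residues' atoms in each other's local frames.
# Minimal variant: CA-distance RBF + relative rotation.
pair_feature_raw <- function(xq, xk, framesq, framesk, ctx, variant,
                             extra = NULL) {
  xg <- ad_gather_rows(xk, ctx$idxf)
  xr <- ad_gather_rows(xq, ctx$rep_idx)
  rotg <- ad_gather_rows(framesk$rot9, ctx$idxf)
  rotr <- ad_gather_rows(framesq$rot9, ctx$rep_idx)
  tg <- ad_gather_rows(framesk$trans, ctx$idxf)
  tr <- ad_gather_rows(framesq$trans, ctx$rep_idx)
  n_atoms_q <- ncol(as_mat(val(xq))) / 3L
  n_atoms_k <- ncol(as_mat(val(xk))) / 3L
  feats <- list()
  if (variant == "full") {
    na <- min(5L, n_atoms_q); nb <- min(5L, n_atoms_k)
    idx_a <- unlist(lapply(seq_len(na), function(a)
      rep.int((3L * a - 2L):(3L * a), nb)))
    idx_b <- rep(unlist(lapply(seq_len(nb), function(b) (3L * b - 2L):(3L * b))),
                 times = na)
    diff <- ad_sub(ad_cols(xr, idx_a), ad_cols(xg, idx_b))
    d <- ad_sqrt(ad_add(point_sq_norms(diff), 1e-12))
    feats[[length(feats) + 1L]] <- ad_rbf(d)
    # directions and cross-frame atom coordinates are expressed in the 10 A
    # network unit to keep linear-layer inputs O(1)
    feats[[length(feats) + 1L]] <- ad_mul(rot_invapply(rotr, ad_sub(tg, tr)), 0.1)
    feats[[length(feats) + 1L]] <- rot_relative(rotr, rotg)
    feats[[length(feats) + 1L]] <- ad_mul(rot_invapply_points(rotr, xg, tr), 0.1)
    feats[[length(feats) + 1L]] <- ad_mul(rot_invapply_points(rotg, xr, tg), 0.1)
  } else {
    diff <- ad_sub(tr, tg)
    d <- ad_sqrt(ad_add(v3_dot(diff, diff), 1e-12))
    feats[[length(feats) + 1L]] <- ad_rbf(d)
    feats[[length(feats) + 1L]] <- rot_relative(rotr, rotg)
  }
  if (!is.null(extra)) feats[[length(feats) + 1L]] <- extra
  do.call(ad_cbind, feats)
}

#' Compute projected pair features
#'
#' @param ps parameter store; \code{name} scopes the projection weights.
#' @param name parameter scope.
#' @param xq,xk query/key coordinate matrices (N x 3A).
#' @param framesq,framesk frame lists with \code{rot9} and \code{trans}.
#' @param ctx neighbour context from \code{nbr_ctx}.
#' @param variant \code{"full"} or \code{"minimal"}.
#' @param pair_size output width.
#' @param extra optional extra invariant channels (rows N*K).
#' @return (N*K) x pair_size feature matrix with masked slots zeroed.
#' @noRd
pair_features <- function(ps, name, xq, xk, framesq, framesk, ctx, variant,
                          pair_size, extra = NULL) {
  raw <- pair_feature_raw(xq, xk, framesq, framesk, ctx, variant, extra)
  out <- linear(ps, paste0(name, "/proj"), raw, pair_size)
  ad_mul(out, ctx$maskf)
}

## sparse invariant point attention --------------------------------------------

softplus <- function(x) log1p(exp(x))

sparse_ipa <- function(ps, name, local_q, local_k, framesq, framesk, ctx,
                       pair_feats, config) {
  H <- config$n_heads; dq <- config$scalar_qk_dim
  Pq <- config$point_qk; Pv <- config$point_v
  n <- ctx$n; k <- ctx$k
  w_l <- sqrt(1 / 3)
  w_c <- sqrt(2 / (9 * Pq))

  q <- linear(ps, paste0(name, "/q"), local_q, H * dq, bias = FALSE)
  kk <- linear(ps, paste0(name, "/k"), local_k, H * dq, bias = FALSE)
  vv <- linear(ps, paste0(name, "/v"), local_k, H * dq, bias = FALSE)
  qp_local <- linear(ps, paste0(name, "/qp"), local_q, H * Pq * 3L, bias = FALSE)
  kp_local <- linear(ps, paste0(name, "/kp"), local_k, H * Pq * 3L, bias = FALSE)
  vp_local <- linear(ps, paste0(name, "/vp"), local_k, H * Pv * 3L, bias = FALSE)
  # frame translations are expressed in the network's 10 A coordinate unit so
  # point-distance attention terms stay O(1) and the softmax does not saturate
  unit <- 1 / config$position_scale
  tq_u <- ad_mul(framesq$trans, unit)
  tk_u <- ad_mul(framesk$trans, unit)
  qp_g <- rot_apply_points(framesq$rot9, qp_local, tq_u)
  kp_g <- rot_apply_points(framesk$rot9, kp_local, tk_u)
  vp_g <- rot_apply_points(framesk$rot9, vp_local, tk_u)

  qg <- ad_gather_rows(q, ctx$rep_idx)
  kg <- ad_gather_rows(kk, ctx$idxf)
  vg <- ad_gather_rows(vv, ctx$idxf)
  qpg <- ad_gather_rows(qp_g, ctx$rep_idx)
  kpg <- ad_gather_rows(kp_g, ctx$idxf)
  vpg <- ad_gather_rows(vp_g, ctx$idxf)

  bias <- linear(ps, paste0(name, "/pair_bias"), pair_feats, H, bias = FALSE)
  gamma_raw <- ps_get(ps, paste0(name, "/gamma"), c(1L, H), "zeros")
  gamma <- if (is_tensor(gamma_raw)) ad_unary(gamma_raw, softplus,
                                              function(x, y) 1 / (1 + exp(-x)))
           else softplus(gamma_raw)

  d2_pts <- point_sq_norms(ad_sub(qpg, kpg))  # (N*K) x (H*Pq)
  head_outputs <- vector("list", H)
  for (h in seq_len(H)) {
    sc <- (h - 1L) * dq + seq_len(dq)
    scal <- ad_mul(ad_rowsums(ad_mul(ad_cols(qg, sc), ad_cols(kg, sc))),
                   1 / sqrt(dq))
    ptd <- ad_rowsums(ad_cols(d2_pts, (h - 1L) * Pq + seq_len(Pq)))
    gam_h <- if (is_tensor(gamma)) ad_cols(gamma, h) else gamma[1, h]
    pt_term <- ad_mul(ad_mul(ptd, gam_h), w_c / 2)
    logit <- ad_mul(ad_sub(ad_add(scal, ad_cols(bias, h)), pt_term), w_l)
    probs <- ad_softmax_rows(ad_group_mat(logit, n, k), ctx$valid)
    pf <- ad_flat_col(probs)

    o_scal <- ad_pool_rows(ad_mul(ad_cols(vg, sc), pf), ctx$rep_idx, n)
    o_pair <- ad_pool_rows(ad_mul(pair_feats, pf), ctx$rep_idx, n)
    vc <- (h - 1L) * Pv * 3L + seq_len(Pv * 3L)
    o_pt_g <- ad_pool_rows(ad_mul(ad_cols(vpg, vc), pf), ctx$rep_idx, n)
    o_pt_local <- rot_invapply_points(framesq$rot9, o_pt_g, tq_u)
    norms <- ad_sqrt(ad_add(point_sq_norms(o_pt_local), 1e-8))
    head_outputs[[h]] <- ad_cbind(o_scal, o_pt_local, norms, o_pair)
  }
  concat <- do.call(ad_cbind, head_outputs)
  linear(ps, paste0(name, "/out"), concat, config$local_size, init = "normal")
}

## update module ---------------------------------------------------------------

update_features <- function(ps, name, local, xmat, frames, chain_index, config) {
  n <- nrow(as_mat(val(local)))
  local_coords <- ad_mul(rot_invapply_points(frames$rot9, xmat, frames$trans),
                         0.1)
  inp <- ad_cbind(local, local_coords)
  h <- geglu(ps, paste0(name, "/geglu"), inp,
             config$ff_factor * config$local_size, config$local_size)
  pooled_in <- linear(ps, paste0(name, "/pool_proj"), local, config$local_size)
  chain_ids <- as.integer(factor(chain_index))
  n_chains <- max(chain_ids)
  counts <- tabulate(chain_ids, n_chains)
  chain_mean <- ad_mul(ad_pool_rows(pooled_in, chain_ids, n_chains),
                       matrix(1 / counts, ncol = 1L))
  per_chain <- ad_gather_rows(chain_mean, chain_ids)
  complex_mean <- ad_mul(ad_pool_rows(pooled_in, rep(1L, n), 1L), 1 / n)
  per_complex <- ad_gather_rows(complex_mean, rep(1L, n))
  summed <- ad_add(ad_add(h, per_chain), per_complex)
  linear(ps, paste0(name, "/out"), summed, config$local_size, init = "normal")
}

## equivariant position update -------------------------------------------------

update_positions <- function(ps, name, local, xmat, frames, config) {
  n_atoms <- ncol(as_mat(val(xmat))) / 3L
  # small-normal rather than zero init: with a zero offset projection every
  # gradient path from the features to the coordinates vanishes at
  # initialization, which deadlocks early training; ~1 A of initial jitter
  # keeps the untrained model near-identity while letting gradients flow
  offsets <- linear(ps, paste0(name, "/offsets"), local, n_atoms * 3L,
                    init = "normal")
  delta_local <- ad_mul(offsets, config$position_scale)
  delta_global <- rot_apply_points(frames$rot9, delta_local)
  ad_add(xmat, delta_global)
}

## conditioning pair channels --------------------------------------------------

# invariant extra channels on conditioning/self-conditioning neighbour slots
cond_pair_channels <- function(cond, ctx) {
  chans <- list()
  pair_at <- function(m) m[cbind(ctx$rep_idx, ctx$idxf)]
  if (!is.null(cond$partial_distances)) {
    d <- pair_at(cond$partial_distances$dist)
    v <- pair_at(cond$partial_distances$valid) * 1
    d[!is.finite(d)] <- 0
    chans[[length(chans) + 1L]] <- rbfEncode(pmax(d, 0) * v)
    chans[[length(chans) + 1L]] <- matrix(v, ncol = 1L)
  }
  if (!is.null(cond$motif)) {
    m <- pair_at(cond$motif$mask) * 1
    d <- if (!is.null(cond$motif$dist)) pair_at(cond$motif$dist) else 0 * m
    chans[[length(chans) + 1L]] <- rbfEncode(pmax(d, 0) * m)
    chans[[length(chans) + 1L]] <- matrix(m, ncol = 1L)
  }
  if (length(chans)) do.call(cbind, chans) else NULL
}

# conditioning pair list for the stage-4 neighbour selection
cond_pair_list <- function(cond) {
  pairs <- NULL
  if (!is.null(cond$partial_distances)) {
    w <- which(cond$partial_distances$valid, arr.ind = TRUE)
    pairs <- rbind(pairs, w[w[, 1] < w[, 2], , drop = FALSE])
  }
  if (!is.null(cond$motif)) {
    w <- which(cond$motif$mask, arr.ind = TRUE)
    pairs <- rbind(pairs, w[w[, 1] < w[, 2], , drop = FALSE])
  }
  pairs
}

## embeddings ------------------------------------------------------------------

onehot <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels))
  hit <- match(labels, levels)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

embed_inputs <- function(ps, cond, n, chain_index, time_value, config) {
  feats <- list()
  if (config$time_embedding)
    feats[[length(feats) + 1L]] <- matrix(fourier_time_embedding(time_value),
                                          n, 16L, byrow = TRUE)
  ss <- if (!is.null(cond$ss)) cond$ss else rep(SS_UNKNOWN, n)
  feats[[length(feats) + 1L]] <- onehot(ss, c(SS_STATES, SS_UNKNOWN))
  aa <- if (!is.null(cond$sequence)) cond$sequence else rep(NA_character_, n)
  aa[is.na(aa)] <- "?"
  feats[[length(feats) + 1L]] <- onehot(aa, c(AA_ONE, "?"))
  hot <- if (!is.null(cond$hotspots)) cond$hotspots * 1 else rep(0, n)
  feats[[length(feats) + 1L]] <- matrix(hot, ncol = 1L)
  pos <- unlist(lapply(split(seq_len(n), chain_index), function(ix)
    seq_along(ix)))[order(unlist(split(seq_len(n), chain_index)))]
  rel <- unlist(lapply(split(seq_len(n), chain_index), function(ix)
    seq_along(ix) / length(ix)))[order(unlist(split(seq_len(n), chain_index)))]
  feats[[length(feats) + 1L]] <- matrix(rel, ncol = 1L)
  # sinusoidal positional features of the within-chain residue position
  k <- 0:7
  freq <- 1 / 10000^(k / 8)
  ang <- outer(pos, freq)
  feats[[length(feats) + 1L]] <- cbind(sin(ang), cos(ang))
  linear(ps, "embed/input", do.call(cbind, feats), config$local_size)
}

## denoising block -------------------------------------------------------------

frames_from_xmat <- function(xmat) {
  frames_differentiable(ad_cols(xmat, 1:3), ad_cols(xmat, 4:6),
                        ad_cols(xmat, 7:9))
}

denoising_block <- function(ps, name, local, xmat, cond, selfcond,
                            residue_index, chain_index, config) {
  n <- nrow(as_mat(val(local)))
  ca_now <- val(ad_cols(xmat, 4:6))
  has_cond_ipa <- !is.null(selfcond) || !is.null(cond$partial_distances) ||
    !is.null(cond$motif)
  nbr_cfg <- if (has_cond_ipa) neighbourConfig() else neighbourConfig()
  nbr1 <- selectNeighbours(ca_now, residue_index, chain_index, nbr_cfg)
  ctx1 <- nbr_ctx(nbr1)
  frames <- frames_from_xmat(xmat)

  run_current_ipa <- function(local) {
    ln <- layernorm(ps, paste0(name, "/ln1"), local)
    pair1 <- pair_features(ps, paste0(name, "/pair1"), xmat, xmat, frames,
                           frames, ctx1, config$pair_variant, config$pair_size)
    ad_add(local, sparse_ipa(ps, paste0(name, "/ipa1"), ln, ln, frames, frames,
                             ctx1, pair1, config))
  }

  run_cond_ipa <- function(local) {
    if (!has_cond_ipa) return(local)
    x_prev <- if (!is.null(selfcond)) selfcond$x_prev else val(xmat)
    x_prev <- ad_detach(x_prev)
    cond_pairs <- cond_pair_list(cond)
    nbr2 <- selectNeighbours(x_prev[, 4:6, drop = FALSE], residue_index,
                             chain_index,
                             neighbourConfig(n_random = 16L, n_cond = 16L),
                             cond_pairs = cond_pairs)
    ctx2 <- nbr_ctx(nbr2)
    frames_prev <- frames_from_xmat(x_prev)
    extra <- cond_pair_channels(cond, ctx2)
    ln <- layernorm(ps, paste0(name, "/ln2"), local)
    local_k <- if (!is.null(selfcond) && !is.null(selfcond$local_prev))
      ad_add(ln, linear(ps, paste0(name, "/prev_embed"),
                        ad_detach(selfcond$local_prev), config$local_size))
    else ln
    pair2 <- pair_features(ps, paste0(name, "/pair2"), xmat, x_prev, frames,
                           frames_prev, ctx2, "minimal", config$pair_size,
                           extra = extra)
    ad_add(local, sparse_ipa(ps, paste0(name, "/ipa2"), ln, local_k, frames,
                             frames_prev, ctx2, pair2, config))
  }

  if (config$motif_first) {
    local <- run_cond_ipa(local)
    local <- run_current_ipa(local)
  } else {
    local <- run_current_ipa(local)
    local <- run_cond_ipa(local)
  }

  ln3 <- layernorm(ps, paste0(name, "/ln3"), local)
  local <- ad_add(local, update_features(ps, paste0(name, "/update"), ln3,
                                         xmat, frames, chain_index, config))
  ln4 <- layernorm(ps, paste0(name, "/ln4"), local)
  xmat <- update_positions(ps, paste0(name, "/pos"), ln4, xmat, frames, config)
  list(local = local, xmat = xmat)
}

## the denoising module --------------------------------------------------------

#' Run the denoising network
#'
#' Embeds the noisy structure and conditioning, runs the configured number of
#' denoising blocks (recording the per-block position trajectory) and returns
#' the denoised estimate plus the auxiliary heads.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param x_t an \linkS4class{AugmentedStructure} (the noisy input).
#' @param cond a \code{\link{conditioningBundle}}.
#' @param time diffusion time in [0, 1] (VP family) or a mapped noise level
#'   (VE; see \code{\link{generateBackbone}}).
#' @param seed optional RNG seed making the per-block random neighbour stage
#'   reproducible.
#' @param .tensors internal: return tensors instead of plain values (training).
#' @return list with \code{x0_pred} (\linkS4class{AugmentedStructure}),
#'   \code{trajectory} (list of N x 60 coordinate matrices, one per block),
#'   \code{local}, \code{aa_logits} (N x 20), \code{ss_logits} (N x 3),
#'   \code{distogram} (list with \code{logits} over neighbour pairs and the
#'   neighbour context) and \code{aa_argmax}.
#' @export
denoiseStructure <- function(model, x_t, cond = conditioningBundle(),
                             time = 1, seed = NULL, .tensors = FALSE) {
  if (!all(is.finite(x_t@atoms))) stop("non-finite coordinates in x_t")
  if (!is.null(seed)) return(with_seed(seed, denoiseStructure(
    model, x_t, cond, time, seed = NULL, .tensors = .tensors)))
  ps <- model$ps; config <- model$config
  n <- nResidues(x_t)
  xmat <- flatten_atoms(x_t@atoms)
  local <- embed_inputs(ps, cond, n, x_t@chainIndex, time, config)
  selfcond <- cond$selfcond
  trajectory <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    st <- denoising_block(ps, sprintf("block%d", b), local, xmat, cond,
                          selfcond, x_t@residueIndex, x_t@chainIndex, config)
    local <- st$local
    xmat <- st$xmat
    trajectory[[b]] <- xmat
  }
  ln <- layernorm(ps, "heads/ln", local)
  aa_logits <- linear(ps, "heads/aa", ln, 20L)
  ss_logits <- linear(ps, "heads/ss", ln, 3L)
  # sparse distogram over the final block's neighbour pairs, symmetrized
  ca_fin <- val(ad_cols(xmat, 4:6))
  nbr_d <- selectNeighbours(ca_fin, x_t@residueIndex, x_t@chainIndex,
                            neighbourConfig())
  ctx_d <- nbr_ctx(nbr_d)
  hsym <- linear(ps, "heads/dist_proj", ln, config$local_size %/% 2L)
  hpair <- ad_add(ad_gather_rows(hsym, ctx_d$rep_idx),
                  ad_gather_rows(hsym, ctx_d$idxf))
  dist_logits <- linear(ps, "heads/dist_out", ad_gelu(hpair),
                        config$distogram_bins)
  out <- list(trajectory = trajectory, local = local, aa_logits = aa_logits,
              ss_logits = ss_logits,
              distogram = list(logits = dist_logits, ctx = ctx_d),
              xmat = xmat)
  if (!.tensors) {
    out$trajectory <- lapply(out$trajectory, val)
    out$local <- val(out$local)
    out$aa_logits <- val(out$aa_logits)
    out$ss_logits <- val(out$ss_logits)
    out$distogram$logits <- val(out$distogram$logits)
    out$xmat <- val(out$xmat)
    out$x0_pred <- augmentedStructure(unflatten_atoms(out$xmat, N_AUG_ATOMS),
                                      x_t@residueIndex, x_t@chainIndex)
    out$aa_argmax <- AA_ONE[max.col(out$aa_logits, ties.method = "first")]
  }
  out
}

## encoder ---------------------------------------------------------------------

encoder_block <- function(ps, name, local, xmat, frames, ctx, config,
                          chain_index) {
  ln <- layernorm(ps, paste0(name, "/ln1"), local)
  pair <- pair_features(ps, paste0(name, "/pair"), xmat, xmat, frames, frames,
                        ctx, config$pair_variant, config$pair_size)
  local <- ad_add(local, sparse_ipa(ps, paste0(name, "/ipa"), ln, ln, frames,
                                    frames, ctx, pair, config))
  ln2 <- layernorm(ps, paste0(name, "/ln2"), local)
  ad_add(local, geglu(ps, paste0(name, "/geglu"), ln2,
                      config$ff_factor * config$local_size, config$local_size,
                      out_init = "normal"))
}

#' Encode a backbone into the augmented all-atom representation
#'
#' Adds the idealized CB and 15 learned pseudoatom positions per residue.
#' The pseudoatoms are emitted as local-frame offsets from CA, so encoding is
#' equivariant by construction. Uses a fixed set of nearest-CA neighbours
#' computed once.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param backbone a \linkS4class{BackboneStructure} with at least 2 residues.
#' @param .tensors internal: return the coordinate tensor (training).
#' @return An \linkS4class{AugmentedStructure} (or its N x 60 tensor).
#' @export
encodeStructure <- function(model, backbone, .tensors = FALSE) {
  stopifnot(nResidues(backbone) >= 2L)
  ps <- model$ps; config <- model$config
  n <- nResidues(backbone)
  cb <- idealizeCb(backbone)
  x5 <- cbind(matrix(backbone@coords[, 1, ], ncol = 3),
              matrix(backbone@coords[, 2, ], ncol = 3),
              matrix(backbone@coords[, 3, ], ncol = 3),
              matrix(backbone@coords[, 4, ], ncol = 3), cb)
  frames <- frames_from_xmat(x5)
  nbr <- nearest_ca_neighbours(caCoords(backbone), config$encoder_k)
  ctx <- nbr_ctx(nbr)
  seed_row <- ps_get(ps, "encoder/seed", c(1L, config$local_size), "normal")
  local <- t_row(seed_row, n)
  for (b in seq_len(config$encoder_blocks))
    local <- encoder_block(ps, sprintf("encoder/block%d", b), local, x5,
                           frames, ctx, config, backbone@chainIndex)
  ln <- layernorm(ps, "encoder/ln_out", local)
  offsets <- linear(ps, "encoder/pseudo", ln, config$n_pseudoatoms * 3L,
                    init = "normal")
  pseudo <- rot_apply_points(frames$rot9, offsets, frames$trans)
  xmat <- ad_cbind(x5, pseudo)
  if (.tensors) return(xmat)
  augmentedStructure(unflatten_atoms(val(xmat), N_AUG_ATOMS),
                     backbone@residueIndex, backbone@chainIndex)
}

## amino-acid decoder ----------------------------------------------------------

# fixed 14-slot side-chain atom layout (backbone N/CA/C/O/CB + up to 9
# side-chain slots); slot existence per amino acid drives loss masking
ATOM14_COUNTS <- c(A = 5L, C = 6L, D = 8L, E = 9L, F = 11L, G = 4L, H = 10L,
                   I = 8L, K = 9L, L = 8L, M = 8L, N = 8L, P = 7L, Q = 9L,
                   R = 11L, S = 6L, T = 7L, V = 7L, W = 14L, Y = 12L)

#' Decode amino-acid identities and side-chain atoms
#'
#' Runs three encoder-type blocks over the denoised structure with a fixed
#' nearest-CA neighbour set computed on the denoised CA positions, predicting
#' logits for every residue (conditioned on any unmasked input residues) and
#' all-atom coordinates as local-frame offsets in a fixed 14-slot layout.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param x0 denoised \linkS4class{AugmentedStructure}.
#' @param local per-residue features from \code{\link{denoiseStructure}}.
#' @param masked_seq per-residue one-letter codes with \code{NA} at masked
#'   positions.
#' @param .tensors internal: return tensors (training).
#' @return list with \code{aa_logits} (N x 20), \code{atoms14}
#'   (N x 14 x 3 array) and \code{aa_argmax}.
#' @export
decodeAminoAcids <- function(model, x0, local, masked_seq = NULL,
                             .tensors = FALSE) {
  ps <- model$ps; config <- model$config
  n <- nResidues(x0)
  xmat <- flatten_atoms(x0@atoms)
  if (is_tensor(local)) xmat <- ad_detach(xmat)
  frames <- frames_from_xmat(xmat)
  nbr <- nearest_ca_neighbours(val(ad_cols(xmat, 4:6)), config$encoder_k)
  ctx <- nbr_ctx(nbr)
  if (is.null(masked_seq)) masked_seq <- rep(NA_character_, n)
  aa_in <- masked_seq
  aa_in[is.na(aa_in)] <- "?"
  emb <- linear(ps, "aadec/embed", onehot(aa_in, c(AA_ONE, "?")),
                config$local_size)
  h <- ad_add(linear(ps, "aadec/local_in", local, config$local_size), emb)
  for (b in seq_len(config$decoder_blocks))
    h <- encoder_block(ps, sprintf("aadec/block%d", b), h, xmat, frames, ctx,
                       config, x0@chainIndex)
  ln <- layernorm(ps, "aadec/ln_out", h)
  aa_logits <- linear(ps, "aadec/logits", ln, 20L)
  sc_offsets <- linear(ps, "aadec/atoms", ln, 14L * 3L, init = "normal")
  atoms14 <- rot_apply_points(frames$rot9, sc_offsets, frames$trans)
  if (.tensors)
    return(list(aa_logits = aa_logits, atoms14 = atoms14))
  list(aa_logits = val(aa_logits),
       atoms14 = unflatten_atoms(val(atoms14), 14L),
       aa_argmax = AA_ONE[max.col(val(aa_logits), ties.method = "first")])
}

## vector quantization ---------------------------------------------------------

#' Vector-quantize per-residue latents
#'
#' Each latent is replaced by its nearest codebook entry (Euclidean). The
#' returned quantized value follows the straight-through convention: for
#' tensors its gradient behaves as the identity on \code{z}.
#'
#' @param z N x latent matrix (plain or tensor).
#' @param codebook M x latent matrix (plain or parameter tensor).
#' @return list with \code{quantized}, \code{indices} (1-based) and
#'   \code{codes} (the gathered codebook rows, tensor-aware for codebook
#'   training).
#' @export
vqQuantize <- function(z, codebook) {
  zv <- as_mat(val(z)); cb <- as_mat(val(codebook))
  if (nrow(cb) < 1L) stop("codebook must be non-empty")
  d2 <- outer(rowSums(zv^2), rep(1, nrow(cb))) - 2 * zv %*% t(cb) +
    outer(rep(1, nrow(zv)), rowSums(cb^2))
  indices <- max.col(-d2, ties.method = "first")
  codes <- ad_gather_rows(codebook, indices)
  quantized <- if (is_tensor(z)) ad_add(z, val(codes) - zv) else val(codes)
  list(quantized = quantized, indices = indices, codes = codes)
}

## structure autoencoder -------------------------------------------------------

#' Autoencode a backbone structure
#'
#' Encoder block over fixed nearest-CA neighbours, layer norm and linear
#' projection to a per-residue latent, optional vector quantization, then a
#' multi-block decoder with recycling: each recycle reuses the previous
#' decoded positions, the first starts from standard normal noise. Decoded
#' latents are invariant, so decoded outputs have arbitrary orientation;
#' comparisons are made after superposition.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param backbone a \linkS4class{BackboneStructure} (N >= 16).
#' @param n_recycles recycling steps in 0..3.
#' @param use_vq quantize the latent.
#' @param seed RNG seed for the decoder's initial positions.
#' @param .tensors internal (training).
#' @return list with \code{decoded} (list of \linkS4class{AugmentedStructure}
#'   per recycle), \code{latent}, \code{vq_indices} (or NULL).
#' @export
autoencodeStructure <- function(model, backbone, n_recycles = 0L,
                                use_vq = FALSE, seed = NULL, .tensors = FALSE) {
  stopifnot(nResidues(backbone) >= 16L, n_recycles >= 0L)
  ps <- model$ps; config <- model$config
  n <- nResidues(backbone)
  cb <- idealizeCb(backbone)
  x5 <- cbind(matrix(backbone@coords[, 1, ], ncol = 3),
              matrix(backbone@coords[, 2, ], ncol = 3),
              matrix(backbone@coords[, 3, ], ncol = 3),
              matrix(backbone@coords[, 4, ], ncol = 3), cb)
  frames <- frames_from_xmat(x5)
  nbr <- nearest_ca_neighbours(caCoords(backbone), config$encoder_k)
  ctx <- nbr_ctx(nbr)
  seed_row <- ps_get(ps, "ae/seed", c(1L, config$local_size), "normal")
  local <- t_row(seed_row, n)
  local <- encoder_block(ps, "ae/enc", local, x5, frames, ctx, config,
                         backbone@chainIndex)
  z <- linear(ps, "ae/latent", layernorm(ps, "ae/ln_latent", local),
              config$latent_size)
  vq <- NULL
  if (use_vq) {
    codebook <- ps_get(ps, "ae/codebook", c(config$vq_codebook,
                                            config$latent_size), "normal")
    vq <- vqQuantize(z, codebook)
    z <- vq$quantized
  }
  local_dec0 <- linear(ps, "ae/dec_in", z, config$local_size)
  results <- vector("list", n_recycles + 1L)
  xmat <- with_seed(seed, matrix(stats::rnorm(n * N_AUG_ATOMS * 3L), n,
                                 N_AUG_ATOMS * 3L))
  for (r in seq_len(n_recycles + 1L)) {
    local_dec <- local_dec0
    if (r > 1L) xmat <- ad_detach(xmat)
    for (b in seq_len(config$ae_decoder_blocks)) {
      st <- denoising_block(ps, sprintf("ae/dec%d", b), local_dec, xmat,
                            conditioningBundle(), NULL,
                            backbone@residueIndex, backbone@chainIndex, config)
      local_dec <- st$local
      xmat <- st$xmat
    }
    results[[r]] <- xmat
  }
  out <- list(latent = if (.tensors) z else val(z),
              vq_indices = vq$indices,
              vq = vq,
              local = if (.tensors) local_dec else NULL)
  out$decoded <- if (.tensors) results else
    lapply(results, function(m) augmentedStructure(
      unflatten_atoms(val(m), N_AUG_ATOMS),
      backbone@residueIndex, backbone@chainIndex))
  out
}
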