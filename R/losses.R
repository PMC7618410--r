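## Training losses: clipped trajectory/atom denoising losses, rotation loss,
## neighbour-restricted squared FAPE, a simplified structural violation loss,
## cross-entropy auxiliary losses and the weighted combinations for the
## denoiser and the autoencoder. All terms are tensor-aware, so the same
## functions serve unit tests (plain numbers in, numbers out) and training.

CLIP_DIST <- 10  # A; all structural losses clip distances here

# select one column per row (cross-entropy gather)
ad_rowselect <- function(a, idx) {
  idx <- as.integer(idx)
  if (!is_tensor(a)) return(matrix(as_mat(a)[cbind(seq_along(idx), idx)], ncol = 1L))
  va <- val(a)
  mk_node(matrix(va[cbind(seq_along(idx), idx)], ncol = 1L), list(a), function(g) {
    acc <- matrix(0, nrow(va), ncol(va))
    acc[cbind(seq_along(idx), idx)] <- g
    list(acc)
  })
}

# mean cross-entropy of row-logits against integer targets; optional row mask
cross_entropy <- function(logits, target_idx, mask = NULL) {
  v <- as_mat(val(logits))
  shift <- apply(v, 1, max)
  z <- ad_sub(logits, matrix(shift, ncol = 1L))
  lse <- ad_add(ad_log(ad_rowsums(ad_exp(z))), matrix(shift, ncol = 1L))
  nll <- ad_sub(lse, ad_rowselect(logits, target_idx))
  if (!is.null(mask)) {
    m <- matrix(as.numeric(mask), ncol = 1L)
    if (sum(m) == 0) return(matrix(0, 1L, 1L))
    ad_mul(ad_sum(ad_mul(nll, m)), 1 / sum(m))
  } else {
    ad_mean(nll)
  }
}

# per-atom clipped squared distance loss, mean over rows and atoms
clipped_sq_dist <- function(pred, gt, n_atoms) {
  d <- ad_sqrt(ad_add(point_sq_norms(ad_sub(pred, gt)), 1e-12))
  ad_mul(ad_sum(ad_clip(d, 0, CLIP_DIST)^2),
         1 / (nrow(as_mat(val(pred))) * n_atoms))
}

#' Trajectory denoising loss
#'
#' Per-block loss: mean over residues and all 20 (pseudo)atom slots of the
#' squared distance to the target, with distances clipped at 10 A before
#' squaring. Blocks are combined as \code{2 * L_n + mean_b(L_b)}, weighting
#' the final prediction by 2.
#'
#' @param trajectory list of per-block N x 60 coordinate matrices (or
#'   \linkS4class{AugmentedStructure}s).
#' @param x_gt target coordinates, same layout.
#' @return list with \code{l_traj} and \code{per_block} (numeric when inputs
#'   are plain).
#' @export
denoisingLosses <- function(trajectory, x_gt) {
  as_xmat <- function(x) if (is(x, "AugmentedStructure")) flatten_atoms(x@atoms) else x
  x_gt <- as_xmat(x_gt)
  n_atoms <- ncol(as_mat(val(x_gt))) / 3L
  blocks <- lapply(trajectory, function(b) clipped_sq_dist(as_xmat(b), x_gt, n_atoms))
  n <- length(blocks)
  acc <- ad_mul(blocks[[n]], 2)
  for (b in blocks) acc <- ad_add(acc, ad_mul(b, 1 / n))
  l_traj <- acc
  if (!is_tensor(l_traj))
    return(list(l_traj = as.numeric(l_traj),
                per_block = vapply(blocks, function(b) as.numeric(val(b)),
                                   numeric(1))))
  list(l_traj = l_traj, per_block = blocks)
}

#' All-atom denoising loss
#'
#' Clipped squared distance between the predicted and ground-truth all-atom
#' (atom14) structures, averaged over the atoms that exist for each residue's
#' amino acid.
#'
#' @param pred14,gt14 N x 42 coordinate matrices (14 atom slots) or
#'   N x 14 x 3 arrays.
#' @param atom_counts number of existing atom slots per residue.
#' @return the loss (numeric for plain inputs).
#' @export
atomLoss <- function(pred14, gt14, atom_counts) {
  as_xmat <- function(x) if (length(dim(val(x))) == 3L) flatten_atoms(val(x)) else x
  pred14 <- as_xmat(pred14); gt14 <- as_xmat(gt14)
  n <- nrow(as_mat(val(pred14)))
  d <- ad_sqrt(ad_add(point_sq_norms(ad_sub(pred14, gt14)), 1e-12))
  exist <- outer(atom_counts, seq_len(14L), ">=") * 1
  per_res <- ad_rowsums(ad_mul(ad_clip(d, 0, CLIP_DIST)^2, exist))
  per_res <- ad_div(per_res, matrix(pmax(atom_counts, 1L), ncol = 1L))
  out <- ad_mul(ad_sum(per_res), 1 / n)
  if (!is_tensor(out)) as.numeric(out) else out
}

# squared Frobenius deviation of R_pred^T R_gt from the identity, per residue
rot_deviation <- function(rot9_pred, rot9_gt) {
  rel <- rot_relative(rot9_pred, rot9_gt)
  id9 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = nrow(as_mat(val(rel)))),
                ncol = 9L)
  diff <- ad_sub(rel, id9)
  ad_rowsums(ad_mul(diff, diff))
}

#' Rotation denoising loss
#'
#' Per block: mean over residues of the squared Frobenius norm of
#' \code{R_r^T R_r_gt - I}; blocks combined as \code{2 * L_n + mean_b(L_b)}.
#'
#' @param frames_traj list of per-block frame lists (\code{rot9} N x 9) or
#'   \linkS4class{FrameSet}s.
#' @param frames_gt ground-truth frames.
#' @return the combined loss (numeric for plain inputs).
#' @export
rotationLosses <- function(frames_traj, frames_gt) {
  as_rot9 <- function(f) {
    if (is(f, "FrameSet")) {
      n <- dim(f@rotations)[1]
      out <- matrix(0, n, 9L)
      for (j in 1:3) for (i in 1:3) out[, (j - 1L) * 3L + i] <- f@rotations[, i, j]
      out
    } else f$rot9
  }
  gt <- as_rot9(frames_gt)
  blocks <- lapply(frames_traj, function(f) ad_mean(rot_deviation(as_rot9(f), gt)))
  n <- length(blocks)
  acc <- ad_mul(blocks[[n]], 2)
  for (b in blocks) acc <- ad_add(acc, ad_mul(b, 1 / n))
  if (!is_tensor(acc)) as.numeric(acc) else acc
}

# FAPE over (i, j) pairs: prediction errors expressed in per-residue frames,
# clipped then squared
fape_pairs <- function(xmat_pred, frames_pred, xmat_gt, frames_gt,
                       i_list, j_list, n_atoms) {
  rot_p <- ad_gather_rows(frames_pred$rot9, i_list)
  tr_p <- ad_gather_rows(frames_pred$trans, i_list)
  rot_g <- frames_gt$rot9[i_list, , drop = FALSE]
  tr_g <- frames_gt$trans[i_list, , drop = FALSE]
  cols <- seq_len(3L * n_atoms)
  lp <- rot_invapply_points(rot_p,
                            ad_gather_rows(ad_cols(xmat_pred, cols), j_list),
                            tr_p)
  lg <- rot_invapply_points(rot_g, xmat_gt[j_list, cols, drop = FALSE], tr_g)
  d <- ad_sqrt(ad_add(point_sq_norms(ad_sub(lp, lg)), 1e-12))
  ad_mul(ad_sum(ad_clip(d, 0, CLIP_DIST)^2), 1 / (length(i_list) * n_atoms))
}

#' Neighbour-restricted squared FAPE losses
#'
#' \code{l_fape}: squared FAPE of each trajectory block against the target,
#' restricted to the 64 nearest neighbours in the ground-truth structure,
#' averaged over blocks with the final block weighted by 2. \code{l_local}:
#' squared FAPE of the predicted all-atom (atom14) structure over the 16
#' nearest ground-truth neighbours. Distances are clipped at 10 A.
#'
#' @param trajectory list of per-block N x 60 matrices.
#' @param x_gt target N x 60 matrix (or \linkS4class{AugmentedStructure}).
#' @param gt_backbone the ground-truth \linkS4class{BackboneStructure}
#'   (frames and neighbour sets are computed from it).
#' @param allatom_pred optional N x 42 predicted atom14 matrix for
#'   \code{l_local}.
#' @param gt14 optional target atom14 matrix.
#' @param atom_counts existing-atom counts for the atom14 mask.
#' @param n_fape,n_local neighbour counts (64 and 16).
#' @return list with \code{l_fape} and \code{l_local} (numeric when plain).
#' @export
fapeLosses <- function(trajectory, x_gt, gt_backbone, allatom_pred = NULL,
                       gt14 = NULL, atom_counts = NULL,
                       n_fape = 64L, n_local = 16L) {
  if (is(x_gt, "AugmentedStructure")) x_gt <- flatten_atoms(x_gt@atoms)
  x_gt <- val(x_gt)
  frames_gt_set <- buildFrames(gt_backbone)
  n <- nrow(x_gt)
  rot9_gt <- matrix(0, n, 9L)
  for (j in 1:3) for (i in 1:3)
    rot9_gt[, (j - 1L) * 3L + i] <- frames_gt_set@rotations[, i, j]
  frames_gt <- list(rot9 = rot9_gt, trans = frames_gt_set@translations)
  ca_gt <- caCoords(gt_backbone)
  pair_list <- function(k) {
    nbr <- nearest_ca_neighbours(ca_gt, k)
    ctx <- nbr_ctx(nbr)
    keep <- as.vector(ctx$maskf) > 0
    list(i = ctx$rep_idx[keep], j = ctx$idxf[keep])
  }
  p64 <- pair_list(n_fape)
  n_atoms <- ncol(as_mat(val(trajectory[[1]]))) / 3L
  blocks <- lapply(trajectory, function(b) {
    fp <- frames_from_xmat(b)
    fape_pairs(b, fp, x_gt, frames_gt, p64$i, p64$j, n_atoms)
  })
  nb <- length(blocks)
  l_fape <- ad_mul(blocks[[nb]], 2)
  for (b in blocks) l_fape <- ad_add(l_fape, ad_mul(b, 1 / nb))

  l_local <- matrix(0, 1L, 1L)
  if (!is.null(allatom_pred)) {
    p16 <- pair_list(n_local)
    fp <- frames_from_xmat(allatom_pred)  # atom14 shares the backbone layout
    # mask pairs whose target atom slot does not exist: restrict atoms to the
    # minimum count over residues for simplicity of the pair expansion
    n_at <- 5L
    l_local <- fape_pairs(allatom_pred, fp, val(gt14), frames_gt,
                          p16$i, p16$j, n_at)
  }
  if (!is_tensor(l_fape) && !is_tensor(l_local))
    return(list(l_fape = as.numeric(val(l_fape)),
                l_local = as.numeric(val(l_local))))
  list(l_fape = l_fape, l_local = l_local)
}

# literature van-der-Waals radii for the 5 physical backbone atoms
VDW_RADII <- c(N = 1.55, CA = 1.7, C = 1.7, O = 1.52, CB = 1.7)
IDEAL_BONDS <- list(c_n = 1.329, c_n_tol = 0.02, ca_c_n = 116.2, c_n_ca = 121.7,
                    angle_tol = 1.5)

#' Simplified structural violation loss
#'
#' Bonded terms: flat-bottomed (12 sigma) penalties on consecutive C-N bond
#' lengths and the CA-C-N / C-N-CA angles against ideal values. Non-bonded
#' term: pairwise clash penalty for atoms of non-adjacent residues closer
#' than the sum of van-der-Waals radii minus a 1.5 A tolerance.
#'
#' @param xmat N x (3A) coordinate matrix with the N/CA/C/O(/CB) layout, or a
#'   \linkS4class{BackboneStructure} / \linkS4class{AugmentedStructure}.
#' @param chain_index per-residue chain ids (bond terms skip chain breaks).
#' @return the loss (numeric for plain input).
#' @export
violationLoss <- function(xmat, chain_index = NULL) {
  if (is(xmat, "BackboneStructure")) {
    chain_index <- chainIndex(xmat)
    xmat <- cbind(matrix(xmat@coords[, 1, ], ncol = 3),
                  matrix(xmat@coords[, 2, ], ncol = 3),
                  matrix(xmat@coords[, 3, ], ncol = 3),
                  matrix(xmat@coords[, 4, ], ncol = 3))
  } else if (is(xmat, "AugmentedStructure")) {
    chain_index <- chainIndex(xmat)
    xmat <- flatten_atoms(xmat@atoms)
  }
  n <- nrow(as_mat(val(xmat)))
  if (is.null(chain_index)) chain_index <- rep(1L, n)
  n_atoms <- min(ncol(as_mat(val(xmat))) / 3L, 5L)
  if (n < 2L) return(0)

  bonded_pairs <- which(chain_index[-n] == chain_index[-1])
  flat <- function(x, ideal, tol) {
    dev <- ad_pmax(abs(ad_sub(x, ideal)), 12 * tol)
    ad_sub(dev, 12 * tol)
  }
  terms <- NULL
  add_term <- function(t) terms <<- if (is.null(terms)) t else ad_add(terms, t)
  if (length(bonded_pairs)) {
    Ci <- ad_gather_rows(ad_cols(xmat, 7:9), bonded_pairs)
    Ni1 <- ad_gather_rows(ad_cols(xmat, 1:3), bonded_pairs + 1L)
    CAi <- ad_gather_rows(ad_cols(xmat, 4:6), bonded_pairs)
    CAi1 <- ad_gather_rows(ad_cols(xmat, 4:6), bonded_pairs + 1L)
    dCN <- ad_sqrt(ad_add(v3_dot(ad_sub(Ci, Ni1), ad_sub(Ci, Ni1)), 1e-12))
    add_term(ad_mean(flat(dCN, IDEAL_BONDS$c_n, IDEAL_BONDS$c_n_tol)^2))
    angle_of <- function(a, b, c) {
      u <- ad_sub(a, b); v <- ad_sub(c, b)
      cosv <- ad_div(v3_dot(u, v),
                     ad_sqrt(ad_add(ad_mul(v3_dot(u, u), v3_dot(v, v)), 1e-12)))
      ad_unary(ad_clip(cosv, -0.9999, 0.9999), function(x) acos(x) * 180 / pi,
               function(x, y) -(180 / pi) / sqrt(1 - x^2))
    }
    add_term(ad_mean(flat(angle_of(CAi, Ci, Ni1), IDEAL_BONDS$ca_c_n,
                          IDEAL_BONDS$angle_tol)^2) * 0.01)
    add_term(ad_mean(flat(angle_of(Ci, Ni1, CAi1), IDEAL_BONDS$c_n_ca,
                          IDEAL_BONDS$angle_tol)^2) * 0.01)
  }
  # clash term over non-adjacent residue pairs, vectorized over atom pairs
  pair_idx <- which(outer(seq_len(n), seq_len(n),
                          function(i, j) j > i + 1L), arr.ind = TRUE)
  if (nrow(pair_idx)) {
    radii <- VDW_RADII[seq_len(n_atoms)]
    idx_a <- unlist(lapply(seq_len(n_atoms), function(a)
      rep.int((3L * a - 2L):(3L * a), n_atoms)))
    idx_b <- rep(unlist(lapply(seq_len(n_atoms), function(b)
      (3L * b - 2L):(3L * b))), times = n_atoms)
    pa <- ad_gather_rows(ad_cols(xmat, idx_a), pair_idx[, 1])
    pb <- ad_gather_rows(ad_cols(xmat, idx_b), pair_idx[, 2])
    d <- ad_sqrt(ad_add(point_sq_norms(ad_sub(pa, pb)), 1e-12))
    rad_sum <- as.vector(vapply(seq_len(n_atoms), function(a)
      radii[a] + radii, numeric(n_atoms)))
    target <- matrix(rad_sum - 1.5, nrow(pair_idx), n_atoms^2, byrow = TRUE)
    pen <- ad_pmax(ad_sub(target, d), 0)
    add_term(ad_mean(pen^2))
  }
  out <- terms
  if (!is_tensor(out)) as.numeric(val(out)) else out
}

DISTOGRAM_MIN <- 2
DISTOGRAM_MAX <- 22

distogram_bin <- function(d, n_bins) {
  pmin(pmax(floor((d - DISTOGRAM_MIN) / ((DISTOGRAM_MAX - DISTOGRAM_MIN) / n_bins)) + 1L,
            1L), n_bins)
}

#' Auxiliary (non-coordinate) losses
#'
#' Cross-entropies of the amino-acid (20-way), secondary-structure (3-way)
#' and distogram heads, combined as
#' \code{l_aux = 10 * l_aa + l_dssp + 0.1 * l_dist}.
#'
#' @param aa_logits N x 20 logits; \code{gt_seq} one-letter codes.
#' @param ss_logits N x 3 logits; \code{gt_ss} H/E/L labels.
#' @param dist_logits pair x bins logits; \code{gt_dist} pair distances in A.
#' @param gt_seq,gt_ss,gt_dist targets (any may be NULL to skip the term).
#' @return list with \code{l_aa}, \code{l_dssp}, \code{l_dist}, \code{l_aux}.
#' @export
auxLosses <- function(aa_logits = NULL, ss_logits = NULL, dist_logits = NULL,
                      gt_seq = NULL, gt_ss = NULL, gt_dist = NULL) {
  zero <- matrix(0, 1L, 1L)
  l_aa <- if (!is.null(aa_logits) && !is.null(gt_seq)) {
    idx <- match(gt_seq, AA_ONE)
    cross_entropy(aa_logits, ifelse(is.na(idx), 1L, idx), mask = !is.na(idx))
  } else zero
  l_dssp <- if (!is.null(ss_logits) && !is.null(gt_ss)) {
    cross_entropy(ss_logits, match(gt_ss, SS_STATES))
  } else zero
  l_dist <- if (!is.null(dist_logits) && !is.null(gt_dist)) {
    n_bins <- ncol(as_mat(val(dist_logits)))
    ok <- !is.na(gt_dist)
    bins <- distogram_bin(ifelse(ok, gt_dist, DISTOGRAM_MIN), n_bins)
    cross_entropy(dist_logits, bins, mask = ok)
  } else zero
  l_aux <- ad_add(ad_add(ad_mul(l_aa, 10), l_dssp), ad_mul(l_dist, 0.1))
  out <- list(l_aa = l_aa, l_dssp = l_dssp, l_dist = l_dist, l_aux = l_aux)
  if (!is_tensor(l_aux)) lapply(out, function(x) as.numeric(val(x))) else out
}

#' Combined denoising-model loss
#'
#' The weighted sum
#' \code{l_traj + l_atom + l_fape + l_rot + 10 * l_local + 10 * l_aa +
#' 0.1 * l_viol + l_aux}, where \code{l_aa} is the AADecoder cross-entropy
#' (masked positions) and the auxiliary bundle carries the denoiser head's
#' own 10-weighted amino-acid term. In the high-noise regime (t > 0.5 for VP
#' models, sigma > 5 A for VE models) \code{l_viol} and \code{l_local}
#' contribute zero.
#'
#' @param parts named list with l_traj, l_atom, l_fape, l_rot, l_local,
#'   l_aa (decoder), l_viol, l_aux (missing entries default to 0).
#' @param noise_level diffusion time t (VP family) or sigma in A (VE).
#' @param kind \code{"VP"}, \code{"VP_scaled"} or \code{"VE"}.
#' @return list of class \code{"LossBreakdown"}: all parts plus \code{total}.
#' @export
totalLoss <- function(parts, noise_level = 0, kind = c("VP", "VP_scaled", "VE")) {
  kind <- match.arg(kind)
  zero <- matrix(0, 1L, 1L)
  g <- function(nm) if (is.null(parts[[nm]])) zero else parts[[nm]]
  high_noise <- if (kind == "VE") noise_level > 5.0 else noise_level > 0.5
  l_local <- if (high_noise) zero else g("l_local")
  l_viol <- if (high_noise) zero else g("l_viol")
  total <- ad_add(ad_add(ad_add(g("l_traj"), g("l_atom")),
                         ad_add(g("l_fape"), g("l_rot"))),
                  ad_add(ad_add(ad_mul(l_local, 10), ad_mul(g("l_aa"), 10)),
                         ad_add(ad_mul(l_viol, 0.1), g("l_aux"))))
  out <- list(l_traj = g("l_traj"), l_atom = g("l_atom"), l_fape = g("l_fape"),
              l_rot = g("l_rot"), l_local = l_local, l_aa = g("l_aa"),
              l_viol = l_viol, l_aux = g("l_aux"), total = total)
  if (!is_tensor(total)) {
    out <- lapply(out, function(x) as.numeric(val(x)))
    class(out) <- "LossBreakdown"
  }
  out
}

#' Combined autoencoder loss
#'
#' \code{l_fape + l_local + l_dist + 10 * l_aa}, plus the vector-quantization
#' codebook and commitment (weight 0.25) terms when VQ is enabled.
#'
#' @param parts named list with l_fape, l_local, l_dist, l_aa and optionally
#'   l_vq_codebook, l_vq_commit.
#' @return list with the parts and \code{total}.
#' @export
autoencoderLoss <- function(parts) {
  zero <- matrix(0, 1L, 1L)
  g <- function(nm) if (is.null(parts[[nm]])) zero else parts[[nm]]
  total <- ad_add(ad_add(g("l_fape"), g("l_local")),
                  ad_add(g("l_dist"), ad_mul(g("l_aa"), 10)))
  total <- ad_add(total, ad_add(g("l_vq_codebook"), ad_mul(g("l_vq_commit"), 0.25)))
  out <- c(parts, list(total = total))
  if (!is_tensor(total)) lapply(out, function(x) as.numeric(val(x))) else out
}

#' @export
print.LossBreakdown <- function(x, ...) {
  cat("LossBreakdown:\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %.5f\n", nm, x[[nm]]))
  invisible(x)
}
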