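## Output-editing implementations: point-group (cyclic) and screw-symmetry
## symmetrization, rigid motif replacement, and multi-state coupling, plus
## the corresponding sampler hook constructors.

#' Symmetry specification
#'
#' The symmetry axis is fixed to z. Cyclic groups rotate consecutive subunits
#' by 360/n degrees; screw symmetries combine a rotation by \code{angle} with
#' a translation \code{translation} along the axis.
#'
#' @param group \code{"cyclic"} or \code{"screw"}.
#' @param n_subunits number of repeat subunits (>= 2).
#' @param radius optional subunit centre-of-mass distance from the axis (A).
#' @param angle screw rotation per subunit in degrees (cyclic: fixed to
#'   360/n).
#' @param translation screw translation per subunit along z (A).
#' @return a classed list.
#' @export
symmetrySpec <- function(group = c("cyclic", "screw"), n_subunits = 3L,
                         radius = NULL, angle = NULL, translation = NULL) {
  group <- match.arg(group)
  stopifnot(n_subunits >= 2L)
  if (group == "cyclic") angle <- 360 / n_subunits
  if (group == "screw") {
    if (is.null(angle) || is.null(translation))
      stop("screw symmetry requires angle and translation")
  } else translation <- 0
  structure(list(group = group, n_subunits = as.integer(n_subunits),
                 radius = radius, angle = angle, translation = translation),
            class = "SymmetrySpec")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# apply group element k (0-based) forward / inverse to an m x 3 matrix
sym_forward <- function(pts, spec, k) {
  out <- pts %*% t(rot_z(k * spec$angle))
  out[, 3] <- out[, 3] + k * spec$translation
  out
}

sym_inverse <- function(pts, spec, k) {
  pts[, 3] <- pts[, 3] - k * spec$translation
  pts %*% t(rot_z(-k * spec$angle))
}

#' Symmetrize a structure under a cyclic or screw group
#'
#' Each subunit is mapped onto subunit 0 by the inverse group action, the
#' mapped subunits are averaged atomwise into a representative, the
#' representative's centre of mass is optionally projected to the specified
#' radius from the axis, and the representative is replicated by the forward
#' action. Cyclic inputs are re-centred so the axis passes through the
#' complex xy-centroid; screw inputs are taken in the given axis frame.
#'
#' @param x an \linkS4class{AugmentedStructure} (total length divisible by
#'   \code{n_subunits}).
#' @param spec a \code{\link{symmetrySpec}}.
#' @return The symmetrized \linkS4class{AugmentedStructure}.
#' @export
symmetrize <- function(x, spec) {
  n <- nResidues(x)
  if (n %% spec$n_subunits != 0L)
    stop("total length is not divisible by the number of subunits")
  l_sub <- n %/% spec$n_subunits
  flat <- flatten_atoms(x@atoms)
  if (spec$group == "cyclic") {
    ctr <- colMeans(caCoords(x))
    for (a in seq_len(N_AUG_ATOMS)) {
      cols <- (3 * a - 2):(3 * a)
      flat[, cols[1]] <- flat[, cols[1]] - ctr[1]
      flat[, cols[2]] <- flat[, cols[2]] - ctr[2]
    }
  }
  as_points <- function(block) {
    # rows l_sub, 20 atoms x 3 -> (l_sub*20) x 3
    matrix(t(block), ncol = 3L, byrow = TRUE)
  }
  from_points <- function(pts, rows) {
    matrix(t(pts), nrow = rows, byrow = TRUE)
  }
  mapped <- 0
  for (k in seq_len(spec$n_subunits) - 1L) {
    rows <- k * l_sub + seq_len(l_sub)
    pts <- as_points(flat[rows, , drop = FALSE])
    mapped <- mapped + sym_inverse(pts, spec, k)
  }
  rep_pts <- mapped / spec$n_subunits
  if (!is.null(spec$radius)) {
    com <- colMeans(rep_pts)
    r_now <- sqrt(com[1]^2 + com[2]^2)
    dir <- if (r_now < 1e-9) c(1, 0) else c(com[1], com[2]) / r_now
    shift <- c(dir * (spec$radius - r_now), 0)
    rep_pts <- sweep(rep_pts, 2, -shift)
  }
  out <- flat
  for (k in seq_len(spec$n_subunits) - 1L) {
    rows <- k * l_sub + seq_len(l_sub)
    out[rows, ] <- from_points(sym_forward(rep_pts, spec, k), l_sub)
  }
  augmentedStructure(unflatten_atoms(out, N_AUG_ATOMS), x@residueIndex,
                     x@chainIndex)
}

#' Sampler hooks enforcing a symmetry
#'
#' The output hook symmetrizes the denoised structure; the input hook
#' (optional) replicates subunit 0's noise to all subunits by the forward
#' group action, so corresponding residues see identical inputs.
#'
#' @param spec a \code{\link{symmetrySpec}}.
#' @param symmetrize_input replicate the representative's noise (default
#'   TRUE).
#' @return an \code{\link{editHooks}}.
#' @export
symmetryHooks <- function(spec, symmetrize_input = TRUE) {
  replicate_input <- function(x, step, t) {
    n <- nResidues(x)
    l_sub <- n %/% spec$n_subunits
    flat <- flatten_atoms(x@atoms)
    rep_pts <- matrix(t(flat[seq_len(l_sub), , drop = FALSE]), ncol = 3L,
                      byrow = TRUE)
    for (k in seq_len(spec$n_subunits - 1L)) {
      rows <- k * l_sub + seq_len(l_sub)
      flat[rows, ] <- matrix(t(sym_forward(rep_pts, spec, k)), nrow = l_sub,
                             byrow = TRUE)
    }
    augmentedStructure(unflatten_atoms(flat, N_AUG_ATOMS), x@residueIndex,
                       x@chainIndex)
  }
  editHooks(
    edit_input = if (symmetrize_input) replicate_input else NULL,
    edit_output = function(x, step, t) symmetrize(x, spec)
  )
}

#' Motif placement
#'
#' @param motif_coords m x 4 x 3 array of the motif's N/CA/C/O coordinates
#'   (or a \linkS4class{BackboneStructure}).
#' @param target_residues strictly increasing residue positions in the
#'   scaffold.
#' @param group_id placements sharing a group id are fitted as one rigid
#'   body.
#' @return a classed list.
#' @export
motifPlacement <- function(motif_coords, target_residues, group_id = 1L) {
  if (is(motif_coords, "BackboneStructure")) motif_coords <- motif_coords@coords
  target_residues <- as.integer(target_residues)
  if (any(diff(target_residues) <= 0))
    stop("target_residues must be strictly increasing")
  if (dim(motif_coords)[1] != length(target_residues))
    stop("motif length does not match the number of target residues")
  structure(list(coords = motif_coords, target = target_residues,
                 group = group_id), class = "MotifPlacement")
}

#' Replace scaffold coordinates by aligned motif coordinates
#'
#' Per rigid group, the motif backbone (N/CA/C/O) is superposed onto the
#' current coordinates of its target residues and the target backbone slots
#' are overwritten by the transformed motif; CB and pseudoatom slots are
#' left untouched.
#'
#' @param x an \linkS4class{AugmentedStructure}.
#' @param placements list of \code{\link{motifPlacement}}s (non-overlapping).
#' @return The edited \linkS4class{AugmentedStructure}.
#' @export
motifReplace <- function(x, placements) {
  if (is(placements, "MotifPlacement")) placements <- list(placements)
  all_targets <- unlist(lapply(placements, `[[`, "target"))
  if (anyDuplicated(all_targets)) stop("motif placements overlap")
  at <- x@atoms
  groups <- split(placements, vapply(placements, `[[`, numeric(1), "group"))
  for (grp in groups) {
    motif_pts <- do.call(rbind, lapply(grp, function(p)
      matrix(aperm(p$coords, c(2, 1, 3)), ncol = 3L)))
    current_pts <- do.call(rbind, lapply(grp, function(p)
      matrix(aperm(at[p$target, 1:4, , drop = FALSE], c(2, 1, 3)), ncol = 3L)))
    tr <- superpose(motif_pts, current_pts)
    moved <- apply_transform(motif_pts, tr)
    at_row <- 0L
    for (p in grp) {
      m <- length(p$target)
      block <- moved[at_row + seq_len(4L * m), , drop = FALSE]
      arr <- array(block, c(4L, m, 3L))
      for (a in 1:4) at[p$target, a, ] <- arr[a, , ]
      at_row <- at_row + 4L * m
    }
  }
  augmentedStructure(at, x@residueIndex, x@chainIndex)
}

#' Sampler hooks enforcing motif placements
#'
#' @param placements list of \code{\link{motifPlacement}}s.
#' @return an \code{\link{editHooks}} whose output hook applies
#'   \code{\link{motifReplace}}.
#' @export
motifHooks <- function(placements) {
  editHooks(edit_output = function(x, step, t) motifReplace(x, placements))
}

#' Couple shared substructures across denoising states
#'
#' For each shared residue set, the states' substructures are superposed into
#' a common frame, combined (atomwise average, or the first state's copy),
#' and the consensus is transformed back into each state's frame, overwriting
#' the shared residues' backbone slots. After coupling, the shared
#' substructures of all states superpose exactly.
#'
#' @param states list (>= 2) of \linkS4class{AugmentedStructure}s.
#' @param shared list of shared sets; each a list of per-state residue index
#'   vectors of equal length >= 3.
#' @param mode \code{"average"} or \code{"copy_first"}.
#' @return The list of edited states.
#' @export
coupleStates <- function(states, shared, mode = c("average", "copy_first")) {
  mode <- match.arg(mode)
  if (length(states) < 2L) stop("multi-state coupling requires >= 2 states")
  n_states <- length(states)
  atoms <- lapply(states, function(s) s@atoms)
  for (set in shared) {
    if (length(set) != n_states)
      stop("each shared set must name residues in every state")
    m <- length(set[[1]])
    if (m < 3L) stop("shared sets of fewer than 3 residues are underdetermined")
    pts <- lapply(seq_len(n_states), function(s) {
      idx <- set[[s]]
      matrix(aperm(atoms[[s]][idx, 1:4, , drop = FALSE], c(2, 1, 3)), ncol = 3L)
    })
    # transform every state's substructure into state 1's frame
    fits <- lapply(seq_len(n_states), function(s) {
      if (s == 1L) list(rotation = diag(3), translation = c(0, 0, 0))
      else superpose(pts[[s]], pts[[1]])
    })
    aligned <- lapply(seq_len(n_states), function(s)
      apply_transform(pts[[s]], fits[[s]]))
    consensus <- if (mode == "copy_first") aligned[[1]] else
      Reduce(`+`, aligned) / n_states
    for (s in seq_len(n_states)) {
      inv <- list(rotation = t(fits[[s]]$rotation),
                  translation = -as.vector(t(fits[[s]]$rotation) %*%
                                             fits[[s]]$translation))
      back <- apply_transform(consensus, inv)
      arr <- array(back, c(4L, m, 3L))
      for (a in 1:4) atoms[[s]][set[[s]], a, ] <- arr[a, , ]
    }
  }
  lapply(seq_len(n_states), function(s)
    augmentedStructure(atoms[[s]], states[[s]]@residueIndex,
                       states[[s]]@chainIndex))
}

#' Generate coupled multi-state backbones
#'
#' Runs one denoising process per state in lockstep, applying
#' \code{\link{coupleStates}} to the denoised outputs at every step so the
#' shared substructures agree across states in the final structures.
#'
#' @param model a \code{\link{denoiserModel}} or model function.
#' @param lengths per-state chain lengths.
#' @param shared shared sets as in \code{\link{coupleStates}}.
#' @param config a \code{\link{samplerConfig}}.
#' @param conds optional list of per-state \code{\link{conditioningBundle}}s.
#' @param mode consensus mode.
#' @return list of per-state results as in \code{\link{generateBackbone}}.
#' @export
generateMultiState <- function(model, lengths, shared,
                               config = samplerConfig(),
                               conds = NULL, mode = "average") {
  n_states <- length(lengths)
  if (is.null(conds)) conds <- rep(list(conditioningBundle()), n_states)
  kind <- config$schedule_kind
  with_seed(config$seed, {
    xs <- lapply(lengths, function(L)
      augmentedStructure(array(0, c(L, N_AUG_ATOMS, 3L))))
    grid <- timestepGrid(config)
    n_iter <- min(config$early_stop_step, length(grid))
    selfconds <- vector("list", n_states)
    outs <- vector("list", n_states)
    for (step in seq_len(n_iter)) {
      tval <- grid[step]
      frac <- if (kind == "VE") 1 - (step - 1) / length(grid) else tval
      for (s in seq_len(n_states)) {
        x <- if (kind != "VE") centre_aug(xs[[s]]) else xs[[s]]
        spec <- switch(kind,
          VP = noiseSpec("VP", t = tval, sigma_noise = config$sigma_noise),
          VP_scaled = noiseSpec("VP_scaled", t = tval),
          VE = noiseSpec("VE", sigma = max(tval, config$sigma_min)))
        x_t <- if (kind == "VP_scaled" && stats::sd(as.vector(x@atoms)) == 0)
          applyNoise(x, noiseSpec("VP", t = tval, sigma_noise = config$sigma_noise))
        else applyNoise(x, spec)
        step_cond <- conds[[s]]
        step_cond$selfcond <- if (frac >= config$t_prev_threshold)
          selfconds[[s]] else NULL
        time_val <- if (kind == "VE") ve_time(tval) else tval
        outs[[s]] <- call_model(model, x_t, step_cond, time_val)
        xs[[s]] <- if (!is.null(outs[[s]]$x0_pred)) outs[[s]]$x0_pred else
          augmentedStructure(unflatten_atoms(outs[[s]]$xmat, N_AUG_ATOMS))
      }
      xs <- coupleStates(xs, shared, mode = mode)
      for (s in seq_len(n_states))
        selfconds[[s]] <- list(x_prev = flatten_atoms(xs[[s]]@atoms),
                               local_prev = outs[[s]]$local)
    }
    lapply(seq_len(n_states), function(s) {
      aa <- AA_ONE[max.col(outs[[s]]$aa_logits, ties.method = "first")]
      list(backbone = backboneStructure(xs[[s]]@atoms[, 1:4, , drop = FALSE],
                                        sequence = aa),
           augmented = xs[[s]], aa_logits = outs[[s]]$aa_logits,
           aa_argmax = aa)
    })
  })
}
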