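## Training: Adam with warmup + cosine decay, residue-budget batch packing
## with the complex-inclusion rule, the two-pass self-conditioning recipe and
## a desk-scale toy trainer over synthetic fixtures. Also the versioned JSON
## weight-checkpoint format.

#' Training configuration
#'
#' @param batch_residues residue budget per batch (default 1024).
#' @param batches_per_iter batches per optimizer iteration (default 32;
#'   32 x 1024 = 32768 residue slots per iteration).
#' @param beta1,beta2 Adam moments (0.9, 0.99).
#' @param lr peak learning rate.
#' @param warmup_steps linear warmup length (default 1000; scale down for
#'   toy runs).
#' @param decay_to final learning rate of the cosine decay (1e-7).
#' @param selfcond_prob probability of the two-pass self-conditioning recipe
#'   per step (0.5).
#' @param steps total optimization steps.
#' @param kind noise schedule trained against.
#' @param seed RNG seed.
#' @return a classed list.
#' @export
trainConfig <- function(batch_residues = 1024L, batches_per_iter = 32L,
                        beta1 = 0.9, beta2 = 0.99, lr = 2e-3,
                        warmup_steps = 1000L, decay_to = 1e-7,
                        selfcond_prob = 0.5, steps = 500L,
                        kind = c("VP", "VP_scaled", "VE"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(batch_residues > 0, batches_per_iter > 0, steps > 0)
  structure(list(batch_residues = as.integer(batch_residues),
                 batches_per_iter = as.integer(batches_per_iter),
                 beta1 = beta1, beta2 = beta2, lr = lr,
                 warmup_steps = as.integer(warmup_steps), decay_to = decay_to,
                 selfcond_prob = selfcond_prob, steps = as.integer(steps),
                 kind = kind, seed = as.integer(seed)),
            class = "TrainConfig")
}

## batch packing ---------------------------------------------------------------

#' Pack a dataset manifest into residue-budget batches
#'
#' Clusters are sampled without replacement per epoch; for each cluster a
#' random member chain is selected. If the chain belongs to a complex and the
#' whole complex fits in the current batch, the complex is added with
#' probability 0.5, otherwise only the chain. Entries are appended until the
#' residue budget is reached; an entry that would overflow the budget closes
#' the batch (zero-padded to the budget) and opens the next one.
#'
#' @param manifest data frame with columns \code{id}, \code{length},
#'   \code{cluster} and optionally \code{complex_id} (NA = monomer).
#' @param config a \code{\link{trainConfig}}.
#' @param seed optional RNG seed.
#' @param epochs number of epochs to pack (default 1).
#' @return list of batches, each a list with \code{ids}, \code{n_content},
#'   \code{n_pad} (\code{n_content + n_pad == batch_residues}).
#' @export
packBatches <- function(manifest, config = trainConfig(), seed = NULL,
                        epochs = 1L) {
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("id", "length", "cluster") %in% names(manifest)))
  if (is.null(manifest$complex_id)) manifest$complex_id <- NA
  budget <- config$batch_residues
  if (any(manifest$length > budget))
    stop("dataset entry longer than the batch residue budget")
  batches <- list()
  cur_ids <- character(0); cur_len <- 0L

  close_batch <- function() {
    if (length(cur_ids)) {
      batches[[length(batches) + 1L]] <<- list(
        ids = cur_ids, n_content = cur_len, n_pad = budget - cur_len)
    }
    cur_ids <<- character(0); cur_len <<- 0L
  }
  add_entries <- function(rows) {
    total <- sum(rows$length)
    if (cur_len + total > budget) close_batch()
    cur_ids <<- c(cur_ids, rows$id)
    cur_len <<- cur_len + total
    if (cur_len == budget) close_batch()
  }

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      clusters <- sample(unique(manifest$cluster))
      for (cl in clusters) {
        members <- manifest[manifest$cluster == cl, , drop = FALSE]
        pick <- members[sample.int(nrow(members), 1L), , drop = FALSE]
        rows <- pick
        if (!is.na(pick$complex_id)) {
          cx <- manifest[!is.na(manifest$complex_id) &
                           manifest$complex_id == pick$complex_id, , drop = FALSE]
          fits <- sum(cx$length) <= budget - cur_len || sum(cx$length) <= budget
          if (fits && sum(cx$length) <= budget && stats::runif(1) < 0.5)
            rows <- cx
        }
        add_entries(rows)
      }
    }
    close_batch()
  })
  batches
}

## Adam ------------------------------------------------------------------------

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(ps, st, lr, beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  st$t <- st$t + 1L
  for (name in names(ps$tensors)) {
    p <- ps$tensors[[name]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(st$m[[name]])) {
      st$m[[name]] <- 0 * g
      st$v[[name]] <- 0 * g
    }
    st$m[[name]] <- beta1 * st$m[[name]] + (1 - beta1) * g
    st$v[[name]] <- beta2 * st$v[[name]] + (1 - beta2) * g^2
    mhat <- st$m[[name]] / (1 - beta1^st$t)
    vhat <- st$v[[name]] / (1 - beta2^st$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    ps$values[[name]] <- p$value
    p$grad <- NULL
  }
  invisible(st)
}

lr_schedule <- function(step, config) {
  warm <- config$warmup_steps
  peak <- config$lr
  if (step <= warm) return(peak * step / max(warm, 1L))
  frac <- (step - warm) / max(config$steps - warm, 1L)
  config$decay_to + (peak - config$decay_to) * 0.5 * (1 + cos(pi * min(frac, 1)))
}

## ground-truth preparation ----------------------------------------------------

gt_atom14 <- function(backbone) {
  n <- nResidues(backbone)
  cb <- idealizeCb(backbone)
  g14 <- matrix(0, n, 14L * 3L)
  for (a in 1:4) g14[, (3 * a - 2):(3 * a)] <- matrix(backbone@coords[, a, ], ncol = 3)
  g14[, 13:15] <- cb
  counts <- ATOM14_COUNTS[aaSequence(backbone)]
  counts[is.na(counts)] <- 5L
  list(mat = g14, counts = pmin(counts, 5L))
}

centre_structure <- function(backbone) {
  ctr <- colMeans(caCoords(backbone))
  transformStructure(backbone, diag(3), -ctr)
}

## toy trainer -----------------------------------------------------------------

# full-objective loss for one structure at one sampled noise level; returns
# the tensor breakdown (callers backpropagate the total)
toy_step_loss <- function(model, bb, gt_ss_i, gt14_i, config) {
  ps <- model$ps
  n <- nResidues(bb)
  x_gt_t <- encodeStructure(model, bb, .tensors = TRUE)
  x_gt_v <- val(x_gt_t)
  gt_aug <- augmentedStructure(unflatten_atoms(x_gt_v, N_AUG_ATOMS),
                               bb@residueIndex, bb@chainIndex)

  if (config$kind == "VE") {
    sigma <- sampleVeSigma(1L)
    spec <- noiseSpec("VE", sigma = sigma)
    noise_level <- sigma
    t_embed <- sigma / (sigma + 10)
  } else {
    t <- stats::runif(1)
    spec <- noiseSpec(config$kind, t = t)
    noise_level <- t
    t_embed <- t
  }
  x_t <- applyNoise(gt_aug, spec)

  cond <- conditioningBundle()
  if (stats::runif(1) < config$selfcond_prob) {
    # gradient-free first pass at an independent time
    if (config$kind == "VE") {
      s2 <- sampleVeSigma(1L)
      spec2 <- noiseSpec("VE", sigma = s2)
      t2 <- s2 / (s2 + 10)
    } else {
      t2 <- stats::runif(1)
      spec2 <- noiseSpec(config$kind, t = t2)
    }
    x_t2 <- applyNoise(gt_aug, spec2)
    stash <- ps$tensors; ps$tensors <- NULL
    first <- denoiseStructure(model, x_t2, cond, time = t2)
    ps$tensors <- stash
    cond$selfcond <- list(x_prev = first$xmat, local_prev = first$local)
  }

  out <- denoiseStructure(model, x_t, cond, time = t_embed, .tensors = TRUE)

  # amino-acid decoder on the (detached) denoised positions
  x0_aug <- augmentedStructure(unflatten_atoms(val(out$xmat), N_AUG_ATOMS),
                               bb@residueIndex, bb@chainIndex)
  mask_frac <- stats::runif(1, 0.01, 1)
  masked <- aaSequence(bb)
  hide <- sample.int(n, round(mask_frac * n))
  masked[hide] <- NA_character_
  dec <- decodeAminoAcids(model, x0_aug, out$local, masked, .tensors = TRUE)

  dn <- denoisingLosses(out$trajectory, x_gt_t)
  frames_traj <- lapply(out$trajectory, frames_from_xmat)
  l_rot <- rotationLosses(frames_traj, buildFrames(bb))
  fp <- fapeLosses(out$trajectory, x_gt_v, bb,
                   allatom_pred = dec$atoms14, gt14 = gt14_i$mat)
  l_atom <- atomLoss(dec$atoms14, gt14_i$mat, gt14_i$counts)
  ctx_d <- out$distogram$ctx
  ca_gt <- caCoords(bb)
  gdist <- sqrt(rowSums((ca_gt[ctx_d$rep_idx, , drop = FALSE] -
                         ca_gt[ctx_d$idxf, , drop = FALSE])^2))
  gdist[as.vector(ctx_d$maskf) == 0] <- NA
  aux <- auxLosses(out$aa_logits, out$ss_logits, out$distogram$logits,
                   aaSequence(bb), gt_ss_i, gdist)
  aa_idx <- match(aaSequence(bb), AA_ONE)
  l_aa_dec <- cross_entropy(dec$aa_logits, ifelse(is.na(aa_idx), 1L, aa_idx),
                            mask = seq_len(n) %in% hide & !is.na(aa_idx))
  high_noise <- if (config$kind == "VE") noise_level > 5 else noise_level > 0.5
  l_viol <- if (high_noise) matrix(0, 1, 1) else
    violationLoss(ad_cols(out$xmat, 1:15), bb@chainIndex)

  parts <- list(l_traj = dn$l_traj, l_atom = l_atom, l_fape = fp$l_fape,
                l_rot = l_rot, l_local = fp$l_local, l_aa = l_aa_dec,
                l_viol = l_viol, l_aux = aux$l_aux)
  breakdown <- totalLoss(parts, noise_level, config$kind)
  breakdown$noise_level <- noise_level
  breakdown
}

#' Train a denoising model on a small fixture set
#'
#' Full training objective at desk scale: Adam with the configured moments,
#' linear warmup and cosine decay, the two-pass self-conditioning recipe
#' (with probability 0.5 a first gradient-free pass provides the previous
#' prediction), and the complete weighted loss with its high-noise zeroing
#' rule. Each optimizer step averages the loss over a mini-batch of
#' structures (all fixtures by default, mirroring the multi-structure
#' batches of full-scale training).
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param fixtures list of \linkS4class{BackboneStructure}s (<= 10 structures
#'   of <= 64 residues).
#' @param config a \code{\link{trainConfig}}.
#' @param structures_per_step structures per optimizer step (default: all
#'   fixtures; 1 gives single-draw stochastic steps).
#' @param verbose print progress every 50 steps.
#' @return list with \code{model} (weights updated in place) and
#'   \code{history} (per-step data frame of the loss breakdown).
#' @export
toyTrain <- function(model, fixtures, config = trainConfig(),
                     structures_per_step = length(fixtures), verbose = FALSE) {
  stopifnot(length(fixtures) <= 10L,
            all(vapply(fixtures, nResidues, integer(1)) <= 64L))
  fixtures <- lapply(fixtures, centre_structure)
  gt_ss <- lapply(fixtures, assignSecondaryStructure)
  gt14 <- lapply(fixtures, gt_atom14)
  ps <- model$ps
  st <- adam_state()
  history <- vector("list", config$steps)
  nb <- min(structures_per_step, length(fixtures))
  with_seed(config$seed, {
    for (step in seq_len(config$steps)) {
      take <- if (nb == length(fixtures)) seq_len(nb) else
        sample.int(length(fixtures), nb)
      ps_train(ps)
      total <- NULL
      acc <- NULL
      for (i in take) {
        breakdown <- toy_step_loss(model, fixtures[[i]], gt_ss[[i]],
                                   gt14[[i]], config)
        total <- if (is.null(total)) breakdown$total else
          ad_add(total, breakdown$total)
        num <- lapply(breakdown[c("l_traj", "l_atom", "l_fape", "l_rot",
                                  "l_local", "l_aa", "l_viol", "l_aux",
                                  "total")],
                      function(x) as.numeric(val(x)))
        num$t <- breakdown$noise_level
        acc <- if (is.null(acc)) num else Map(`+`, acc, num)
      }
      total <- ad_mul(total, 1 / nb)
      if (!is.finite(val(total)[1]))
        stop(sprintf("training diverged at step %d (non-finite loss)", step))
      ad_backward(total)
      adam_step(ps, st, lr_schedule(step, config), config$beta1, config$beta2)
      ps$tensors <- NULL

      acc <- lapply(acc, function(x) x / nb)
      history[[step]] <- data.frame(
        step = step, t = acc$t, total = acc$total, l_traj = acc$l_traj,
        l_atom = acc$l_atom, l_fape = acc$l_fape, l_rot = acc$l_rot,
        l_local = acc$l_local, l_aa = acc$l_aa, l_viol = acc$l_viol,
        l_aux = acc$l_aux, lr = lr_schedule(step, config))
      if (verbose && step %% 50L == 0L)
        message(sprintf("step %4d  total %.4f  lr %.2e", step,
                        history[[step]]$total, history[[step]]$lr))
    }
  })
  ps_freeze(ps)
  list(model = model, history = do.call(rbind, history))
}

## checkpoints -----------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Write a weight checkpoint
#'
#' JSON archive with a shape manifest, the model configuration and the
#' parameter values; versioned.
#'
#' @param model a \code{\link{denoiserModel}}.
#' @param path output file.
#' @export
writeCheckpoint <- function(model, path) {
  ps <- model$ps
  params <- lapply(ps$values, function(v)
    list(dim = dim(v), values = as.vector(v)))
  payload <- list(version = CHECKPOINT_VERSION,
                  config = unclass(model$config),
                  seed = ps$seed,
                  manifest = lapply(ps$values, dim),
                  params = params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a weight checkpoint
#'
#' @param path checkpoint file written by \code{\link{writeCheckpoint}}.
#' @return a \code{\link{denoiserModel}} with restored weights.
#' @export
readCheckpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (payload$version > CHECKPOINT_VERSION)
    stop("checkpoint version ", payload$version, " is newer than supported")
  cfg_args <- payload$config
  cfg <- do.call(modelConfig, cfg_args)
  model <- denoiserModel(cfg, seed = payload$seed)
  for (name in names(payload$params)) {
    p <- payload$params[[name]]
    model$ps$values[[name]] <- matrix(p$values, p$dim[1], p$dim[2])
  }
  model
}
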