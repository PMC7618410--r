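## The edited iterative denoising loop: per step, noise is re-applied to the
## current denoised estimate at the step's own noise level, the (optionally
## input-edited) noisy structure is denoised, and the output editor enforces
## structural constraints. Self-conditioning carries the previous prediction
## while the diffusion time is above a threshold.

#' Sampler configuration
#'
#' @param n_steps diffusion time steps (default 500).
#' @param early_stop_step iteration at which traversal stops (default 400).
#' @param t_prev_threshold self-conditioning cutoff: the carry is supplied
#'   only while the (normalized) diffusion time is >= this value (default
#'   0.8 for the VP family, 0.99 for VE).
#' @param schedule_kind \code{"VP"}, \code{"VP_scaled"} or \code{"VE"}.
#' @param sigma_noise VP noise scale at t = 1 (10 A).
#' @param sigma_max,sigma_min VE noise ladder bounds (80 A down to 0.1 A,
#'   log-linear).
#' @param seed RNG seed for the run.
#' @param trace_stride record a denoised snapshot every this many steps
#'   (0 = no trace).
#' @return a classed list.
#' @export
samplerConfig <- function(n_steps = 500L, early_stop_step = 400L,
                          t_prev_threshold = NULL,
                          schedule_kind = c("VP", "VP_scaled", "VE"),
                          sigma_noise = 10, sigma_max = 80, sigma_min = 0.1,
                          seed = 1L, trace_stride = 0L) {
  schedule_kind <- match.arg(schedule_kind)
  if (is.null(t_prev_threshold))
    t_prev_threshold <- if (schedule_kind == "VE") 0.99 else 0.8
  stopifnot(n_steps >= 1L, early_stop_step >= 1L, early_stop_step <= n_steps,
            t_prev_threshold >= 0, t_prev_threshold <= 1)
  structure(list(n_steps = as.integer(n_steps),
                 early_stop_step = as.integer(early_stop_step),
                 t_prev_threshold = t_prev_threshold,
                 schedule_kind = schedule_kind, sigma_noise = sigma_noise,
                 sigma_max = sigma_max, sigma_min = sigma_min,
                 seed = as.integer(seed),
                 trace_stride = as.integer(trace_stride)),
            class = "SamplerConfig")
}

#' Descending timestep grid
#'
#' VP family: the interval [0, 1] is partitioned into \code{n_steps} equally
#' spaced steps (t_0 ... t_N with t_N = 1) and traversed from t_N downward.
#' VE: a log-linear sigma ladder from \code{sigma_max} down to
#' \code{sigma_min}. Traversal is truncated after \code{early_stop_step}
#' iterations by the sampler.
#'
#' @param config a \code{\link{samplerConfig}}.
#' @return descending numeric vector of t (or sigma) values.
#' @export
timestepGrid <- function(config) {
  if (config$schedule_kind == "VE") {
    exp(seq(log(config$sigma_max), log(config$sigma_min),
            length.out = config$n_steps))
  } else {
    rev(seq(0, 1, length.out = config$n_steps + 1L))
  }
}

#' Edit hooks
#'
#' Pure transforms applied to the denoiser's input and output at every
#' sampling step (identity by default). Each hook receives the
#' \linkS4class{AugmentedStructure}, the step index and the step's t value.
#'
#' @param edit_input,edit_output functions \code{(x, step, t) -> x}.
#' @return a classed list.
#' @export
editHooks <- function(edit_input = NULL, edit_output = NULL) {
  id <- function(x, step, t) x
  structure(list(edit_input = edit_input %||% id,
                 edit_output = edit_output %||% id),
            class = "EditHooks")
}

# map a VE sigma to the embedding time value
ve_time <- function(sigma) sigma / (sigma + 10)

centre_aug <- function(aug) {
  ctr <- colMeans(caCoords(aug))
  at <- aug@atoms
  for (k in 1:3) at[, , k] <- at[, , k] - ctr[k]
  augmentedStructure(at, aug@residueIndex, aug@chainIndex)
}

# call either a DenoiserModel or a bare model function with the denoise
# contract (used by tests with oracle models)
call_model <- function(model, x_t, cond, time) {
  if (is.function(model)) {
    out <- model(x_t, cond, time)
    if (is.null(out$xmat)) out$xmat <- flatten_atoms(out$x0_pred@atoms)
    if (is.null(out$local)) out$local <- matrix(0, nResidues(x_t), 1L)
    if (is.null(out$aa_logits)) out$aa_logits <- matrix(0, nResidues(x_t), 20L)
    out
  } else {
    denoiseStructure(model, x_t, cond, time = time)
  }
}

#' Generate a protein backbone by edited iterative denoising
#'
#' Starts from an all-zero structure (or the provided shaped initialization
#' for VE) and repeats: centre, apply noise at the step's own grid value,
#' edit the input, denoise, edit the output. Self-conditioning is supplied
#' while the normalized diffusion time is at or above the configured
#' threshold. The returned backbone carries the argmax of the amino-acid head
#' at the final step.
#'
#' @param model a \code{\link{denoiserModel}} or a function with the denoise
#'   contract \code{(x_t, cond, time) -> list(x0_pred, ...)}.
#' @param n_residues chain length (ignored when \code{init} is given).
#' @param config a \code{\link{samplerConfig}}.
#' @param cond a \code{\link{conditioningBundle}}.
#' @param hooks an \code{\link{editHooks}}.
#' @param init optional initial \linkS4class{AugmentedStructure} (e.g. from
#'   \code{\link{shapedInitialNoise}}).
#' @param chain_index optional per-residue chain ids.
#' @return list with \code{backbone} (\linkS4class{BackboneStructure}),
#'   \code{augmented} (final \linkS4class{AugmentedStructure}),
#'   \code{aa_logits}, \code{aa_argmax} and \code{trace} (list of snapshots,
#'   possibly empty).
#' @export
generateBackbone <- function(model, n_residues = 100L,
                             config = samplerConfig(),
                             cond = conditioningBundle(),
                             hooks = editHooks(), init = NULL,
                             chain_index = NULL) {
  kind <- config$schedule_kind
  with_seed(config$seed, {
    if (!is.null(init)) {
      x <- init
      n_residues <- nResidues(init)
    } else {
      n_residues <- as.integer(n_residues)
      if (is.null(chain_index)) chain_index <- rep(1L, n_residues)
      x <- augmentedStructure(array(0, c(n_residues, N_AUG_ATOMS, 3L)),
                              chainIndex = chain_index)
    }
    grid <- timestepGrid(config)
    n_iter <- min(config$early_stop_step, length(grid))
    selfcond <- NULL
    trace <- list()
    out <- NULL
    for (step in seq_len(n_iter)) {
      tval <- grid[step]
      frac <- if (kind == "VE") 1 - (step - 1) / length(grid) else tval
      if (kind == "VE" && step == 1L && !is.null(init)) {
        x_t <- x  # shaped initialization is already the fully noised state
      } else {
        if (kind != "VE") x <- centre_aug(x)
        spec <- switch(kind,
          VP = noiseSpec("VP", t = tval, sigma_noise = config$sigma_noise),
          VP_scaled = noiseSpec("VP_scaled", t = tval),
          VE = noiseSpec("VE", sigma = max(tval, config$sigma_min)))
        x_t <- if (kind == "VP_scaled" && stats::sd(as.vector(x@atoms)) == 0)
          applyNoise(x, noiseSpec("VP", t = tval, sigma_noise = config$sigma_noise))
        else applyNoise(x, spec)
      }
      x_t <- hooks$edit_input(x_t, step, tval)
      step_cond <- cond
      step_cond$selfcond <- if (frac >= config$t_prev_threshold) selfcond else NULL
      time_val <- if (kind == "VE") ve_time(tval) else tval
      out <- call_model(model, x_t, step_cond, time_val)
      if (!all(is.finite(out$xmat)))
        stop(sprintf("model produced non-finite coordinates at step %d", step))
      x0 <- if (!is.null(out$x0_pred)) out$x0_pred else
        augmentedStructure(unflatten_atoms(out$xmat, N_AUG_ATOMS),
                           x@residueIndex, x@chainIndex)
      x <- hooks$edit_output(x0, step, tval)
      selfcond <- list(x_prev = flatten_atoms(x@atoms), local_prev = out$local)
      if (config$trace_stride > 0L && step %% config$trace_stride == 0L)
        trace[[length(trace) + 1L]] <- x
    }
    aa <- AA_ONE[max.col(out$aa_logits, ties.method = "first")]
    backbone <- backboneStructure(x@atoms[, 1:4, , drop = FALSE],
                                  x@residueIndex, x@chainIndex, sequence = aa)
    list(backbone = backbone, augmented = x, aa_logits = out$aa_logits,
         aa_argmax = aa, trace = trace)
  })
}
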