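## Noise processes: variance-preserving (VP) with a cosine schedule, VP with
## protein-size-dependent standard deviation (VP scaled), variance-expanding
## (VE) noise with a log-normal scale sampler, and shaped-noise
## initialization from Gaussian-chain or user-supplied centres.

#' Cosine-schedule noise level
#'
#' Realizes the cosine schedule as sigma_t = sin(pi/2 * t), so that the
#' signal coefficient sqrt(1 - sigma_t^2) = cos(pi/2 * t); sigma_0 = 0 and
#' sigma_1 = 1.
#'
#' @param t diffusion time(s) in [0, 1].
#' @param kind schedule family; the cosine form applies to the VP family.
#' @return sigma_t in [0, 1].
#' @export
sigmaOfT <- function(t, kind = c("VP", "VP_scaled")) {
  kind <- match.arg(kind)
  if (any(t < 0 | t > 1)) stop("diffusion time t must lie in [0, 1]")
  sin(pi / 2 * t)
}

#' Noise specification
#'
#' @param kind \code{"VP"}, \code{"VP_scaled"} or \code{"VE"}.
#' @param t diffusion time in [0, 1] (VP family).
#' @param sigma noise scale in Angstrom (VE).
#' @param sigma_noise VP noise standard deviation at t = 1 (default 10 A;
#'   ignored for VP_scaled, which uses the CA spread of the input).
#' @return a classed list with the schedule value \code{sigma_t} filled in
#'   for the VP family.
#' @export
noiseSpec <- function(kind = c("VP", "VP_scaled", "VE"), t = NULL, sigma = NULL,
                      sigma_noise = 10) {
  kind <- match.arg(kind)
  if (kind == "VE") {
    if (is.null(sigma) || sigma <= 0) stop("VE noise requires sigma > 0")
    spec <- list(kind = kind, sigma = sigma)
  } else {
    if (is.null(t)) stop("VP-family noise requires a diffusion time t")
    spec <- list(kind = kind, t = t, sigma_t = sigmaOfT(t),
                 sigma_noise = sigma_noise)
  }
  structure(spec, class = "NoiseSpec")
}

# pooled per-coordinate standard deviation of CA positions about their
# centroid (the sigma(x_CA) of the VP-scaled schedule)
sigmaCa <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 2L) stop("sigma(x_CA) is undefined for fewer than 2 residues")
  centred <- sweep(ca, 2, colMeans(ca))
  sqrt(sum(centred^2) / length(centred))
}

#' Apply noise to a structure
#'
#' VP family: \code{x_t = sqrt(1 - sigma_t^2) * x + sigma_t * sigma_noise * eps}
#' with standard normal eps per coordinate; VE: \code{x_sigma = x + sigma * eps}.
#' The mean-shrinkage of the VP form presumes input centred at the origin;
#' centring is the caller's (the sampler's) responsibility.
#'
#' @param x an \linkS4class{AugmentedStructure}, or any numeric array/matrix
#'   of coordinates.
#' @param spec a \code{\link{noiseSpec}}.
#' @param seed optional RNG seed.
#' @return Object of the same type as \code{x}.
#' @export
applyNoise <- function(x, spec, seed = NULL) {
  is_aug <- is(x, "AugmentedStructure")
  arr <- if (is_aug) x@atoms else x
  if (!all(is.finite(arr))) stop("cannot noise a non-finite structure")
  with_seed(seed, {
    eps <- array(stats::rnorm(length(arr)), dim = dim(arr) %||% length(arr))
    out <- switch(spec$kind,
      VP = sqrt(1 - spec$sigma_t^2) * arr + spec$sigma_t * spec$sigma_noise * eps,
      VP_scaled = {
        ca <- if (is_aug) caCoords(x) else stop(
          "VP_scaled requires an AugmentedStructure to measure sigma(x_CA)")
        s <- sigmaCa(ca)
        sqrt(1 - spec$sigma_t^2) * arr + spec$sigma_t * s * eps
      },
      VE = arr + spec$sigma * eps
    )
    if (is_aug) augmentedStructure(out, x@residueIndex, x@chainIndex) else out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample VE noise scales
#'
#' Draws sigma with \code{ln(sigma) ~ Normal(1.6, 1.4)} (log-mean 1.6,
#' log-sd 1.4), in Angstrom.
#'
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of positive noise scales.
#' @export
sampleVeSigma <- function(n = 1L, seed = NULL) {
  with_seed(seed, exp(stats::rnorm(n, mean = 1.6, sd = 1.4)))
}

#' Shaped-noise specification
#'
#' @param centres matrix (or data frame) of centre coordinates in Angstrom;
#'   one row per centre.
#' @param residues_per_centre residues assigned to each centre, in consecutive
#'   blocks (default 200).
#' @param sigma_init standard deviation of the initial noise about each centre
#'   (default 80 A).
#' @return a classed list.
#' @export
shapedNoiseSpec <- function(centres, residues_per_centre = 200L, sigma_init = 80) {
  centres <- as.matrix(centres)
  if (nrow(centres) < 1L) stop("shaped noise requires at least one centre")
  if (ncol(centres) == 2L) centres <- cbind(centres, 0)
  stopifnot(ncol(centres) == 3L, residues_per_centre >= 1L)
  structure(list(centres = centres,
                 residues_per_centre = as.integer(residues_per_centre),
                 sigma_init = sigma_init),
            class = "ShapedNoiseSpec")
}

#' Block assignment of residues to shaped-noise centres
#'
#' Residues are assigned in consecutive blocks: residues 1..rpc to centre 1,
#' rpc+1..2*rpc to centre 2, and so on.
#'
#' @param n_residues chain length.
#' @param residues_per_centre block size.
#' @return integer vector of centre ids.
#' @export
centreAssignment <- function(n_residues, residues_per_centre = 200L) {
  (seq_len(n_residues) - 1L) %/% as.integer(residues_per_centre) + 1L
}

#' Sample random shaped-noise centres
#'
#' Centres are built as a Gaussian chain: centre_i = centre_{i-1} + eps_i with
#' eps_i ~ N(0, (10 A)^2) per coordinate, then compacted by ten steps of
#' gradient descent (learning rate 0.1) on a harmonic restraint centred on
#' 10 A over all centre pairs. A literal cumulative-sum chain variant
#' (centre_i = sum_{k<i} centre_k + eps_i) is available for audit.
#'
#' @param n_residues number of residues the centres must cover.
#' @param residues_per_centre residues per centre (default 200).
#' @param seed optional RNG seed.
#' @param step_sd per-coordinate standard deviation of chain steps (10 A).
#' @param literal_sum use the literal cumulative-sum chain.
#' @param optimize apply the globularity restraint (default TRUE).
#' @return matrix of centre coordinates, one row per centre.
#' @export
makeShapedCentres <- function(n_residues, residues_per_centre = 200L,
                              seed = NULL, step_sd = 10, literal_sum = FALSE,
                              optimize = TRUE) {
  stopifnot(n_residues >= 1L)
  n_centres <- ceiling(n_residues / residues_per_centre)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(n_centres * 3, sd = step_sd), n_centres, 3)
    centres <- matrix(0, n_centres, 3)
    for (i in seq_len(n_centres)) {
      prev <- if (literal_sum) {
        if (i > 1) colSums(centres[seq_len(i - 1L), , drop = FALSE]) else c(0, 0, 0)
      } else {
        if (i > 1) centres[i - 1L, ] else c(0, 0, 0)
      }
      centres[i, ] <- prev + eps[i, ]
    }
    if (optimize && n_centres > 1L)
      centres <- compact_centres(centres, target = 10, lr = 0.1, steps = 10L)
    centres
  })
}

# gradient descent on sum_{i<j} (d_ij - target)^2
compact_centres <- function(centres, target = 10, lr = 0.1, steps = 10L) {
  n <- nrow(centres)
  for (s in seq_len(steps)) {
    grad <- matrix(0, n, 3)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        diffv <- centres[i, ] - centres[j, ]
        d <- sqrt(sum(diffv^2))
        if (d < 1e-8) next
        g <- 2 * (d - target) * diffv / d
        grad[i, ] <- grad[i, ] + g
        grad[j, ] <- grad[j, ] - g
      }
    }
    centres <- centres - lr * grad
  }
  centres
}

#' Shaped initial noise
#'
#' Draws the fully noised starting structure for VE sampling: every atom slot
#' of residue i is drawn from N(centre of i, sigma_init^2 per coordinate),
#' with residues assigned to centres in consecutive blocks. Subsequent
#' denoising steps use standard VE noise.
#'
#' @param spec a \code{\link{shapedNoiseSpec}}.
#' @param n_residues chain length; must be covered by the centres.
#' @param seed optional RNG seed.
#' @return An \linkS4class{AugmentedStructure}.
#' @export
shapedInitialNoise <- function(spec, n_residues, seed = NULL) {
  assign_id <- centreAssignment(n_residues, spec$residues_per_centre)
  if (max(assign_id) > nrow(spec$centres))
    stop(sprintf("%d centres cannot cover %d residues at %d residues per centre",
                 nrow(spec$centres), n_residues, spec$residues_per_centre))
  with_seed(seed, {
    atoms <- array(stats::rnorm(n_residues * N_AUG_ATOMS * 3, sd = spec$sigma_init),
                   c(n_residues, N_AUG_ATOMS, 3L))
    for (k in 1:3)
      atoms[, , k] <- atoms[, , k] + spec$centres[assign_id, k]
    augmentedStructure(atoms)
  })
}
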