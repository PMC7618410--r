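## Three-stage sparse neighbour selection: sequence neighbours, Euclidean
## neighbours, distance-decaying random neighbours, plus an optional stage of
## conditioning-derived neighbours. Bounds attention cost to O(N * K).

#' Neighbour selection configuration
#'
#' Defaults follow the standard budget: 16 sequence + 16 Euclidean +
#' 32 random neighbours (64 in total); when a conditioning stage is used the
#' random stage shrinks to 16 and 16 conditioning neighbours are added.
#'
#' @param n_index sequence-nearest neighbours (default 16).
#' @param n_euclidean CA-distance-nearest neighbours (default 16).
#' @param n_random random neighbours sampled with probability ~ 1/d_CA^3
#'   (default 32).
#' @param n_cond neighbours taken from a conditioning pair list (default 0).
#' @param random_power exponent of the distance-decaying sampling weight
#'   (default 3).
#' @return a classed list.
#' @export
neighbourConfig <- function(n_index = 16L, n_euclidean = 16L, n_random = 32L,
                            n_cond = 0L, random_power = 3) {
  stopifnot(n_index >= 0, n_euclidean >= 0, n_random >= 0, n_cond >= 0)
  structure(list(n_index = as.integer(n_index),
                 n_euclidean = as.integer(n_euclidean),
                 n_random = as.integer(n_random),
                 n_cond = as.integer(n_cond),
                 random_power = random_power),
            class = "NeighbourConfig")
}

#' Select sparse neighbours for each residue
#'
#' Stage 1 picks the \code{n_index} nearest residues by sequence separation
#' within the same chain; stage 2 the \code{n_euclidean} nearest by CA
#' distance among the remaining residues; stage 3 samples \code{n_random}
#' distinct residues without replacement with probability proportional to
#' 1/d_CA^3 (d clamped below at 0.1 A); stage 4 takes up to \code{n_cond}
#' neighbours from a conditioning pair list. A residue is never its own
#' neighbour; ties are broken toward the lower residue position so runs are
#' bit-reproducible. Surplus slots are masked invalid when fewer than K
#' other residues exist.
#'
#' @param ca_coords N x 3 matrix of CA coordinates.
#' @param residue_index,chain_index per-residue integer indexing.
#' @param config a \code{\link{neighbourConfig}}.
#' @param cond_pairs optional two-column matrix of residue-position pairs.
#' @param seed optional RNG seed making the random stage deterministic.
#' @return A \linkS4class{NeighbourSet}.
#' @export
selectNeighbours <- function(ca_coords, residue_index = NULL, chain_index = NULL,
                             config = neighbourConfig(), cond_pairs = NULL,
                             seed = NULL) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < 1L || !all(is.finite(ca_coords)))
    stop("ca_coords must be a non-empty finite matrix")
  if (is.null(residue_index)) residue_index <- seq_len(n)
  if (is.null(chain_index)) chain_index <- rep(1L, n)
  k_total <- config$n_index + config$n_euclidean + config$n_random + config$n_cond
  idx <- matrix(0L, n, k_total)
  valid <- matrix(FALSE, n, k_total)
  src <- matrix("", n, k_total)
  if (k_total == 0L)
    return(new("NeighbourSet", indices = idx, valid = valid, source = src))

  dmat <- as.matrix(stats::dist(ca_coords))
  cond_list <- vector("list", n)
  if (!is.null(cond_pairs) && nrow(cond_pairs) > 0) {
    for (r in seq_len(nrow(cond_pairs))) {
      a <- cond_pairs[r, 1]; b <- cond_pairs[r, 2]
      if (a != b) {
        cond_list[[a]] <- c(cond_list[[a]], b)
        cond_list[[b]] <- c(cond_list[[b]], a)
      }
    }
  }

  with_seed(seed, {
    for (i in seq_len(n)) {
      taken <- logical(n)
      taken[i] <- TRUE
      slot <- 0L

      put <- function(js, tag) {
        for (j in js) {
          slot <<- slot + 1L
          idx[i, slot] <<- as.integer(j)
          valid[i, slot] <<- TRUE
          src[i, slot] <<- tag
          taken[j] <<- TRUE
        }
      }

      # stage 1: sequence neighbours within the chain, ties toward lower index
      same <- which(chain_index == chain_index[i] & !taken)
      if (length(same) && config$n_index > 0) {
        sep <- abs(residue_index[same] - residue_index[i])
        ord <- same[order(sep, same)]
        put(utils::head(ord, config$n_index), "index")
      }

      # stage 2: Euclidean nearest among the rest
      if (config$n_euclidean > 0) {
        cand <- which(!taken)
        if (length(cand)) {
          ord <- cand[order(dmat[i, cand], cand)]
          put(utils::head(ord, config$n_euclidean), "euclidean")
        }
      }

      # stage 3: distance-decaying random sample without replacement
      if (config$n_random > 0) {
        cand <- which(!taken)
        if (length(cand)) {
          w <- 1 / pmax(dmat[i, cand], 0.1)^config$random_power
          m <- min(config$n_random, length(cand))
          pick <- if (length(cand) == 1L) cand else
            cand[sample.int(length(cand), m, prob = w)]
          put(pick, "random")
        }
      }

      # stage 4: conditioning neighbours
      if (config$n_cond > 0 && length(cond_list[[i]])) {
        cand <- unique(cond_list[[i]])
        cand <- cand[!taken[cand]]
        put(utils::head(cand, config$n_cond), "conditioning")
      }
    }
  })
  new("NeighbourSet", indices = idx, valid = valid, source = src)
}

# fixed 32-nearest-CA-neighbour set used by the Encoder and AADecoder
nearest_ca_neighbours <- function(ca_coords, k = 32L) {
  n <- nrow(ca_coords)
  k_eff <- min(k, n - 1L)
  idx <- matrix(0L, n, k)
  valid <- matrix(FALSE, n, k)
  src <- matrix("", n, k)
  if (n >= 2L) {
    dmat <- as.matrix(stats::dist(ca_coords))
    for (i in seq_len(n)) {
      cand <- setdiff(seq_len(n), i)
      ord <- cand[order(dmat[i, cand], cand)]
      pick <- utils::head(ord, k_eff)
      idx[i, seq_along(pick)] <- pick
      valid[i, seq_along(pick)] <- TRUE
      src[i, seq_along(pick)] <- "euclidean"
    }
  }
  new("NeighbourSet", indices = idx, valid = valid, source = src)
}
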