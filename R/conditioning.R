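## Conditioning signals: random three-state secondary-structure strings,
## element masking, multi-motif masks, contact/hotspot derivation,
## training-time conditioning dropout and an internal CA-geometry-based
## three-state secondary-structure assigner.

SS_STATES <- c("H", "E", "L")
SS_UNKNOWN <- "X"

# heuristic element-length bounds: helices 4-30 residues, strands 3-12
SS_ELEMENT_BOUNDS <- list(H = c(4L, 30L), E = c(3L, 12L))

#' Conditioning bundle
#'
#' Container for all conditioning modalities consumed by the denoising
#' network. All components are optional.
#'
#' @param ss per-residue secondary structure in \code{H/E/L/X}.
#' @param sequence per-residue one-letter amino-acid codes (NA = unknown).
#' @param block_contacts two-column matrix of secondary-structure-element id
#'   pairs in contact.
#' @param chain_contacts two-column matrix of chain id pairs in contact.
#' @param hotspots logical per-residue hotspot flags.
#' @param partial_distances list with elements \code{dist} (N x N CB distance
#'   matrix) and \code{valid} (N x N logical mask).
#' @param motif list with elements \code{dist} (N x N CA distance matrix),
#'   \code{mask} (N x N logical), \code{segment_group} and \code{active}
#'   per-residue vectors (see \code{\link{makeMultimotifMask}}).
#' @param selfcond list with elements \code{x_prev}
#'   (\linkS4class{AugmentedStructure}) and \code{local_prev} (matrix).
#' @return a classed list.
#' @export
conditioningBundle <- function(ss = NULL, sequence = NULL, block_contacts = NULL,
                               chain_contacts = NULL, hotspots = NULL,
                               partial_distances = NULL, motif = NULL,
                               selfcond = NULL) {
  structure(list(ss = ss, sequence = sequence, block_contacts = block_contacts,
                 chain_contacts = chain_contacts, hotspots = hotspots,
                 partial_distances = partial_distances, motif = motif,
                 selfcond = selfcond),
            class = "ConditioningBundle")
}

# partition n residues into k element lengths, each within [lo, hi]
random_composition <- function(n, k, lo, hi) {
  lens <- rep(lo, k)
  leftover <- n - lo * k
  while (leftover > 0L) {
    open <- which(lens < hi)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    add <- min(leftover, sample.int(hi - lens[pick], 1L))
    lens[pick] <- lens[pick] + add
    leftover <- leftover - add
  }
  lens
}

#' Sample a random three-state secondary-structure string
#'
#' Draws a loop fraction uniform in [0, 0.5] and splits the remaining budget
#' between helix and strand uniformly; element counts are drawn between
#' heuristic bounds (helix length 4-30, strand length 3-12), residues are
#' distributed across elements, elements shuffled uniformly and loop residues
#' placed at random gaps. Realized per-class counts equal the drawn integer
#' targets exactly.
#'
#' @param length string length (>= 10).
#' @param seed optional RNG seed.
#' @return character vector of \code{"H"}, \code{"E"}, \code{"L"} labels.
#' @export
sampleRandomSS <- function(length, seed = NULL) {
  L <- as.integer(length)
  if (L < 10L) stop("random secondary structure requires length >= 10")
  with_seed(seed, {
    n_loop <- min(round(L * stats::runif(1, 0, 0.5)), L %/% 2L)
    rem <- L - n_loop
    n_h <- round(rem * stats::runif(1))
    n_e <- rem - n_h
    # feasibility: reassign residue budgets too small to form a single element
    if (n_h > 0L && n_h < SS_ELEMENT_BOUNDS$H[1]) { n_e <- n_e + n_h; n_h <- 0L }
    if (n_e > 0L && n_e < SS_ELEMENT_BOUNDS$E[1]) { n_h <- n_h + n_e; n_e <- 0L }

    elements <- list()
    for (cls in c("H", "E")) {
      n_cls <- if (cls == "H") n_h else n_e
      if (n_cls == 0L) next
      b <- SS_ELEMENT_BOUNDS[[cls]]
      k_min <- ceiling(n_cls / b[2]); k_max <- n_cls %/% b[1]
      k <- if (k_max > k_min) k_min + sample.int(k_max - k_min + 1L, 1L) - 1L else k_min
      lens <- random_composition(n_cls, k, b[1], b[2])
      for (l in lens) elements[[length(elements) + 1L]] <- list(cls = cls, len = l)
    }
    if (length(elements) > 1L)
      elements <- elements[sample.int(length(elements))]

    n_gaps <- length(elements) + 1L
    gap_sizes <- tabulate(sample.int(n_gaps, n_loop, replace = TRUE), n_gaps)
    out <- character(0)
    for (e in seq_along(elements)) {
      out <- c(out, rep("L", gap_sizes[e]),
               rep(elements[[e]]$cls, elements[[e]]$len))
    }
    out <- c(out, rep("L", gap_sizes[n_gaps]))
    # drawn targets and element table attached for auditability (adjacent
    # same-class elements merge in the realized string)
    attr(out, "targets") <- c(H = n_h, E = n_e, L = n_loop)
    attr(out, "elements") <- data.frame(
      cls = vapply(elements, function(e) e$cls, character(1)),
      len = vapply(elements, function(e) as.integer(e$len), integer(1)))
    out
  })
}

# runs of contiguous H/E elements in an ss string
ss_elements <- function(ss) {
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("H", "E")
  data.frame(start = starts[keep], end = ends[keep], cls = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Mask a secondary-structure string for conditioning
#'
#' Each contiguous helix/strand element is replaced entirely by unknown
#' (\code{"X"}) with probability 0.5; the first and last residues of every
#' surviving element are also set to unknown, leaving boundary assignment to
#' the model.
#'
#' @param ss character vector of H/E/L labels.
#' @param seed optional RNG seed.
#' @return character vector with masked positions set to \code{"X"}.
#' @export
maskSsForConditioning <- function(ss, seed = NULL) {
  el <- ss_elements(ss)
  with_seed(seed, {
    out <- ss
    for (i in seq_len(nrow(el))) {
      if (stats::runif(1) < 0.5) {
        out[el$start[i]:el$end[i]] <- SS_UNKNOWN
      } else {
        out[el$start[i]] <- SS_UNKNOWN
        out[el$end[i]] <- SS_UNKNOWN
      }
    }
    out
  })
}

#' Multi-motif conditioning mask
#'
#' Training-style segmentation: the chain is partitioned into contiguous
#' segments with random lengths between 10 and 50 residues, each assigned to
#' one of two segment groups and set active with probability 0.5. The pair
#' mask is \code{mask_ij = (s_i == s_j) & a_i & a_j} where s is the segment
#' group and a the active flag. With explicit \code{segments} (data frame
#' with columns start, end, group, active) the segmentation is taken as
#' given.
#'
#' @param length chain length (>= 10).
#' @param segments optional explicit segmentation.
#' @param ca optional N x 3 CA coordinates; when given, the CA distance map
#'   is attached.
#' @param seed optional RNG seed.
#' @return list with \code{mask} (N x N logical), \code{segment_group},
#'   \code{active} (per residue), \code{segments} (data frame) and
#'   \code{dist} (N x N or NULL).
#' @export
makeMultimotifMask <- function(length, segments = NULL, ca = NULL, seed = NULL) {
  L <- as.integer(length)
  if (L < 10L) stop("multi-motif masking requires length >= 10")
  with_seed(seed, {
    if (is.null(segments)) {
      starts <- integer(0); ends <- integer(0)
      pos <- 1L
      while (pos <= L) {
        remaining <- L - pos + 1L
        len <- if (remaining <= 50L) remaining else
          sample(10:min(50L, remaining - 10L), 1L)
        starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
        pos <- pos + len
      }
      segments <- data.frame(start = starts, end = ends,
                             group = sample(1:2, length(starts), replace = TRUE),
                             active = stats::runif(length(starts)) < 0.5)
    } else {
      segments <- as.data.frame(segments)
      covered <- integer(0)
      for (i in seq_len(nrow(segments))) {
        span <- segments$start[i]:segments$end[i]
        if (any(span %in% covered)) stop("explicit segments overlap")
        covered <- c(covered, span)
      }
    }
    s <- integer(L); a <- logical(L)
    for (i in seq_len(nrow(segments))) {
      span <- segments$start[i]:segments$end[i]
      s[span] <- segments$group[i]
      a[span] <- segments$active[i]
    }
    mask <- outer(s, s, "==") & outer(a, a, "&") & s > 0L
    dist <- if (!is.null(ca)) as.matrix(stats::dist(ca)) else NULL
    list(mask = mask, segment_group = s, active = a, segments = segments,
         dist = dist)
  })
}

#' Derive contacts and hotspots from a backbone
#'
#' Residues are in contact when their CA distance is below 8 A; secondary
#' structure elements and chains are in contact when any constituent residue
#' pair is; hotspot residues have at least one inter-chain contact.
#'
#' @param backbone a \linkS4class{BackboneStructure}.
#' @param ss optional secondary-structure string (defaults to
#'   \code{\link{assignSecondaryStructure}}).
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return list with \code{residue_contacts} (N x N logical, diagonal FALSE),
#'   \code{block_contacts} (element-id pair matrix), \code{chain_contacts}
#'   (chain-id pair matrix), \code{hotspots} (logical per residue) and
#'   \code{elements} (the element table used).
#' @export
deriveContactsHotspots <- function(backbone, ss = NULL, cutoff = 8) {
  ca <- caCoords(backbone)
  chain <- chainIndex(backbone)
  n <- nrow(ca)
  dmat <- as.matrix(stats::dist(ca))
  contacts <- dmat < cutoff
  diag(contacts) <- FALSE
  if (is.null(ss)) ss <- assignSecondaryStructure(backbone)
  el <- ss_elements(ss)
  block <- matrix(integer(0), 0, 2)
  if (nrow(el) > 1L) {
    for (i in seq_len(nrow(el) - 1L)) {
      for (j in (i + 1L):nrow(el)) {
        if (any(contacts[el$start[i]:el$end[i], el$start[j]:el$end[j]]))
          block <- rbind(block, c(i, j))
      }
    }
  }
  chains <- sort(unique(chain))
  chain_pairs <- matrix(integer(0), 0, 2)
  hot <- rep(FALSE, n)
  if (length(chains) > 1L) {
    inter <- contacts & outer(chain, chain, "!=")
    hot <- rowSums(inter) > 0
    for (i in seq_along(chains)[-length(chains)]) {
      for (j in (i + 1L):length(chains)) {
        if (any(contacts[chain == chains[i], chain == chains[j]]))
          chain_pairs <- rbind(chain_pairs, c(chains[i], chains[j]))
      }
    }
  }
  list(residue_contacts = contacts, block_contacts = block,
       chain_contacts = chain_pairs, hotspots = hot, elements = el)
}

#' Assign three-state secondary structure from CA geometry
#'
#' Deterministic P-SEA-style assignment using windows on CA distances
#' d(i, i+2), d(i, i+3), d(i, i+4) and the CA pseudo-dihedral: helices show
#' d3 near 5.2 A with a positive ~50 degree pseudo-dihedral, strands show
#' extended d3 near 10.5 A. Chains shorter than the 5-residue window are
#' labelled all loop.
#'
#' @param backbone a \linkS4class{BackboneStructure}.
#' @return character vector of \code{"H"}, \code{"E"}, \code{"L"}.
#' @export
assignSecondaryStructure <- function(backbone) {
  ca <- caCoords(backbone)
  chain <- chainIndex(backbone)
  n <- nrow(ca)
  out <- rep("L", n)
  for (ch in unique(chain)) {
    pos <- which(chain == ch)
    if (length(pos) < 5L) next
    x <- ca[pos, , drop = FALSE]
    m <- length(pos)
    d <- function(off) {
      v <- rep(NA_real_, m)
      v[seq_len(m - off)] <-
        sqrt(rowSums((x[seq_len(m - off), , drop = FALSE] -
                      x[(1 + off):m, , drop = FALSE])^2))
      v
    }
    d2 <- d(2L); d3 <- d(3L); d4 <- d(4L)
    dih <- rep(NA_real_, m)
    for (i in seq_len(m - 3L)) {
      b1 <- x[i + 1, ] - x[i, ]; b2 <- x[i + 2, ] - x[i + 1, ]
      b3 <- x[i + 3, ] - x[i + 2, ]
      cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
      n1 <- cr(b1, b2); n2 <- cr(b2, b3)
      dih[i] <- atan2(sum(b2 / sqrt(sum(b2^2)) * cr(n1, n2)), sum(n1 * n2)) * 180 / pi
    }
    lab <- rep("L", m)
    for (i in seq_len(m - 4L)) {
      is_h <- !is.na(d3[i]) && d2[i] > 4.9 && d2[i] < 6.0 &&
        d3[i] > 4.6 && d3[i] < 5.9 && d4[i] > 5.6 && d4[i] < 7.2 &&
        !is.na(dih[i]) && dih[i] > 20 && dih[i] < 85
      if (is_h) lab[i:(i + 4L)] <- "H"
    }
    for (i in seq_len(m - 3L)) {
      is_e <- !is.na(d3[i]) && d2[i] > 6.2 && d2[i] < 7.3 &&
        d3[i] > 9.3 && d3[i] < 11.3 &&
        !is.na(dih[i]) && abs(dih[i]) > 140
      if (is_e && all(lab[i:(i + 3L)] == "L")) lab[i:(i + 3L)] <- "E"
    }
    out[pos] <- lab
  }
  out
}

#' Training-time conditioning dropout
#'
#' With probability 0.5 the whole bundle is dropped (all modalities removed);
#' otherwise each modality is masked for a uniform random fraction of
#' residues in [0.2, 1.0], except partial distance conditioning whose masked
#' fraction is uniform in [0.2, 0.8].
#'
#' @param cond a \code{\link{conditioningBundle}}.
#' @param seed optional RNG seed.
#' @return the masked bundle (selfcond is always carried through).
#' @export
trainingConditioningDropout <- function(cond, seed = NULL) {
  with_seed(seed, {
    if (stats::runif(1) < 0.5)
      return(conditioningBundle(selfcond = cond$selfcond))
    n_of <- function(x) if (is.null(x)) 0L else length(x)
    mask_residues <- function(n, lo, hi) {
      frac <- stats::runif(1, lo, hi)
      sample.int(n, round(frac * n))
    }
    out <- cond
    if (!is.null(out$ss)) {
      drop <- mask_residues(length(out$ss), 0.2, 1.0)
      out$ss[drop] <- SS_UNKNOWN
    }
    if (!is.null(out$sequence)) {
      drop <- mask_residues(length(out$sequence), 0.2, 1.0)
      out$sequence[drop] <- NA_character_
    }
    if (!is.null(out$hotspots)) {
      drop <- mask_residues(length(out$hotspots), 0.2, 1.0)
      out$hotspots[drop] <- FALSE
    }
    if (!is.null(out$partial_distances)) {
      n <- nrow(out$partial_distances$dist)
      drop <- mask_residues(n, 0.2, 0.8)
      out$partial_distances$valid[drop, ] <- FALSE
      out$partial_distances$valid[, drop] <- FALSE
      attr(out$partial_distances, "masked_fraction") <- length(drop) / n
    }
    out
  })
}
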