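#' @import methods
#' @importFrom stats rnorm runif sd setNames
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
AUGMENTED_ATOMS <- c("N", "CA", "C", "O", "CB", paste0("PS", seq_len(15)))
N_PSEUDO_ATOMS <- 15L
N_AUG_ATOMS <- 20L

#' Protein backbone structure
#'
#' Per-residue backbone atom coordinates (N, CA, C, O) with chain and residue
#' indexing and an optional amino-acid sequence. Coordinates are in Angstrom.
#'
#' @slot coords numeric array of dimension \code{c(N, 4, 3)}; atom order
#'   N, CA, C, O.
#' @slot residueIndex integer vector of length N, strictly increasing within
#'   each chain (PDB-style numbering is preserved).
#' @slot chainIndex integer vector of length N (first chain is 1).
#' @slot sequence character vector of one-letter amino-acid codes, possibly
#'   \code{NA} where unknown.
#' @export
setClass("BackboneStructure",
  representation(
    coords = "array",
    residueIndex = "integer",
    chainIndex = "integer",
    sequence = "character"
  )
)

setValidity("BackboneStructure", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 4L || d[3] != 3L)
    return("coords must be an N x 4 x 3 array")
  n <- d[1]
  if (!all(is.finite(object@coords)))
    return("coordinates must be finite")
  if (length(object@residueIndex) != n || length(object@chainIndex) != n)
    return("residueIndex and chainIndex must have one entry per residue")
  if (length(object@sequence) != n)
    return("sequence must have one entry per residue (NA allowed)")
  for (ch in unique(object@chainIndex)) {
    ri <- object@residueIndex[object@chainIndex == ch]
    if (any(diff(ri) <= 0))
      return(sprintf("residueIndex must be strictly increasing within chain %d", ch))
  }
  TRUE
})

#' Construct a BackboneStructure
#'
#' @param coords N x 4 x 3 array of N/CA/C/O coordinates in Angstrom.
#' @param residueIndex integer residue numbers (default 1..N).
#' @param chainIndex integer chain ids (default all 1).
#' @param sequence optional one-letter amino-acid codes.
#' @return A \linkS4class{BackboneStructure}.
#' @export
backboneStructure <- function(coords, residueIndex = NULL, chainIndex = NULL,
                              sequence = NULL) {
  n <- dim(coords)[1]
  if (is.null(residueIndex)) residueIndex <- seq_len(n)
  if (is.null(chainIndex)) chainIndex <- rep(1L, n)
  if (is.null(sequence)) sequence <- rep(NA_character_, n)
  new("BackboneStructure", coords = coords,
      residueIndex = as.integer(residueIndex),
      chainIndex = as.integer(chainIndex),
      sequence = as.character(sequence))
}

#' Augmented all-atom diffusion state
#'
#' Per-residue 20-atom coordinate block: 5 physical atoms (N, CA, C, O, CB)
#' followed by 15 learned pseudoatoms. This is the state the denoising
#' process operates on.
#'
#' @slot atoms numeric array of dimension \code{c(N, 20, 3)}.
#' @slot residueIndex integer per residue.
#' @slot chainIndex integer per residue.
#' @export
setClass("AugmentedStructure",
  representation(
    atoms = "array",
    residueIndex = "integer",
    chainIndex = "integer"
  )
)

setValidity("AugmentedStructure", function(object) {
  d <- dim(object@atoms)
  if (length(d) != 3L || d[2] != N_AUG_ATOMS || d[3] != 3L)
    return("atoms must be an N x 20 x 3 array")
  if (!all(is.finite(object@atoms)))
    return("atom coordinates must be finite")
  n <- d[1]
  if (length(object@residueIndex) != n || length(object@chainIndex) != n)
    return("residueIndex and chainIndex must have one entry per residue")
  TRUE
})

#' Construct an AugmentedStructure
#'
#' @param atoms N x 20 x 3 array (N, CA, C, O, CB + 15 pseudoatoms).
#' @param residueIndex,chainIndex per-residue indexing (defaults as in
#'   \code{\link{backboneStructure}}).
#' @return An \linkS4class{AugmentedStructure}.
#' @export
augmentedStructure <- function(atoms, residueIndex = NULL, chainIndex = NULL) {
  n <- dim(atoms)[1]
  if (is.null(residueIndex)) residueIndex <- seq_len(n)
  if (is.null(chainIndex)) chainIndex <- rep(1L, n)
  new("AugmentedStructure", atoms = atoms,
      residueIndex = as.integer(residueIndex),
      chainIndex = as.integer(chainIndex))
}

#' Per-residue rigid frames
#'
#' @slot rotations numeric array \code{c(N, 3, 3)} of orthonormal rotation
#'   matrices (determinant +1).
#' @slot translations numeric matrix \code{N x 3} of CA positions.
#' @export
setClass("FrameSet",
  representation(rotations = "array", translations = "matrix")
)

setValidity("FrameSet", function(object) {
  d <- dim(object@rotations)
  if (length(d) != 3L || d[2] != 3L || d[3] != 3L)
    return("rotations must be an N x 3 x 3 array")
  if (nrow(object@translations) != d[1] || ncol(object@translations) != 3L)
    return("translations must be an N x 3 matrix")
  for (i in seq_len(d[1])) {
    R <- object@rotations[i, , ]
    if (max(abs(crossprod(R) - diag(3))) > 1e-5)
      return(sprintf("rotation %d is not orthonormal", i))
    if (abs(det(R) - 1) > 1e-5)
      return(sprintf("rotation %d is not proper (det != +1)", i))
  }
  TRUE
})

#' Sparse neighbour sets
#'
#' Per-residue fixed-width neighbour index lists with validity masks and a
#' per-slot provenance tag.
#'
#' @slot indices integer matrix \code{N x K}; entries of invalid slots are 0.
#' @slot valid logical matrix \code{N x K}.
#' @slot source character matrix \code{N x K} with entries in
#'   \code{"index"}, \code{"euclidean"}, \code{"random"}, \code{"conditioning"}
#'   or \code{""} for invalid slots.
#' @export
setClass("NeighbourSet",
  representation(indices = "matrix", valid = "matrix", source = "matrix")
)

setValidity("NeighbourSet", function(object) {
  n <- nrow(object@indices)
  k <- ncol(object@indices)
  if (!all(dim(object@valid) == c(n, k)) || !all(dim(object@source) == c(n, k)))
    return("indices, valid and source must share dimensions")
  idx <- object@indices[object@valid]
  if (length(idx) && (any(idx < 1L) || any(idx > n)))
    return("valid neighbour indices must lie in [1, N]")
  for (i in seq_len(n)) {
    v <- object@indices[i, object@valid[i, ]]
    if (anyDuplicated(v))
      return(sprintf("residue %d has duplicate valid neighbours", i))
  }
  TRUE
})

#' @describeIn BackboneStructure number of residues
#' @param x object
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname BackboneStructure
#' @export
setMethod("nResidues", "BackboneStructure", function(x) dim(x@coords)[1])

#' @rdname AugmentedStructure
#' @param x object
#' @export
setMethod("nResidues", "AugmentedStructure", function(x) dim(x@atoms)[1])

#' Coordinate accessors
#'
#' \code{atomCoords} returns the coordinate array; \code{caCoords} returns the
#' N x 3 matrix of CA positions.
#'
#' @param x a \linkS4class{BackboneStructure} or \linkS4class{AugmentedStructure}.
#' @return numeric array or matrix.
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname atomCoords
#' @export
setMethod("atomCoords", "BackboneStructure", function(x) x@coords)

#' @rdname atomCoords
#' @export
setMethod("atomCoords", "AugmentedStructure", function(x) x@atoms)

#' @rdname atomCoords
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname atomCoords
#' @export
setMethod("caCoords", "BackboneStructure", function(x) {
  m <- x@coords[, 2, , drop = FALSE]
  dim(m) <- c(dim(x@coords)[1], 3L)
  m
})

#' @rdname atomCoords
#' @export
setMethod("caCoords", "AugmentedStructure", function(x) {
  m <- x@atoms[, 2, , drop = FALSE]
  dim(m) <- c(dim(x@atoms)[1], 3L)
  m
})

#' @rdname atomCoords
#' @export
setGeneric("residueIndex", function(x) standardGeneric("residueIndex"))

#' @rdname atomCoords
#' @export
setMethod("residueIndex", "BackboneStructure", function(x) x@residueIndex)

#' @rdname atomCoords
#' @export
setMethod("residueIndex", "AugmentedStructure", function(x) x@residueIndex)

#' @rdname atomCoords
#' @export
setGeneric("chainIndex", function(x) standardGeneric("chainIndex"))

#' @rdname atomCoords
#' @export
setMethod("chainIndex", "BackboneStructure", function(x) x@chainIndex)

#' @rdname atomCoords
#' @export
setMethod("chainIndex", "AugmentedStructure", function(x) x@chainIndex)

#' @rdname atomCoords
#' @export
setGeneric("aaSequence", function(x) standardGeneric("aaSequence"))

#' @rdname atomCoords
#' @export
setMethod("aaSequence", "BackboneStructure", function(x) x@sequence)

setMethod("show", "BackboneStructure", function(object) {
  n <- nResidues(object)
  cat(sprintf("BackboneStructure: %d residues, %d chain(s)\n",
              n, length(unique(object@chainIndex))))
  if (any(!is.na(object@sequence)))
    cat("  sequence: ", paste0(utils::head(object@sequence, 20), collapse = ""),
        if (n > 20) "..." else "", "\n", sep = "")
})

setMethod("show", "AugmentedStructure", function(object) {
  cat(sprintf("AugmentedStructure: %d residues x %d atoms (%d backbone + %d pseudo)\n",
              nResidues(object), N_AUG_ATOMS, 5L, N_PSEUDO_ATOMS))
})

setMethod("show", "FrameSet", function(object) {
  cat(sprintf("FrameSet: %d residue frames\n", dim(object@rotations)[1]))
})

setMethod("show", "NeighbourSet", function(object) {
  cat(sprintf("NeighbourSet: %d residues x %d slots (%d valid on average)\n",
              nrow(object@indices), ncol(object@indices),
              round(mean(rowSums(object@valid)), 1)))
})

## internal helpers shared across modules ------------------------------------

# flatten an N x A x 3 array into N x (3A) with columns grouped per atom
flatten_atoms <- function(arr) {
  d <- dim(arr)
  out <- matrix(0, d[1], d[2] * 3L)
  for (a in seq_len(d[2])) out[, (3 * a - 2):(3 * a)] <- arr[, a, ]
  out
}

unflatten_atoms <- function(mat, n_atoms) {
  n <- nrow(mat)
  arr <- array(0, c(n, n_atoms, 3L))
  for (a in seq_len(n_atoms)) arr[, a, ] <- mat[, (3 * a - 2):(3 * a)]
  arr
}

# run expr with a locally-set RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
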