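## PDB and tabular I/O. PDB parsing and writing go through bio3d; chains are
## mapped to integer chain indices in file order, alternate locations are
## resolved to the highest occupancy and insertion codes are rejected.

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA_FROM_THREE <- setNames(names(AA_THREE), AA_THREE)

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records, keeps the highest-occupancy alternate location,
#' rejects insertion codes, drops (with a warning) residues missing any of
#' N/CA/C/O and maps chains to integer indices in file order.
#'
#' @param path PDB file path.
#' @return A \linkS4class{BackboneStructure}.
#' @export
readPdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported: ", path)
  # resolve altloc by occupancy (keep the best per atom)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix[which.max(at$o[ix])]
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  chains <- unique(at$chain)
  res_rows <- split(seq_len(nrow(at)), paste(match(at$chain, chains),
                                             at$resno, sep = "_"))
  # preserve file order of residues
  first_row <- vapply(res_rows, min, integer(1))
  res_rows <- res_rows[order(first_row)]
  keep <- list()
  for (rr in res_rows) {
    names_here <- at$elety[rr]
    if (all(c("N", "CA", "C", "O") %in% names_here)) {
      keep[[length(keep) + 1L]] <- rr
    } else {
      warning(sprintf("dropping residue %s%d (missing backbone atoms)",
                      at$chain[rr[1]], at$resno[rr[1]]))
    }
  }
  if (length(keep) == 0L) stop("no residues with complete backbones in ", path)
  n <- length(keep)
  co <- array(0, c(n, 4L, 3L))
  ri <- integer(n); ci <- integer(n); sq <- character(n)
  for (i in seq_len(n)) {
    rr <- keep[[i]]
    for (a in seq_along(BACKBONE_ATOMS)) {
      row <- rr[at$elety[rr] == BACKBONE_ATOMS[a]][1]
      co[i, a, ] <- c(at$x[row], at$y[row], at$z[row])
    }
    ri[i] <- at$resno[rr[1]]
    ci[i] <- match(at$chain[rr[1]], chains)
    sq[i] <- AA_FROM_THREE[at$resid[rr[1]]]
  }
  backboneStructure(co, ri, ci, sq)
}

#' Write a backbone structure to a PDB file
#'
#' Coordinates are written in the standard 3-decimal PDB dialect; residues
#' without a known amino acid are written as glycine.
#'
#' @param structure a \linkS4class{BackboneStructure}.
#' @param path output file path.
#' @export
writePdb <- function(structure, path) {
  n <- nResidues(structure)
  xyz <- numeric(0)
  elety <- character(0); resid <- character(0); resno <- integer(0)
  chain <- character(0)
  seqc <- aaSequence(structure)
  chain_letters <- LETTERS[structure@chainIndex]
  for (i in seq_len(n)) {
    for (a in seq_along(BACKBONE_ATOMS)) {
      xyz <- c(xyz, structure@coords[i, a, ])
      elety <- c(elety, BACKBONE_ATOMS[a])
      aa <- seqc[i]
      resid <- c(resid, if (is.na(aa)) "GLY" else AA_THREE[aa])
      resno <- c(resno, structure@residueIndex[i])
      chain <- c(chain, chain_letters[i])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", length(elety)),
                   resno = resno, resid = resid, eleno = seq_along(elety),
                   elety = elety, chain = chain)
  invisible(path)
}

#' Read shape-node coordinates from a CSV file
#'
#' Expects columns x, y and optionally z (in arbitrary units); nodes are
#' scaled to Angstrom by \code{scale} and 2D paths are placed in the z = 0
#' plane.
#'
#' @param path CSV file path.
#' @param scale multiplicative scale factor to Angstrom.
#' @return matrix of node coordinates (one row per node, 3 columns).
#' @export
readShapeNodes <- function(path, scale = 1) {
  tab <- utils::read.csv(path)
  if (nrow(tab) == 0L) stop("shape-node file is empty: ", path)
  if (!all(c("x", "y") %in% names(tab)))
    stop("shape-node CSV must contain columns x, y[, z]")
  for (cn in intersect(c("x", "y", "z"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column %s, row %d", cn,
                   which(is.na(v))[1]))
    tab[[cn]] <- v
  }
  z <- if ("z" %in% names(tab)) tab$z else 0
  cbind(x = tab$x, y = tab$y, z = z) * scale
}

#' Write a loss history to CSV
#'
#' @param history per-step loss data frame from \code{\link{toyTrain}}.
#' @param path output CSV path.
#' @export
writeLossCurve <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Read a sampler/model/training configuration from YAML
#'
#' A single YAML schema with optional blocks \code{model}, \code{sampler}
#' and \code{train}; named presets \code{default_vp}, \code{default_vp_scaled}
#' and \code{default_ve} select the noise schedule.
#'
#' @param path YAML file path (or NULL for a preset only).
#' @param preset preset name.
#' @return list with \code{model} (\code{\link{modelConfig}}), \code{sampler}
#'   (\code{\link{samplerConfig}}) and \code{train}
#'   (\code{\link{trainConfig}}).
#' @export
readConfig <- function(path = NULL,
                       preset = c("default_vp", "default_vp_scaled",
                                  "default_ve")) {
  preset <- match.arg(preset)
  kind <- switch(preset, default_vp = "VP", default_vp_scaled = "VP_scaled",
                 default_ve = "VE")
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  model <- do.call(modelConfig, raw$model %||% list())
  sampler_args <- raw$sampler %||% list()
  if (is.null(sampler_args$schedule_kind)) sampler_args$schedule_kind <- kind
  sampler <- do.call(samplerConfig, sampler_args)
  train_args <- raw$train %||% list()
  if (is.null(train_args$kind)) train_args$kind <- kind
  train <- do.call(trainConfig, train_args)
  list(model = model, sampler = sampler, train = train)
}
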