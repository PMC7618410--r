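## Designability, the diversity decomposition, single-linkage TM clustering
## with subsampling, and structure statistics.

#' Generation records
#'
#' Validates a table of per-design evaluation records as consumed by the
#' metrics functions.
#'
#' @param id design identifiers.
#' @param scrmsd best self-consistency RMSD over designed sequences (A).
#' @param plddt best sequence's predictor confidence (0-100).
#' @param length optional design lengths.
#' @return a data frame with class \code{"GenerationRecords"}.
#' @export
generationRecords <- function(id, scrmsd, plddt, length = NA_integer_) {
  stopifnot(all(scrmsd >= 0), all(plddt >= 0 & plddt <= 100))
  out <- data.frame(id = as.character(id), scrmsd = scrmsd, plddt = plddt,
                    length = length, stringsAsFactors = FALSE)
  class(out) <- c("GenerationRecords", "data.frame")
  out
}

#' Read generation records from a predictor score table
#'
#' Expects a TSV with columns id, length, scrmsd, plddt (one row per designed
#' sequence); the best sequence per design (lowest scRMSD, its pLDDT) is kept.
#'
#' @param path TSV file path.
#' @return a \code{\link{generationRecords}} table.
#' @export
readGenerationRecords <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "scrmsd", "plddt")
  if (!all(need %in% names(tab)))
    stop("record table must contain columns id, scrmsd, plddt")
  best <- do.call(rbind, lapply(split(tab, tab$id), function(d) {
    d[which.min(d$scrmsd), , drop = FALSE]
  }))
  generationRecords(best$id, best$scrmsd, best$plddt,
                    if ("length" %in% names(best)) best$length else NA_integer_)
}

#' Designability
#'
#' Fraction of designs meeting both success cuts (strict inequalities:
#' scRMSD < rmsd_cut and pLDDT > plddt_cut).
#'
#' @param records a \code{\link{generationRecords}} table.
#' @param rmsd_cut scRMSD cut in Angstrom (default 2).
#' @param plddt_cut pLDDT cut (default 70).
#' @return fraction in [0, 1].
#' @export
designability <- function(records, rmsd_cut = 2.0, plddt_cut = 70) {
  if (nrow(records) == 0L) stop("designability of an empty record set is undefined")
  mean(records$scrmsd < rmsd_cut & records$plddt > plddt_cut)
}

is_designable <- function(records, rmsd_cut = 2.0, plddt_cut = 70) {
  records$scrmsd < rmsd_cut & records$plddt > plddt_cut
}

#' Single-linkage clusters from a TM-score matrix
#'
#' Connected components of the graph whose edges join pairs with TM-score
#' strictly above the threshold. Labels are canonicalized to the smallest
#' member index of each cluster, making the result invariant to input order.
#'
#' @param tm_matrix symmetric matrix with unit diagonal.
#' @param threshold TM-score threshold (default 0.6, strict \code{>}).
#' @return integer vector of cluster labels.
#' @export
singleLinkageClusters <- function(tm_matrix, threshold = 0.6) {
  tm_matrix <- as.matrix(tm_matrix)
  if (nrow(tm_matrix) != ncol(tm_matrix) ||
      max(abs(tm_matrix - t(tm_matrix))) > 1e-6)
    stop("tm_matrix must be symmetric")
  adj <- tm_matrix > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # canonical labels: smallest member index per component
  canon <- tapply(seq_along(comp), comp, min)
  as.integer(canon[as.character(comp)])
}

#' Diversity decomposition with subsampling
#'
#' Per random subsample of the generated set: cluster the designable members
#' by single-linkage TM clustering and compute
#' \code{diversity_all = n_clusters / n_all},
#' \code{diversity_designable = n_clusters / n_designable} and
#' \code{designability = n_designable / n_all}; the identity
#' \code{diversity_all = diversity_designable * designability} holds exactly
#' per draw. Median, minimum and maximum over draws are reported.
#'
#' @param records a \code{\link{generationRecords}} table.
#' @param tm_matrix TM-score matrix aligned with \code{records} rows.
#' @param subsample subsample size (default 100).
#' @param n_draws number of subsamples (default 10).
#' @param threshold TM clustering threshold (default 0.6).
#' @param rmsd_cut,plddt_cut designability cuts.
#' @param seed optional RNG seed.
#' @return a list of class \code{"DiversityReport"}.
#' @export
diversity <- function(records, tm_matrix, subsample = 100L, n_draws = 10L,
                      threshold = 0.6, rmsd_cut = 2.0, plddt_cut = 70,
                      seed = NULL) {
  n <- nrow(records)
  if (nrow(tm_matrix) != n) stop("records and tm_matrix are not aligned")
  if (subsample > n) stop("subsample size exceeds the number of records")
  desig <- is_designable(records, rmsd_cut, plddt_cut)
  with_seed(seed, {
    draws <- lapply(seq_len(n_draws), function(d) {
      take <- sort(sample.int(n, subsample))
      des <- take[desig[take]]
      n_clusters <- if (length(des)) {
        labels <- singleLinkageClusters(
          tm_matrix[des, des, drop = FALSE], threshold)
        length(unique(labels))
      } else 0L
      list(n_all = subsample, n_designable = length(des),
           n_clusters = n_clusters,
           diversity_all = n_clusters / subsample,
           diversity_designable =
             if (length(des)) n_clusters / length(des) else NA_real_,
           designability = length(des) / subsample)
    })
    agg <- function(field) {
      v <- vapply(draws, `[[`, numeric(1), field)
      c(median = stats::median(v, na.rm = TRUE),
        min = suppressWarnings(min(v, na.rm = TRUE)),
        max = suppressWarnings(max(v, na.rm = TRUE)))
    }
    structure(list(
      n_all = n, n_draws = n_draws, subsample = subsample,
      draws = draws,
      diversity_all = agg("diversity_all"),
      diversity_designable = agg("diversity_designable"),
      designability = agg("designability")
    ), class = "DiversityReport")
  })
}

#' @export
print.DiversityReport <- function(x, ...) {
  cat(sprintf("DiversityReport: %d records, %d subsamples of %d\n",
              x$n_all, x$n_draws, x$subsample))
  for (f in c("designability", "diversity_designable", "diversity_all"))
    cat(sprintf("  %-21s median %.3f  [%.3f, %.3f]\n", f,
                x[[f]]["median"], x[[f]]["min"], x[[f]]["max"]))
  invisible(x)
}

#' Read a long-form TM-score matrix
#'
#' Accepts a TSV with columns id_a, id_b, tm as produced by external
#' structure-alignment tools. Asymmetries between the two directions are
#' resolved by taking the maximum; the diagonal is set to 1.
#'
#' @param path TSV file path.
#' @param ids optional id ordering for the output matrix.
#' @return a symmetric TM-score matrix.
#' @export
readTmMatrix <- function(path, ids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b", "tm") %in% names(tab)))
    stop("TM table must contain columns id_a, id_b, tm")
  if (is.null(ids)) ids <- sort(unique(c(tab$id_a, tab$id_b)))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(tab))) {
    a <- tab$id_a[r]; b <- tab$id_b[r]
    m[a, b] <- max(m[a, b], tab$tm[r])
    m[b, a] <- max(m[b, a], tab$tm[r])
  }
  diag(m) <- 1
  m
}

#' Pairwise TM-score matrix from structures
#'
#' Internal fixed-pairing TM-score over all pairs of equal-length structures;
#' symmetrized by the maximum of the two directions.
#'
#' @param structures list of \linkS4class{BackboneStructure}s of equal length.
#' @return symmetric TM matrix.
#' @export
tmMatrix <- function(structures) {
  n <- length(structures)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tm <- max(tmScoreFixedPairing(structures[[i]], structures[[j]]),
                  tmScoreFixedPairing(structures[[j]], structures[[i]]))
        m[i, j] <- m[j, i] <- tm
      }
    }
  }
  m
}

#' Secondary-structure content statistics
#'
#' Per-structure helix/strand/loop fractions, the 20 x 20 histogram over
#' (helix fraction, strand fraction) and the Shannon entropy of the
#' normalized histogram (in nats).
#'
#' @param structures list of \linkS4class{BackboneStructure}s.
#' @param bins bins per axis (default 20).
#' @return list with \code{content} (data frame), \code{histogram} and
#'   \code{entropy}.
#' @export
ssStatistics <- function(structures, bins = 20L) {
  content <- do.call(rbind, lapply(structures, function(s) {
    ss <- assignSecondaryStructure(s)
    data.frame(helix = mean(ss == "H"), strand = mean(ss == "E"),
               loop = mean(ss == "L"))
  }))
  brk <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(v) pmin(findInterval(v, brk, rightmost.closed = TRUE), bins)
  hist2 <- matrix(0L, bins, bins)
  for (i in seq_len(nrow(content))) {
    hist2[bin_of(content$helix[i]), bin_of(content$strand[i])] <-
      hist2[bin_of(content$helix[i]), bin_of(content$strand[i])] + 1L
  }
  p <- hist2 / sum(hist2)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  list(content = content, histogram = hist2, entropy = entropy)
}

#' Structure and sequence composition statistics
#'
#' sigma_CA (pooled per-coordinate standard deviation of CA positions about
#' their centroid) per structure, and alanine/glycine fractions per sequence.
#'
#' @param structures list of \linkS4class{BackboneStructure}s.
#' @param sequences optional list/vector of sequences (defaults to the
#'   structures' own).
#' @return data frame with columns sigma_ca, ala_fraction, gly_fraction,
#'   ala_gly_fraction.
#' @export
compositionStats <- function(structures, sequences = NULL) {
  if (is.null(sequences))
    sequences <- lapply(structures, aaSequence)
  stopifnot(length(sequences) == length(structures))
  do.call(rbind, lapply(seq_along(structures), function(i) {
    ca <- caCoords(structures[[i]])
    sca <- if (nrow(ca) >= 2L) sigmaCa(ca) else 0
    sq <- sequences[[i]]
    sq <- sq[!is.na(sq)]
    ala <- if (length(sq)) mean(sq == "A") else NA_real_
    gly <- if (length(sq)) mean(sq == "G") else NA_real_
    data.frame(sigma_ca = sca, ala_fraction = ala, gly_fraction = gly,
               ala_gly_fraction = ala + gly)
  }))
}
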