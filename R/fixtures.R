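## Synthetic idealized backbone fixtures: helices, strands, Gaussian chains
## and mixed topologies, built from ideal internal coordinates. These make
## every module testable without any structure download.

# ideal backbone internal coordinates (Engh-Huber-style averages)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

deg2rad <- function(x) x * pi / 180

# NeRF atom placement: position D given bonded chain A-B-C, bond |C-D|,
# angle B-C-D and dihedral A-B-C-D
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build a backbone from per-residue (phi, psi) dihedrals; omega fixed trans
backbone_from_dihedrals <- function(phi, psi) {
  g <- IDEAL_GEOM
  n_res <- length(phi)
  co <- array(0, c(n_res, 4L, 3L))
  co[1, 1, ] <- c(0, 0, 0)
  co[1, 2, ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$a_n_ca_c)
  co[1, 3, ] <- co[1, 2, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      co[i, 1, ] <- place_atom(co[i - 1, 1, ], co[i - 1, 2, ], co[i - 1, 3, ],
                               g$b_c_n, g$a_ca_c_n, psi[i - 1])
      co[i, 2, ] <- place_atom(co[i - 1, 2, ], co[i - 1, 3, ], co[i, 1, ],
                               g$b_n_ca, g$a_c_n_ca, g$omega)
      co[i, 3, ] <- place_atom(co[i - 1, 3, ], co[i, 1, ], co[i, 2, ],
                               g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    co[i, 4, ] <- place_atom(co[i, 1, ], co[i, 2, ], co[i, 3, ],
                             g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  co
}

#' Fixture specification
#'
#' @param kind one of \code{"helix"}, \code{"strand"}, \code{"gaussian_chain"},
#'   \code{"mixed"}.
#' @param length number of residues (>= 2).
#' @param seed RNG seed for stochastic kinds and the random sequence.
#' @param ca_step CA step length for Gaussian chains (default 3.8 A).
#' @return a classed list describing the fixture.
#' @export
fixtureSpec <- function(kind = c("helix", "strand", "gaussian_chain", "mixed"),
                        length = 20L, seed = 1L, ca_step = 3.8) {
  kind <- match.arg(kind)
  stopifnot(length >= 2L)
  structure(list(kind = kind, length = as.integer(length),
                 seed = as.integer(seed), ca_step = ca_step),
            class = "FixtureSpec")
}

#' Generate a synthetic idealized backbone
#'
#' Helices and strands are built by internal-coordinate chain construction
#' from ideal bond lengths/angles and canonical dihedrals (helix: phi = -57,
#' psi = -47; strand: phi = -139, psi = 135). Gaussian chains place CA atoms
#' via fixed-length random steps and rebuild N/C/O with idealized local
#' geometry. Deterministic for a given seed; a random amino-acid sequence is
#' attached.
#'
#' @param spec a \code{\link{fixtureSpec}}, or a kind string (with \code{...}
#'   forwarded to \code{fixtureSpec}).
#' @param ... passed to \code{\link{fixtureSpec}} when \code{spec} is a string.
#' @return A \linkS4class{BackboneStructure}.
#' @export
makeFixture <- function(spec, ...) {
  if (is.character(spec)) spec <- fixtureSpec(spec, ...)
  L <- spec$length
  with_seed(spec$seed, {
    co <- switch(spec$kind,
      helix = backbone_from_dihedrals(rep(-57, L), rep(-47, L)),
      strand = backbone_from_dihedrals(rep(-139, L), rep(135, L)),
      gaussian_chain = gaussian_chain_backbone(L, spec$ca_step),
      mixed = mixed_backbone(L)
    )
    seqc <- sample(AA_ONE, L, replace = TRUE)
    backboneStructure(co, sequence = seqc)
  })
}

gaussian_chain_backbone <- function(L, step) {
  ca <- matrix(0, L, 3)
  dir <- c(1, 0, 0)
  for (i in 2:L) {
    # biased random walk: keeps consecutive steps from folding back onto
    # themselves so N/CA/C rebuilding stays non-degenerate
    prop <- stats::rnorm(3)
    prop <- prop / sqrt(sum(prop^2))
    d <- 0.6 * dir + prop
    d <- d / sqrt(sum(d^2))
    ca[i, ] <- ca[i - 1, ] + step * d
    dir <- d
  }
  rebuild_from_ca(ca)
}

# rebuild N/C/O around given CA positions with idealized local geometry
rebuild_from_ca <- function(ca) {
  g <- IDEAL_GEOM
  L <- nrow(ca)
  co <- array(0, c(L, 4L, 3L))
  co[, 2, ] <- ca
  for (i in seq_len(L)) {
    f <- if (i < L) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    f <- f / sqrt(sum(f^2))
    up <- if (abs(f[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- c(f[2] * up[3] - f[3] * up[2],
           f[3] * up[1] - f[1] * up[3],
           f[1] * up[2] - f[2] * up[1])
    p <- p / sqrt(sum(p^2))
    th_c <- deg2rad(21)
    c_dir <- cos(th_c) * f + sin(th_c) * p
    th_n <- th_c + deg2rad(g$a_n_ca_c)
    n_dir <- cos(th_n) * f + sin(th_n) * p
    co[i, 3, ] <- ca[i, ] + g$b_ca_c * c_dir
    co[i, 1, ] <- ca[i, ] + g$b_n_ca * n_dir
    co[i, 4, ] <- place_atom(co[i, 1, ], co[i, 2, ], co[i, 3, ], g$b_c_o,
                             g$a_ca_c_o, 120)
  }
  co
}

mixed_backbone <- function(L) {
  phi <- numeric(0); psi <- numeric(0)
  kinds <- c("helix", "strand", "loop")
  while (length(phi) < L) {
    k <- sample(kinds, 1)
    len <- sample(3:12, 1)
    len <- min(len, L - length(phi))
    dih <- switch(k,
      helix = list(phi = rep(-57, len), psi = rep(-47, len)),
      strand = list(phi = rep(-139, len), psi = rep(135, len)),
      loop = list(phi = stats::runif(len, -150, -50),
                  psi = stats::runif(len, -60, 160))
    )
    phi <- c(phi, dih$phi); psi <- c(psi, dih$psi)
  }
  backbone_from_dihedrals(phi[seq_len(L)], psi[seq_len(L)])
}
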