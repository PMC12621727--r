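#' Featurizer configuration
#'
#' Controls the k-nearest-neighbour graph featurization consumed by the
#' network. Edge features are Gaussian radial basis function (RBF)
#' encodings of the 16 backbone atom-pair distances (N/CA/C/O crossed with
#' N/CA/C/O), a sinusoidal relative-sequence-separation code, and a
#' same-chain indicator; node features are backbone dihedral sines and
#' cosines.
#'
#' @param k_neighbors neighbours per residue (default 30); must be `< L`.
#' @param rbf_count number of RBF centers (default 16).
#' @param rbf_min,rbf_max RBF center range in Angstrom (defaults 2 and 22);
#'   the RBF width equals the center spacing.
#' @param include_sidechain_distances reserved flag for an extra edge
#'   channel of sidechain-atom distances when sidechain context is
#'   supplied (default off; backbone-only inputs ignore it).
#' @return A list of class `"featurizer_config"`.
#' @export
featurizer_config <- function(k_neighbors = 30L, rbf_count = 16L,
                              rbf_min = 2.0, rbf_max = 22.0,
                              include_sidechain_distances = FALSE) {
  stopifnot(k_neighbors >= 1, rbf_count >= 2, rbf_min < rbf_max)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 rbf_count = as.integer(rbf_count),
                 rbf_min = rbf_min, rbf_max = rbf_max,
                 include_sidechain_distances =
                   isTRUE(include_sidechain_distances)),
            class = "featurizer_config")
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

rbf_encode <- function(d, centers, width) {
  exp(-((d - centers) / width)^2)
}

#' Build the k-NN feature graph of a backbone
#'
#' Neighbours are the `k` nearest residues by CA--CA distance (self
#' excluded; ties broken by residue index). All features are functions of
#' interatomic distances and dihedrals only, so they are invariant to rigid
#' motions of the input.
#'
#' @param s a [backbone_structure()].
#' @param cfg a [featurizer_config()].
#' @return A list of class `"feature_graph"` with `L`, `neighbors`
#'   (`L x k`), `node_features` (`L x d_node`), `edge_features`
#'   (`L x k x d_edge`), and the config echo.
#' @export
featurize <- function(s, cfg = featurizer_config()) {
  stopifnot(inherits(s, "backbone_structure"),
            inherits(cfg, "featurizer_config"))
  L <- s$L
  k <- cfg$k_neighbors
  if (k >= L) stop("k_neighbors must be smaller than the chain length")
  ca <- matrix(s$coords[, "CA", ], ncol = 3)
  D <- as.matrix(stats::dist(ca))
  neighbors <- matrix(0L, L, k)
  for (i in seq_len(L)) {
    # distances quantized to 1e-6 A so that exact ties (ideal geometries)
    # break by residue index, stable under rigid-motion rounding noise
    ord <- order(round(D[i, ], 6), seq_len(L))
    neighbors[i, ] <- setdiff(ord, i)[seq_len(k)]
  }

  # node features: phi/psi/omega sin+cos, zero-padded at chain termini
  node <- matrix(0, L, 6)
  for (i in seq_len(L)) {
    prev_ok <- i > 1 && s$chain[i - 1] == s$chain[i]
    next_ok <- i < L && s$chain[i + 1] == s$chain[i]
    phi <- if (prev_ok) {
      torsion_angle(s$coords[i - 1, "C", ], s$coords[i, "N", ],
                    s$coords[i, "CA", ], s$coords[i, "C", ])
    } else NA
    psi <- if (next_ok) {
      torsion_angle(s$coords[i, "N", ], s$coords[i, "CA", ],
                    s$coords[i, "C", ], s$coords[i + 1, "N", ])
    } else NA
    omega <- if (prev_ok) {
      torsion_angle(s$coords[i - 1, "CA", ], s$coords[i - 1, "C", ],
                    s$coords[i, "N", ], s$coords[i, "CA", ])
    } else NA
    ang <- c(phi, psi, omega)
    node[i, ] <- ifelse(is.na(rep(ang, each = 2)), 0,
                        c(rbind(sin(ang), cos(ang))))
  }

  centers <- seq(cfg$rbf_min, cfg$rbf_max, length.out = cfg$rbf_count)
  width <- centers[2] - centers[1]
  freqs <- 2^(0:3)
  d_edge <- 16L * cfg$rbf_count + 2L * length(freqs) + 1L
  idx_i <- rep(seq_len(L), times = k)
  idx_j <- as.vector(neighbors)
  eflat <- matrix(0, L * k, d_edge)
  col <- 0L
  for (ai in BACKBONE_ATOMS) {
    for (aj in BACKBONE_ATOMS) {
      diffs <- s$coords[idx_i, ai, ] - s$coords[idx_j, aj, ]
      dv <- sqrt(rowSums(diffs^2))
      eflat[, col + seq_len(cfg$rbf_count)] <-
        exp(-(outer(dv, centers, `-`) / width)^2)
      col <- col + cfg$rbf_count
    }
  }
  same_chain <- s$chain[idx_i] == s$chain[idx_j]
  sep <- ifelse(same_chain, pmax(-32, pmin(32, idx_j - idx_i)), 0)
  eflat[, col + seq_along(freqs)] <- sin(outer(sep, freqs, `/`))
  eflat[, col + length(freqs) + seq_along(freqs)] <- cos(outer(sep, freqs, `/`))
  eflat[, d_edge] <- as.numeric(same_chain)
  edge <- array(eflat, c(L, k, d_edge))
  structure(list(L = L, neighbors = neighbors, node_features = node,
                 edge_features = edge, config = cfg),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat("<feature_graph> L =", x$L, "| k =", ncol(x$neighbors),
      "| d_node =", ncol(x$node_features),
      "| d_edge =", dim(x$edge_features)[3], "\n")
  invisible(x)
}
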