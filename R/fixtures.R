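IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# place atom D given three predecessors, bond length, bond angle (deg) and
# torsion (deg) -- standard internal-coordinate (NeRF) construction
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  C + cbind(bc, m, n) %*% d2
}

#' Build an ideal toy backbone
#'
#' Constructs backbone coordinates by sequential atom placement from
#' standard bond lengths and angles, with per-residue `(phi, psi)` set by
#' `kind`: `"helix"` uses (-60, -45) degrees, `"extended"` (-135, 135),
#' and `"perturbed"` draws each residue's basin at random (seeded) and
#' jitters the torsions, producing varied compact shapes useful as
#' synthetic training structures.
#'
#' @param length number of residues (`>= 4`).
#' @param kind `"helix"`, `"extended"`, or `"perturbed"`.
#' @param seed RNG seed (used by `"perturbed"` only).
#' @param jitter_deg torsion jitter standard deviation in degrees for
#'   `"perturbed"` (default 12).
#' @return A [backbone_structure()].
#' @examples
#' hel <- make_toy_backbone(20, "helix")
#' @export
make_toy_backbone <- function(length, kind = c("helix", "extended", "perturbed"),
                              seed = 1L, jitter_deg = 12) {
  kind <- match.arg(kind)
  if (length < 4) stop("toy backbones need at least 4 residues")
  L <- as.integer(length)
  tor <- switch(kind,
    helix = list(phi = rep(-60, L), psi = rep(-45, L)),
    extended = list(phi = rep(-135, L), psi = rep(135, L)),
    perturbed = withr::with_seed(seed, {
      basin <- sample(c(TRUE, FALSE), L, replace = TRUE, prob = c(0.6, 0.4))
      list(phi = ifelse(basin, -60, -135) + stats::rnorm(L, 0, jitter_deg),
           psi = ifelse(basin, -45, 135) + stats::rnorm(L, 0, jitter_deg))
    })
  )
  g <- IDEAL_GEOM
  coords <- array(NA_real_, c(L, 4, 3))
  # residue 1: N at origin, CA on x, C in the xy plane
  coords[1, 1, ] <- c(0, 0, 0)
  coords[1, 2, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  coords[1, 3, ] <- coords[1, 2, ] +
    g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      coords[i, 1, ] <- place_atom(coords[i - 1, 1, ], coords[i - 1, 2, ],
                                   coords[i - 1, 3, ], g$b_c_n, g$a_ca_c_n,
                                   tor$psi[i - 1])
      coords[i, 2, ] <- place_atom(coords[i - 1, 2, ], coords[i - 1, 3, ],
                                   coords[i, 1, ], g$b_n_ca, g$a_c_n_ca, 180)
      coords[i, 3, ] <- place_atom(coords[i - 1, 3, ], coords[i, 1, ],
                                   coords[i, 2, ], g$b_ca_c, g$a_n_ca_c,
                                   tor$phi[i])
    }
    coords[i, 4, ] <- place_atom(coords[i, 1, ], coords[i, 2, ],
                                 coords[i, 3, ], g$b_c_o, g$a_ca_c_o,
                                 tor$psi[i] + 180)
  }
  backbone_structure(coords)
}

#' Draw a random Potts model
#'
#' Fields and couplings are i.i.d. centered Gaussians at the stated scales;
#' the edge set is a seeded uniform subset of all `L (L - 1) / 2` pairs
#' with expected fraction `edge_density`.
#'
#' @param L,A sites and alphabet size.
#' @param edge_density fraction of pairs carrying a coupling, in `[0, 1]`.
#' @param field_scale,coupling_scale Gaussian standard deviations (`>= 0`).
#' @param seed RNG seed.
#' @param alphabet optional alphabet (default: first `A` canonical amino
#'   acids).
#' @return A [potts_model()].
#' @export
make_random_potts <- function(L, A, edge_density = 0.5, field_scale = 1.0,
                              coupling_scale = 1.0, seed = 1L,
                              alphabet = NULL) {
  stopifnot(edge_density >= 0, edge_density <= 1,
            field_scale >= 0, coupling_scale >= 0)
  if (is.null(alphabet)) {
    alphabet <- make_alphabet(make_alphabet()$symbols[seq_len(A)])
  }
  stopifnot(alphabet$size == A)
  withr::with_seed(seed, {
    h <- matrix(stats::rnorm(L * A, 0, field_scale), L, A)
    pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    n_edges <- round(edge_density * nrow(pairs))
    if (n_edges == 0) {
      potts_model(h, alphabet = alphabet)
    } else {
      sel <- sort(sample.int(nrow(pairs), n_edges))
      edges <- pairs[sel, , drop = FALSE]
      J <- lapply(seq_len(n_edges), function(k) {
        matrix(stats::rnorm(A * A, 0, coupling_scale), A, A)
      })
      potts_model(h, edges, J, alphabet)
    }
  })
}

#' Geometric sequence rule used by the synthetic datasets
#'
#' Builds the ground-truth Potts model a toy backbone implies under the
#' package's geometric rule: each residue's burial (number of other CA
#' atoms within `burial_radius`) is binned into one of four classes, and
#' the field favours that class by `field_strength`; CA pairs closer than
#' `contact_radius` (sequence separation `>= 3`) receive a coupling of
#' `-coupling_strength` for complementary class pairs (`b = A + 1 - a`).
#'
#' @param s a [backbone_structure()].
#' @param rule list of rule constants; see [dataset_rule_defaults()].
#' @return A [potts_model()] over the rule's 4-letter alphabet.
#' @export
rule_potts_for_backbone <- function(s, rule = dataset_rule_defaults()) {
  alphabet <- rule$alphabet
  A <- alphabet$size
  L <- s$L
  cls <- burial_classes(s, rule)
  h <- matrix(0, L, A)
  h[cbind(seq_len(L), cls)] <- -rule$field_strength
  ca <- matrix(s$coords[, "CA", ], ncol = 3)
  D <- as.matrix(stats::dist(ca))
  edges <- NULL
  J <- list()
  comp <- matrix(0, A, A)
  comp[cbind(seq_len(A), A + 1 - seq_len(A))] <- -rule$coupling_strength
  for (i in seq_len(L)) {
    if (i + 3 > L) break
    for (j in (i + 3):L) {
      if (D[i, j] < rule$contact_radius) {
        edges <- rbind(edges, c(i, j))
        J[[length(J) + 1]] <- comp
      }
    }
  }
  if (is.null(edges)) {
    potts_model(h, alphabet = alphabet)
  } else {
    potts_model(h, edges, J, alphabet)
  }
}

#' @rdname rule_potts_for_backbone
#' @export
dataset_rule_defaults <- function() {
  list(burial_radius = 10.0, burial_breaks = c(-Inf, 5, 8, 11, Inf),
       field_strength = 3.0, coupling_strength = 1.5, contact_radius = 8.0,
       label_noise = 0.05,
       alphabet = make_alphabet(c("L", "A", "S", "E")))
}

#' @rdname rule_potts_for_backbone
#' @export
burial_classes <- function(s, rule = dataset_rule_defaults()) {
  ca <- matrix(s$coords[, "CA", ], ncol = 3)
  D <- as.matrix(stats::dist(ca))
  counts <- rowSums(D < rule$burial_radius) - 1L
  as.integer(cut(counts, rule$burial_breaks, labels = FALSE))
}

#' Synthetic structure-to-sequence dataset
#'
#' Generates `n` perturbed toy backbones, assigns each a sequence by
#' sampling the geometric-rule Potts model ([rule_potts_for_backbone()])
#' at temperature 1, applies label-noise flips, optionally perturbs the
#' stored coordinates with Gaussian noise of `noise_sigma` Angstrom, and
#' splits items into disjoint training and held-out sets. All randomness
#' derives from `seed`, so equal calls are bit-identical.
#'
#' @param n number of items (`>= 2`).
#' @param length residues per backbone.
#' @param rule rule constants ([dataset_rule_defaults()]).
#' @param noise_sigma coordinate observation noise in Angstrom.
#' @param seed RNG seed.
#' @param holdout_fraction fraction of items held out (default 0.2).
#' @return A list with `train` and `holdout` (lists of items, each item a
#'   list with `backbone`, `clean_backbone`, `seq`), plus `alphabet` and
#'   `rule`.
#' @export
make_structure_sequence_dataset <- function(n, length = 30L,
                                            rule = dataset_rule_defaults(),
                                            noise_sigma = 0.0, seed = 1L,
                                            holdout_fraction = 0.2) {
  stopifnot(n >= 2, noise_sigma >= 0)
  A <- rule$alphabet$size
  items <- lapply(seq_len(n), function(i) {
    item_seed <- seed * 10000L + i
    clean <- make_toy_backbone(length, "perturbed", seed = item_seed)
    model <- rule_potts_for_backbone(clean, rule)
    sq <- gibbs_sample(model, 1,
                       sampler_config(seed = item_seed + 1L))$samples[1, ]
    sq <- withr::with_seed(item_seed + 2L, {
      flip <- stats::runif(length) < rule$label_noise
      sq[flip] <- sample.int(A, sum(flip), replace = TRUE)
      sq
    })
    backbone <- if (noise_sigma > 0) {
      withr::with_seed(item_seed + 3L, {
        noisy <- clean
        noisy$coords <- clean$coords +
          array(stats::rnorm(base::length(clean$coords), 0, noise_sigma),
                dim(clean$coords))
        noisy
      })
    } else clean
    list(backbone = backbone, clean_backbone = clean, seq = sq)
  })
  n_hold <- max(1L, round(holdout_fraction * n))
  hold_idx <- withr::with_seed(seed, sort(sample.int(n, n_hold)))
  list(train = items[setdiff(seq_len(n), hold_idx)],
       holdout = items[hold_idx],
       alphabet = rule$alphabet, rule = rule)
}
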