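BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Backbone structures and conformational ensembles
#'
#' A backbone structure holds, per residue, the chain id, residue number
#' (with insertion code, if any), residue name, and coordinates in Angstrom
#' for the four backbone atoms N, CA, C, O, stored as an `L x 4 x 3` array.
#'
#' @param coords numeric `L x 4 x 3` array; second dimension ordered
#'   N, CA, C, O.
#' @param chain character vector of chain ids (length `L`).
#' @param resno residue identifiers (numbers, optionally with insertion
#'   codes), length `L`.
#' @param resname residue names, length `L` (default `"GLY"`).
#' @return An object of class `"backbone_structure"`.
#' @export
backbone_structure <- function(coords, chain = NULL, resno = NULL,
                               resname = NULL) {
  coords <- unname(coords)
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 4, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  L <- dim(coords)[1]
  if (is.null(chain)) chain <- rep("A", L)
  if (is.null(resno)) resno <- as.character(seq_len(L))
  if (is.null(resname)) resname <- rep("GLY", L)
  stopifnot(length(chain) == L, length(resno) == L, length(resname) == L)
  dimnames(coords) <- list(NULL, BACKBONE_ATOMS, c("x", "y", "z"))
  structure(list(L = L, coords = coords, chain = as.character(chain),
                 resno = as.character(resno), resname = as.character(resname)),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat("<backbone_structure> L =", x$L, "| chains:",
      paste(unique(x$chain), collapse = ","), "\n")
  invisible(x)
}

#' @param reference a [backbone_structure()].
#' @param conformers list of additional structures with identical residue
#'   topology (possibly empty).
#' @rdname backbone_structure
#' @export
structure_ensemble <- function(reference, conformers = list()) {
  stopifnot(inherits(reference, "backbone_structure"))
  for (s in conformers) {
    if (!inherits(s, "backbone_structure") || s$L != reference$L ||
        !identical(s$chain, reference$chain) ||
        !identical(s$resno, reference$resno)) {
      stop("conformers must share residue topology with the reference")
    }
  }
  structure(list(reference = reference, conformers = conformers,
                 K = 1L + length(conformers)),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble> K =", x$K, "| L =", x$reference$L, "\n")
  invisible(x)
}

same_topology <- function(a, b) {
  a$L == b$L && identical(a$chain, b$chain) && identical(a$resno, b$resno)
}

#' Read backbone structures from a PDB file
#'
#' Extracts the N, CA, C, O backbone atoms per residue per chain via
#' `bio3d::read.pdb`. Multi-model files yield one structure per MODEL
#' record (returned as a list); insertion codes are preserved in the
#' residue ids.
#'
#' @param path a PDB file.
#' @param gap_policy what to do with residues missing a backbone atom:
#'   `"reject"` (default; error naming the residue) or `"drop"` (silently
#'   skip such residues).
#' @return A [backbone_structure()], or a list of them for multi-model
#'   files.
#' @export
read_backbone_pdb <- function(path, gap_policy = c("reject", "drop")) {
  gap_policy <- match.arg(gap_policy)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  sel <- atoms$elety %in% BACKBONE_ATOMS & atoms$type %in% c("ATOM", "HETATM")
  atoms <- atoms[sel, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no backbone atoms found in ", path)
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  rid <- paste(atoms$chain, atoms$resno, ins, sep = "|")
  rid_order <- unique(rid)
  n_models <- nrow(pdb$xyz)
  # map each retained atom row to its xyz column triple
  xyz_idx <- which(sel)
  out <- vector("list", n_models)
  for (mdl in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[mdl, ], ncol = 3, byrow = TRUE)[xyz_idx, , drop = FALSE]
    keep <- logical(length(rid_order))
    coords <- array(NA_real_, c(length(rid_order), 4, 3))
    for (r in seq_along(rid_order)) {
      rows <- which(rid == rid_order[r])
      at <- match(BACKBONE_ATOMS, atoms$elety[rows])
      if (anyNA(at)) {
        if (gap_policy == "reject") {
          stop("residue ", gsub("\\|$", "", gsub("\\|", " ", rid_order[r])),
               " is missing backbone atoms (",
               paste(BACKBONE_ATOMS[is.na(at)], collapse = ","), ")")
        }
        next
      }
      coords[r, , ] <- xyz[rows[at], , drop = FALSE]
      keep[r] <- TRUE
    }
    ridx <- which(keep)
    if (length(ridx) == 0) stop("no complete backbone residues in ", path)
    first_rows <- match(rid_order[ridx], rid)
    ins1 <- ins[first_rows]
    out[[mdl]] <- backbone_structure(
      coords[ridx, , , drop = FALSE],
      chain = atoms$chain[first_rows],
      resno = paste0(atoms$resno[first_rows], ins1),
      resname = atoms$resid[first_rows]
    )
  }
  if (n_models == 1) out[[1]] else out
}

#' Write a minimal PDB file
#'
#' Emits standard fixed-width ATOM records (coordinates at 0.001 Angstrom
#' precision) for one structure, or MODEL/ENDMDL blocks for an ensemble.
#' Intended for fixtures and design outputs; round-trips through
#' [read_backbone_pdb()].
#'
#' @param x a [backbone_structure()] or [structure_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(x, path) {
  if (inherits(x, "structure_ensemble")) {
    members <- c(list(x$reference), x$conformers)
    lines <- character(0)
    for (k in seq_along(members)) {
      lines <- c(lines, sprintf("MODEL     %4d", k),
                 pdb_atom_lines(members[[k]]), "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
  } else {
    stopifnot(inherits(x, "backbone_structure"))
    writeLines(c(pdb_atom_lines(x), "END"), path)
  }
  invisible(path)
}

pdb_atom_lines <- function(s) {
  n <- 0L
  lines <- character(s$L * 4L)
  elements <- c(N = "N", CA = "C", C = "C", O = "O")
  for (r in seq_len(s$L)) {
    resno <- sub("([0-9]+).*", "\\1", s$resno[r])
    icode <- sub("^[0-9]+", "", s$resno[r])
    if (!nzchar(icode)) icode <- " "
    for (a in seq_along(BACKBONE_ATOMS)) {
      n <- n + 1L
      atom <- BACKBONE_ATOMS[a]
      lines[n] <- sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4s%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        n, paste0(" ", atom), " ", substr(s$resname[r], 1, 3),
        substr(s$chain[r], 1, 1), resno, icode,
        s$coords[r, a, 1], s$coords[r, a, 2], s$coords[r, a, 3],
        1.00, 0.00, elements[[atom]])
    }
  }
  lines
}

#' Optimal superposition RMSD (Kabsch algorithm)
#'
#' With `superpose = TRUE`, finds the least-squares optimal proper rotation
#' (reflections excluded via the SVD determinant correction) and
#' translation of `b` onto `a` over the chosen atom set, then reports the
#' RMSD; with `superpose = FALSE` the direct coordinate RMSD is returned.
#'
#' @param a,b [backbone_structure()] objects with equal residue ordering.
#' @param superpose superpose before computing the RMSD (default `TRUE`).
#' @param atoms which backbone atoms to use (default `"CA"`).
#' @return The RMSD in Angstrom, with attributes `rotation` (3x3) and
#'   `translation` when superposing.
#' @export
kabsch_rmsd <- function(a, b, superpose = TRUE, atoms = "CA") {
  stopifnot(inherits(a, "backbone_structure"),
            inherits(b, "backbone_structure"))
  if (a$L != b$L) stop("structures differ in length")
  atoms <- match.arg(atoms, BACKBONE_ATOMS, several.ok = TRUE)
  P <- do.call(rbind, lapply(atoms, function(at) a$coords[, at, , drop = TRUE]))
  Q <- do.call(rbind, lapply(atoms, function(at) b$coords[, at, , drop = TRUE]))
  if (is.null(dim(P))) { P <- matrix(P, ncol = 3); Q <- matrix(Q, ncol = 3) }
  if (!superpose) {
    return(sqrt(mean(rowSums((P - Q)^2))))
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(Q0, P0)                 # rotate Q onto P
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P0 - Qr)^2)))
  attr(rmsd, "rotation") <- R
  attr(rmsd, "translation") <- cp - drop(R %*% cq)
  rmsd
}

#' Generate a Gaussian-noise conformational ensemble
#'
#' A cheap ensemble generator: each of the `K - 1` conformers adds i.i.d.
#' zero-mean Gaussian noise (standard deviation `sigma` per coordinate
#' axis) to every backbone atom of the reference. `sigma = 0` reproduces
#' the reference exactly.
#'
#' @param s a [backbone_structure()].
#' @param sigma noise standard deviation in Angstrom (`>= 0`).
#' @param K total ensemble size including the reference (default 16).
#' @param seed integer RNG seed.
#' @return A [structure_ensemble()].
#' @export
gaussian_ensemble <- function(s, sigma, K = 16L, seed = NULL) {
  stopifnot(inherits(s, "backbone_structure"), K >= 1)
  if (sigma < 0) stop("sigma must be nonnegative")
  body <- function() {
    conf <- lapply(seq_len(K - 1), function(k) {
      noisy <- s
      noisy$coords <- s$coords +
        array(stats::rnorm(length(s$coords), 0, sigma), dim(s$coords))
      noisy
    })
    structure_ensemble(s, conf)
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' Structural diversity of an ensemble
#'
#' Mean over conformers of the superposed CA RMSD to the reference
#' structure — the scale on which ensemble effects on design are measured.
#'
#' @param e a [structure_ensemble()] with `K >= 2`.
#' @return Mean RMSD in Angstrom.
#' @export
ensemble_diversity <- function(e) {
  stopifnot(inherits(e, "structure_ensemble"))
  if (e$K < 2) stop("ensemble diversity needs at least one conformer (K >= 2)")
  mean(vapply(e$conformers,
              function(s) as.numeric(kabsch_rmsd(e$reference, s)), 0))
}
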