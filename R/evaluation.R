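#' Native sequence recovery
#'
#' Fraction of positions at which the designed sequence matches the native
#' one.
#'
#' @param designed,native integer sequences of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_recovery <- function(designed, native) {
  if (length(designed) != length(native)) {
    stop("sequences differ in length")
  }
  mean(designed == native)
}

#' Per-position profile of a design set
#'
#' The position-specific residue frequency table of a set of designed
#' sequences, optionally pseudocount-smoothed; each row sums to 1.
#'
#' @param seqs an `n x L` integer matrix of designs (rows) or a list of
#'   equal-length integer sequences.
#' @param A alphabet size.
#' @param pseudocount added to every count before normalizing (default 0).
#' @return An `L x A` probability matrix (a PSSM).
#' @export
sequence_profile <- function(seqs, A, pseudocount = 0) {
  if (is.list(seqs)) seqs <- do.call(rbind, seqs)
  seqs <- as.matrix(seqs)
  if (nrow(seqs) < 1) stop("empty design set")
  stopifnot(pseudocount >= 0)
  L <- ncol(seqs)
  prof <- matrix(0, L, A)
  for (i in seq_len(L)) {
    prof[i, ] <- tabulate(seqs[, i], nbins = A) + pseudocount
  }
  prof / rowSums(prof)
}

check_pssm <- function(p) {
  p <- as.matrix(p)
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("PSSM rows must be nonnegative and sum to 1")
  }
  p
}

js_divergence_row <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' PSSM similarity as one minus Jensen--Shannon divergence
#'
#' `1 - mean_i JSD(profile[i, ], reference[i, ])` with base-2 logarithms,
#' so each row's divergence lies in `[0, 1]` bits and the similarity lies
#' in `[0, 1]`: 1 for identical profiles, 0 when every position puts the
#' two distributions on disjoint support.
#'
#' @param profile,reference `L x A` row-stochastic matrices.
#' @return Similarity in `[0, 1]`.
#' @export
pssm_similarity <- function(profile, reference) {
  profile <- check_pssm(profile)
  reference <- check_pssm(reference)
  if (!all(dim(profile) == dim(reference))) stop("PSSM shapes differ")
  jsd <- vapply(seq_len(nrow(profile)), function(i) {
    js_divergence_row(profile[i, ], reference[i, ])
  }, 0)
  1 - mean(jsd)
}

#' Diversity of a design set
#'
#' Mean pairwise sequence identity over all unordered pairs of designs,
#' and its complement (diversity).
#'
#' @param seqs an `n x L` integer matrix with `n >= 2`, or a list of
#'   equal-length sequences.
#' @return A list with `identity` and `diversity`, both in `[0, 1]`.
#' @export
design_diversity <- function(seqs) {
  if (is.list(seqs)) seqs <- do.call(rbind, seqs)
  seqs <- as.matrix(seqs)
  n <- nrow(seqs)
  if (n < 2) stop("design diversity needs at least 2 sequences")
  ids <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ids <- c(ids, sequence_recovery(seqs[i, ], seqs[j, ]))
    }
  }
  list(identity = mean(ids), diversity = 1 - mean(ids))
}

#' FASTA input and output for design sets
#'
#' Reading goes through `seqinr`; sequences are converted to integer index
#' vectors under `alphabet` and must share one length. The writer emits
#' the package's design header schema
#' `>design_{idx}|energy={e}|K={K}|seed={seed}` when the metadata columns
#' are supplied.
#'
#' @param path FASTA file.
#' @param alphabet an [make_alphabet()].
#' @return `read_fasta_designs`: a list with `seqs` (`n x L` matrix) and
#'   `names`.
#' @export
read_fasta_designs <- function(path, alphabet = make_alphabet()) {
  fas <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  seqs <- lapply(fas, function(x) {
    seq_from_string(toupper(as.character(x)), alphabet)
  })
  lens <- vapply(seqs, length, 0L)
  if (length(unique(lens)) != 1) stop("sequences differ in length")
  list(seqs = do.call(rbind, seqs), names = names(fas))
}

#' @rdname read_fasta_designs
#' @param seqs `n x L` integer matrix of designs.
#' @param energies optional per-design composite energies for the headers.
#' @param K,seed optional metadata echoed into the headers.
#' @export
write_fasta_designs <- function(seqs, path, alphabet = make_alphabet(),
                                energies = NULL, K = NA, seed = NA) {
  seqs <- as.matrix(seqs)
  headers <- vapply(seq_len(nrow(seqs)), function(i) {
    if (is.null(energies)) {
      sprintf("design_%d", i)
    } else {
      sprintf("design_%d|energy=%.4f|K=%s|seed=%s", i, energies[i], K, seed)
    }
  }, "")
  strings <- apply(seqs, 1, seq_to_string, alphabet = alphabet)
  seqinr::write.fasta(as.list(strings), headers, path, nbchar = 80)
  invisible(path)
}

#' PSSM files as TSV
#'
#' `L` rows by `A` columns with the alphabet symbols as header; rows are
#' validated to sum to 1 on read.
#'
#' @param path TSV file.
#' @param pssm `L x A` row-stochastic matrix.
#' @param alphabet an [make_alphabet()].
#' @export
write_pssm_tsv <- function(pssm, path, alphabet = make_alphabet()) {
  pssm <- check_pssm(pssm)
  colnames(pssm) <- alphabet$symbols
  utils::write.table(pssm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm_tsv
#' @export
read_pssm_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  check_pssm(as.matrix(tab))
}
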