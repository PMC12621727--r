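#' Potts sequence models
#'
#' A Potts model over length-`L` sequences assigns every sequence `S` the
#' energy
#' \deqn{E(S) = \sum_i h_i(s_i) + \sum_{i<j} J_{ij}(s_i, s_j)}
#' where `h` are per-site fields (an `L x A` matrix) and `J` are pairwise
#' couplings stored as one dense `A x A` block per undirected edge
#' `{i, j}` with `i < j`; the first block axis scores the residue at the
#' smaller site index. The Boltzmann distribution is
#' `p(S) = exp(-E(S)) / Z`. Site indices are 1-based in R; the JSON
#' interchange format is 0-based.
#'
#' @param h numeric `L x A` field matrix (dimensionless energy units).
#' @param edges integer `m x 2` matrix of site pairs, each row `i < j`
#'   (1-based); may have zero rows.
#' @param J list of `m` numeric `A x A` coupling blocks aligned with the
#'   rows of `edges`.
#' @param alphabet an [make_alphabet()] object with `A` symbols.
#' @return An object of class `"potts_model"` with elements `L`, `alphabet`,
#'   `h`, `edges`, `J`.
#' @examples
#' m <- potts_model(h = matrix(0, 3, 4), alphabet = make_alphabet(c("A","C","G","T")))
#' potts_energy(m, c(1, 2, 3))
#' @export
potts_model <- function(h, edges = matrix(integer(), 0, 2), J = list(),
                        alphabet = make_alphabet()) {
  h <- as.matrix(h)
  edges <- matrix(as.integer(edges), ncol = 2)
  L <- nrow(h)
  A <- alphabet$size
  if (ncol(h) != A) stop("h must have one column per alphabet symbol")
  if (!all(is.finite(h))) stop("h contains non-finite values")
  if (L < 1) stop("model must have at least one site")
  if (nrow(edges) != length(J)) stop("edges and J must align")
  if (nrow(edges) > 0) {
    if (any(edges[, 1] >= edges[, 2]) || any(edges[, 1] < 1) ||
        any(edges[, 2] > L)) {
      stop("each edge must satisfy 1 <= i < j <= L")
    }
    key <- edge_keys(edges)
    if (anyDuplicated(key)) stop("duplicate edges")
    for (b in J) {
      b <- as.matrix(b)
      if (!all(dim(b) == c(A, A))) stop("each coupling block must be A x A")
      if (!all(is.finite(b))) stop("couplings contain non-finite values")
    }
    J <- lapply(J, function(b) {
      b <- as.matrix(b); dimnames(b) <- NULL; b
    })
    ord <- order(edges[, 1], edges[, 2])
    edges <- edges[ord, , drop = FALSE]
    J <- J[ord]
  }
  dimnames(h) <- NULL
  structure(list(L = L, alphabet = alphabet, h = h, edges = edges, J = J),
            class = "potts_model")
}

edge_keys <- function(edges) paste(edges[, 1], edges[, 2], sep = "-")

#' @export
print.potts_model <- function(x, ...) {
  cat("<potts_model> L =", x$L, " A =", x$alphabet$size,
      " edges =", nrow(x$edges), "\n")
  invisible(x)
}

#' Look up one coupling block
#'
#' Returns the `A x A` block scoring `(s_i, s_j)` for any site order:
#' `coupling_block(m, j, i)` is the transpose of `coupling_block(m, i, j)`.
#' Absent edges return a zero block.
#'
#' @param model a [potts_model()].
#' @param i,j distinct site indices.
#' @export
coupling_block <- function(model, i, j) {
  stopifnot(i != j, i >= 1, j >= 1, i <= model$L, j <= model$L)
  a <- min(i, j); b <- max(i, j)
  hit <- which(model$edges[, 1] == a & model$edges[, 2] == b)
  A <- model$alphabet$size
  blk <- if (length(hit)) model$J[[hit]] else matrix(0, A, A)
  if (i < j) blk else t(blk)
}

#' Potts energy of a sequence
#'
#' @param model a [potts_model()].
#' @param s integer vector of length `model$L`, entries in `1..A`.
#' @return The scalar energy `sum_i h[i, s_i] + sum_edges J[s_i, s_j]`.
#' @export
potts_energy <- function(model, s) {
  s <- check_seq(s, model$alphabet$size, model$L)
  e <- sum(model$h[cbind(seq_len(model$L), s)])
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      e <- e + model$J[[k]][s[model$edges[k, 1]], s[model$edges[k, 2]]]
    }
  }
  e
}

# per-site incidence: for each site, the edge indices touching it and whether
# the site is the first (smaller) endpoint
site_incidence <- function(model) {
  inc <- vector("list", model$L)
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      i <- model$edges[k, 1]; j <- model$edges[k, 2]
      inc[[i]] <- rbind(inc[[i]], c(k, j, 1L))
      inc[[j]] <- rbind(inc[[j]], c(k, i, 0L))
    }
  }
  inc
}

#' Energies of all single-site substitutions
#'
#' Entry `a` is the full-sequence energy with `site` set to residue `a`,
#' computed locally in `O(A * degree(site))` rather than by `A` full
#' re-evaluations.
#'
#' @inheritParams potts_energy
#' @param site site index in `1..L`.
#' @return numeric vector of length `A`.
#' @export
site_substitution_energies <- function(model, s, site) {
  s <- check_seq(s, model$alphabet$size, model$L)
  if (length(site) != 1 || site < 1 || site > model$L) {
    stop("site out of range")
  }
  base <- potts_energy(model, s)
  local <- site_local_energies(model, s, site)
  base - local[s[site]] + local
}

# h[site, ] plus coupling contributions of `site` against the rest of s,
# for every candidate residue at `site`
site_local_energies <- function(model, s, site) {
  A <- model$alphabet$size
  loc <- model$h[site, ]
  if (nrow(model$edges) > 0) {
    first <- which(model$edges[, 1] == site)
    for (k in first) loc <- loc + model$J[[k]][, s[model$edges[k, 2]]]
    second <- which(model$edges[, 2] == site)
    for (k in second) loc <- loc + model$J[[k]][s[model$edges[k, 1]], ]
  }
  loc
}

#' Average Potts models across an ensemble
#'
#' Parameter-space averaging: the returned model's fields are the weighted
#' mean of the input fields and its edge set is the union of the input edge
#' sets, each coupling block the weighted mean with absent blocks counted as
#' zero. Because the energy is linear in `(h, J)`, the averaged model's
#' energy of any sequence equals the weighted mean of the per-model
#' energies, and its Boltzmann distribution is the renormalized weighted
#' geometric mean (product of experts) of the per-model distributions.
#'
#' @param models non-empty list of [potts_model()] objects sharing `L` and
#'   alphabet.
#' @param weights optional nonnegative weights summing to 1 (default
#'   uniform `1/K`).
#' @return A [potts_model()].
#' @export
average_models <- function(models, weights = NULL) {
  K <- length(models)
  if (K == 0) stop("empty model list")
  for (m in models) {
    if (!inherits(m, "potts_model")) stop("models must be potts_model objects")
    if (m$L != models[[1]]$L) stop("models disagree on L")
    if (!alphabets_equal(m$alphabet, models[[1]]$alphabet)) {
      stop("models disagree on alphabet")
    }
  }
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a length-K simplex vector")
  }
  A <- models[[1]]$alphabet$size
  h <- Reduce(`+`, Map(function(m, w) w * m$h, models, weights))
  all_keys <- unique(unlist(lapply(models, function(m) edge_keys(m$edges))))
  if (length(all_keys) == 0) {
    return(potts_model(h, alphabet = models[[1]]$alphabet))
  }
  parts <- do.call(rbind, strsplit(all_keys, "-", fixed = TRUE))
  edges <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
  J <- vector("list", nrow(edges))
  for (r in seq_len(nrow(edges))) {
    blk <- matrix(0, A, A)
    for (k in seq_len(K)) {
      m <- models[[k]]
      hit <- which(m$edges[, 1] == edges[r, 1] & m$edges[, 2] == edges[r, 2])
      if (length(hit)) blk <- blk + weights[k] * m$J[[hit]]
    }
    J[[r]] <- blk
  }
  potts_model(h, edges, J, models[[1]]$alphabet)
}

#' Exhaustively enumerate the Boltzmann distribution
#'
#' Computes `p(S) = exp(-E(S)) / Z` for all `A^L` sequences in lexicographic
#' order (site 1 most significant), in the log domain so large `|E|` does
#' not overflow. Refuses instances with more than `cap` states.
#'
#' @param model a [potts_model()].
#' @param cap maximum admissible number of states `A^L` (default `1e6`).
#' @return A list of class `"potts_exact"` with `logZ`, `prob` (length
#'   `A^L`), `energies`, and `states` (an `A^L x L` matrix of sequences).
#' @export
enumerate_distribution <- function(model, cap = 1e6) {
  A <- model$alphabet$size
  n <- A^model$L
  if (n > cap) {
    stop("A^L = ", n, " exceeds the enumeration cap of ", cap)
  }
  states <- all_states(model$L, A)
  e <- states_energy(model, states)
  logZ <- log_sum_exp(-e)
  structure(list(model = model, logZ = logZ, prob = exp(-e - logZ),
                 energies = e, states = states),
            class = "potts_exact")
}

# all A^L sequences, lexicographic with site 1 most significant
all_states <- function(L, A) {
  n <- A^L
  states <- matrix(0L, n, L)
  for (i in seq_len(L)) {
    states[, i] <- rep(rep(seq_len(A), each = A^(L - i)), length.out = n)
  }
  states
}

# vectorized energies for a matrix of sequences (rows)
states_energy <- function(model, states) {
  e <- numeric(nrow(states))
  for (i in seq_len(model$L)) e <- e + model$h[i, ][states[, i]]
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      i <- model$edges[k, 1]; j <- model$edges[k, 2]
      e <- e + model$J[[k]][cbind(states[, i], states[, j])]
    }
  }
  e
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Canonicalize a model into the zero-sum gauge
#'
#' Potts parameters are not identifiable: per-site constant field shifts and
#' row/column shifts between couplings and fields leave every sequence
#' probability unchanged. The zero-sum gauge is the canonical representative
#' in which every coupling block has zero row means and zero column means;
#' the shifted mass is absorbed into the fields so that per-sequence
#' energies are preserved exactly. Use it before comparing learned and true
#' couplings.
#'
#' @param model a [potts_model()].
#' @return A gauge-fixed [potts_model()] with identical energies.
#' @export
apply_zero_sum_gauge <- function(model) {
  h <- model$h
  J <- model$J
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      blk <- J[[k]]
      r <- rowMeans(blk); cc <- colMeans(blk); m <- mean(blk)
      J[[k]] <- blk - outer(r, rep(1, length(cc))) -
        outer(rep(1, length(r)), cc) + m
      i <- model$edges[k, 1]; j <- model$edges[k, 2]
      h[i, ] <- h[i, ] + r - m
      h[j, ] <- h[j, ] + cc
    }
  }
  potts_model(h, model$edges, J, model$alphabet)
}

#' Read and write the package's Potts JSON interchange format
#'
#' Versioned JSON with keys `version`, `alphabet`, `L`, `h` (row-major
#' `L x A`), `edges` (0-based `[i, j]` pairs, `i < j`) and `J` (one
#' row-major `A x A` block per edge). The writer emits a canonical key
#' order; the reader validates all model invariants.
#'
#' @param model a [potts_model()].
#' @param path file path.
#' @return `read_potts_json` returns a [potts_model()];
#'   `write_potts_json` returns `path` invisibly.
#' @export
write_potts_json <- function(model, path) {
  obj <- list(
    version = "1",
    alphabet = paste(model$alphabet$symbols, collapse = ""),
    L = model$L,
    h = model$h,
    edges = if (nrow(model$edges)) unname(model$edges - 1L) else list(),
    J = if (length(model$J)) lapply(model$J, unname) else list()
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_potts_json
#' @export
read_potts_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version)) stop("not a Potts JSON file: missing version")
  alphabet <- make_alphabet(strsplit(obj$alphabet, "")[[1]])
  h <- as.matrix(obj$h)
  n_edges <- if (is.null(dim(obj$edges))) length(obj$edges) else nrow(obj$edges)
  if (n_edges == 0) {
    return(potts_model(h, alphabet = alphabet))
  }
  edges <- matrix(as.integer(obj$edges), ncol = 2) + 1L
  A <- alphabet$size
  J <- obj$J
  if (is.array(J) && length(dim(J)) == 3) {
    J <- lapply(seq_len(dim(J)[1]), function(k) matrix(J[k, , ], A, A))
  } else {
    J <- lapply(J, function(b) matrix(as.numeric(b), A, A))
  }
  potts_model(h, edges, J, alphabet)
}
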