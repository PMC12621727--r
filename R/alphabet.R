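#' Residue alphabets
#'
#' An alphabet is the ordered set of residue symbols a Potts model scores.
#' The default is the 20 canonical amino acids in alphabetical one-letter
#' order, `"ACDEFGHIKLMNPQRSTVWY"`; this fixed order defines the column
#' indexing of every field matrix and coupling block in the package.
#'
#' @param symbols character vector of unique single-character residue symbols.
#' @return An object of class `"ens_alphabet"` with elements `symbols` and
#'   `size`.
#' @examples
#' aa <- make_alphabet()
#' aa$size
#' toy <- make_alphabet(c("A", "C", "G", "T"))
#' @export
make_alphabet <- function(symbols = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  symbols <- as.character(symbols)
  stopifnot(length(symbols) >= 2, all(nchar(symbols) == 1L),
            !anyDuplicated(symbols))
  structure(list(symbols = symbols, size = length(symbols)),
            class = "ens_alphabet")
}

#' @export
print.ens_alphabet <- function(x, ...) {
  cat("<ens_alphabet> size", x$size, ":", paste(x$symbols, collapse = ""), "\n")
  invisible(x)
}

alphabets_equal <- function(a, b) identical(a$symbols, b$symbols)

#' Convert between residue strings and index vectors
#'
#' Sequences are represented internally as integer vectors of 1-based
#' alphabet indices. Symbols outside the alphabet are rejected (there is no
#' wildcard mapping by default).
#'
#' @param x a character scalar (for `seq_from_string`) or an integer vector
#'   of indices in `1..A` (for `seq_to_string`).
#' @param alphabet an [make_alphabet()] object.
#' @return An integer vector, or a single string.
#' @export
seq_from_string <- function(x, alphabet = make_alphabet()) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "")[[1]]
  idx <- match(chars, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("symbols not in alphabet: ", paste(bad, collapse = ", "))
  }
  idx
}

#' @rdname seq_from_string
#' @export
seq_to_string <- function(x, alphabet = make_alphabet()) {
  check_seq(x, alphabet$size)
  paste(alphabet$symbols[x], collapse = "")
}

check_seq <- function(s, A, L = NULL) {
  if (!is.numeric(s) || anyNA(s) || any(s < 1L) || any(s > A) ||
      any(s != as.integer(s))) {
    stop("sequence must be integer indices in 1..", A)
  }
  if (!is.null(L) && length(s) != L) {
    stop("sequence length ", length(s), " does not match model length ", L)
  }
  invisible(as.integer(s))
}
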