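# shared oracle helpers: everything here is deliberately naive / independent
# of the package's optimized code paths

# lexicographic index of sequences (rows), site 1 most significant
seq_lex_index <- function(S, A) {
  S <- matrix(S, ncol = ncol(as.matrix(S)))
  L <- ncol(S)
  as.vector((S - 1) %*% (A^((L:1) - 1))) + 1L
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

empirical_dist <- function(samples, A) {
  L <- ncol(samples)
  tabulate(seq_lex_index(samples, A), nbins = A^L) / nrow(samples)
}

# term-by-term Potts energy, written independently of potts_energy()
naive_energy <- function(model, s) {
  e <- 0
  for (i in seq_len(model$L)) e <- e + model$h[i, s[i]]
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      i <- model$edges[k, 1]; j <- model$edges[k, 2]
      e <- e + model$J[[k]][s[i], s[j]]
    }
  }
  e
}

# window-by-window LCP penalty recomputation
naive_lcp <- function(s, cfg, A) {
  total <- 0
  for (start in 1:(length(s) - cfg$window + 1)) {
    win <- s[start:(start + cfg$window - 1)]
    cnt <- sapply(seq_len(A), function(a) sum(win == a)) + cfg$pseudocount
    p <- cnt / sum(cnt)
    H <- -sum(p * log(p))
    total <- total + max(0, cfg$p_min - exp(H))^2
  }
  total
}

rotate_structure <- function(s, theta = 0.7, shift = c(5, -2, 7)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  out <- s
  for (a in 1:4) {
    out$coords[, a, ] <- s$coords[, a, ] %*% t(R) +
      rep(shift, each = s$L)
  }
  out
}

toy_alphabet <- function(A) make_alphabet(make_alphabet()$symbols[seq_len(A)])
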