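#' Sampler configuration
#'
#' Controls for the discrete MCMC samplers. Step units are sweeps: one
#' Discrete Langevin Monte Carlo (DLMC) step proposes all `L` sites jointly
#' and one Gibbs step is a full scan of `L` site updates, so defaults are
#' comparable between the two chains.
#'
#' @param temperature constant sampling temperature (ignored when
#'   `temperature_schedule` is given).
#' @param temperature_schedule optional vector of per-sweep temperatures;
#'   when supplied its length must equal the total number of sweeps
#'   (`burn_in + n_samples * thinning`).
#' @param dlmc_step_size DLMC step size; larger values make the factorized
#'   proposal less lazy (more likely to move each site).
#' @param mh_correction apply the Metropolis--Hastings correction so the
#'   chain targets `p(S) proportional to exp(-E/T)` exactly (default on).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param burn_in sweeps discarded before recording; default `10 * L`.
#' @param thinning record every `thinning`-th post-burn-in sweep.
#' @return A list of class `"sampler_config"`.
#' @export
sampler_config <- function(temperature = 1.0, temperature_schedule = NULL,
                           dlmc_step_size = 1.0, mh_correction = TRUE,
                           seed = NULL, burn_in = NULL, thinning = 1L) {
  stopifnot(temperature > 0, dlmc_step_size > 0, thinning >= 1)
  if (!is.null(burn_in)) stopifnot(burn_in >= 0)
  if (!is.null(temperature_schedule)) stopifnot(all(temperature_schedule > 0))
  structure(list(temperature = temperature,
                 temperature_schedule = temperature_schedule,
                 dlmc_step_size = dlmc_step_size,
                 mh_correction = isTRUE(mh_correction),
                 seed = seed, burn_in = burn_in,
                 thinning = as.integer(thinning)),
            class = "sampler_config")
}

#' Local composition perplexity (LCP) restraint configuration
#'
#' The LCP restraint penalizes low-complexity (repetitive) sequence
#' stretches during sampling. Every length-`window` stretch whose
#' pseudocount-smoothed composition perplexity `exp(H)` falls below
#' `p_min` contributes `(p_min - perplexity)^2` to the composite energy,
#' scaled by `lambda`.
#'
#' @param enabled logical.
#' @param window window width in residues (default 16).
#' @param p_min perplexity floor, in effective residue types
#'   (`1 <= p_min <= A`; default 8).
#' @param lambda restraint weight (default 1).
#' @param pseudocount smoothing pseudocount per residue type (default 0.1).
#' @return A list of class `"lcp_config"`.
#' @export
lcp_config <- function(enabled = TRUE, window = 16L, p_min = 8.0,
                       lambda = 1.0, pseudocount = 0.1) {
  stopifnot(window >= 1, p_min >= 1, lambda >= 0, pseudocount > 0)
  structure(list(enabled = isTRUE(enabled), window = as.integer(window),
                 p_min = p_min, lambda = lambda, pseudocount = pseudocount),
            class = "lcp_config")
}

#' Local composition perplexity penalty of a sequence
#'
#' Sum over all length-`window` windows of
#' `max(0, p_min - exp(H_window))^2`, where `H_window` is the natural-log
#' entropy of the window's pseudocount-smoothed residue composition. A
#' maximally diverse window has perplexity near `min(window, A)` and incurs
#' no penalty; a homopolymer window has perplexity near 1.
#'
#' @param s integer residue-index sequence.
#' @param cfg an [lcp_config()].
#' @param A alphabet size.
#' @return Nonnegative scalar (unweighted by `lambda`).
#' @export
lcp_penalty <- function(s, cfg, A) {
  s <- check_seq(s, A)
  L <- length(s)
  if (cfg$window > L) stop("LCP window is longer than the sequence")
  total <- 0
  for (start in seq_len(L - cfg$window + 1)) {
    win <- s[start:(start + cfg$window - 1)]
    cnt <- tabulate(win, nbins = A) + cfg$pseudocount
    p <- cnt / sum(cnt)
    perp <- exp(-sum(p * log(p)))
    total <- total + max(0, cfg$p_min - perp)^2
  }
  total
}

#' Composite sampling energy
#'
#' The target the samplers actually use: Potts energy plus
#' `lambda * lcp_penalty`. Equals the plain Potts energy when the LCP
#' restraint is disabled or `lambda = 0`.
#'
#' @param model a [potts_model()].
#' @param s integer sequence.
#' @param lcp an [lcp_config()].
#' @export
composite_energy <- function(model, s, lcp = lcp_config(enabled = FALSE)) {
  e <- potts_energy(model, s)
  if (lcp$enabled && lcp$lambda > 0) {
    e <- e + lcp$lambda * lcp_penalty(s, lcp, model$alphabet$size)
  }
  e
}

resolve_chain <- function(model, cfg, lcp, n_samples, init) {
  L <- model$L
  burn_in <- if (is.null(cfg$burn_in)) 10L * L else as.integer(cfg$burn_in)
  total <- burn_in + n_samples * cfg$thinning
  temps <- if (is.null(cfg$temperature_schedule)) {
    rep(cfg$temperature, total)
  } else {
    if (length(cfg$temperature_schedule) != total) {
      stop("temperature_schedule must have length burn_in + n_samples * thinning = ",
           total)
    }
    cfg$temperature_schedule
  }
  if (lcp$enabled && lcp$window > L) {
    stop("LCP window is longer than the sequence")
  }
  if (!is.null(init)) {
    init <- check_seq(init, model$alphabet$size, L)
  }
  list(burn_in = burn_in, total = total, temps = temps, init = init)
}

run_chain <- function(model, cfg, lcp, n_samples, init, kind) {
  stopifnot(inherits(model, "potts_model"), inherits(cfg, "sampler_config"),
            inherits(lcp, "lcp_config"), n_samples >= 1)
  ch <- resolve_chain(model, cfg, lcp, n_samples, init)
  body <- function() {
    init0 <- if (is.null(ch$init)) {
      sample.int(model$alphabet$size, model$L, replace = TRUE) - 1L
    } else {
      ch$init - 1L
    }
    edges0 <- if (nrow(model$edges)) model$edges - 1L else matrix(integer(), 0, 2)
    if (kind == "gibbs") {
      cpp_gibbs_chain(model$h, edges0, model$J, init0, as.integer(n_samples),
                      ch$burn_in, cfg$thinning, ch$temps, lcp$enabled,
                      lcp$window, lcp$p_min, lcp$lambda, lcp$pseudocount)
    } else {
      cpp_dlmc_chain(model$h, edges0, model$J, init0, as.integer(n_samples),
                     ch$burn_in, cfg$thinning, ch$temps, cfg$dlmc_step_size,
                     cfg$mh_correction, lcp$enabled, lcp$window, lcp$p_min,
                     lcp$lambda, lcp$pseudocount)
    }
  }
  res <- if (is.null(cfg$seed)) body() else withr::with_seed(cfg$seed, body())
  list(samples = res$samples + 1L,
       trace = structure(list(energy = as.numeric(res$energy),
                              acceptance_rate = res$acceptance_rate,
                              seed = cfg$seed, sampler = kind,
                              burn_in = ch$burn_in, thinning = cfg$thinning),
                         class = "sampler_trace"))
}

#' @export
print.sampler_trace <- function(x, ...) {
  cat("<sampler_trace>", x$sampler, "| recorded", length(x$energy),
      "| acceptance", format(x$acceptance_rate, digits = 3), "\n")
  invisible(x)
}

#' Sample sequences with Discrete Langevin Monte Carlo
#'
#' Each sweep proposes, independently per site, a categorical substitution
#' with probability proportional to
#' `exp(-Delta_i(a) / (2 T) - 1[a != s_i] / (2 * step_size))`, where
#' `Delta_i(a)` is the composite (Potts + LCP) energy change of the
#' single-site substitution. With `mh_correction` on, the joint proposal is
#' accepted or rejected with the standard reverse-proposal ratio, so the
#' chain targets `p(S) proportional to exp(-composite_energy(S)/T)` exactly.
#'
#' @param model a [potts_model()].
#' @param n_samples number of recorded (post-burn-in, thinned) states.
#' @param cfg a [sampler_config()].
#' @param lcp an [lcp_config()]; disabled by default.
#' @param init optional starting sequence; default uniform at random from
#'   the seeded RNG.
#' @return A list with `samples` (an `n_samples x L` integer matrix) and a
#'   `trace` recording composite energies, acceptance rate and seed.
#' @examples
#' m <- make_random_potts(4, 3, edge_density = 0.5, seed = 1)
#' out <- dlmc_sample(m, 100, sampler_config(seed = 7))
#' dim(out$samples)
#' @export
dlmc_sample <- function(model, n_samples, cfg = sampler_config(),
                        lcp = lcp_config(enabled = FALSE), init = NULL) {
  run_chain(model, cfg, lcp, n_samples, init, "dlmc")
}

#' Sample sequences with systematic-scan Gibbs
#'
#' Reference sampler targeting the same composite distribution as
#' [dlmc_sample()]: each sweep resamples every site from its full
#' conditional in a seeded random scan order.
#'
#' @inheritParams dlmc_sample
#' @return As [dlmc_sample()].
#' @export
gibbs_sample <- function(model, n_samples, cfg = sampler_config(),
                         lcp = lcp_config(enabled = FALSE), init = NULL) {
  run_chain(model, cfg, lcp, n_samples, init, "gibbs")
}

#' Combine per-structure logits by weighted averaging
#'
#' Softmax of the weighted mean of logit vectors. This equals the
#' renormalized weighted geometric mean (product of experts) of the per-set
#' softmax distributions, which is why tied autoregressive decoding with
#' averaged logits samples the geometric-mean next-token distribution.
#'
#' @param logits a `K x A` matrix (or list of length-`A` vectors) of finite
#'   logits.
#' @param weights optional simplex weights (default uniform).
#' @return Probability vector of length `A`.
#' @export
geometric_mean_combine <- function(logits, weights = NULL) {
  if (is.list(logits)) logits <- do.call(rbind, logits)
  logits <- as.matrix(logits)
  K <- nrow(logits)
  if (K == 0) stop("empty logit set")
  if (!all(is.finite(logits))) stop("logits must be finite")
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a length-K simplex vector")
  }
  mean_logit <- drop(crossprod(logits, weights))
  z <- exp(mean_logit - max(mean_logit))
  z / sum(z)
}

#' Tied autoregressive decoding over a model ensemble
#'
#' Decodes sites in the given order; at each site the per-model
#' full-conditional logits (negated local energies given all currently
#' assigned sites; unassigned sites contribute no coupling terms) are
#' combined with [geometric_mean_combine()] and a residue is drawn at the
#' configured temperature.
#'
#' @param models non-empty list of compatible [potts_model()] objects.
#' @param order a permutation of `1..L` giving the decoding order.
#' @param cfg a [sampler_config()] (temperature and seed are used).
#' @param weights optional per-model simplex weights.
#' @return An integer sequence of length `L`.
#' @export
tied_conditional_decode <- function(models, order = NULL,
                                    cfg = sampler_config(), weights = NULL) {
  if (length(models) == 0) stop("empty model list")
  L <- models[[1]]$L
  A <- models[[1]]$alphabet$size
  for (m in models) {
    if (m$L != L || !alphabets_equal(m$alphabet, models[[1]]$alphabet)) {
      stop("models must share L and alphabet")
    }
  }
  if (is.null(order)) order <- seq_len(L)
  if (!identical(sort(as.integer(order)), seq_len(L))) {
    stop("order must be a permutation of 1..L")
  }
  body <- function() {
    s <- integer(L)
    assigned <- logical(L)
    for (site in order) {
      logits <- matrix(0, length(models), A)
      for (k in seq_along(models)) {
        m <- models[[k]]
        loc <- m$h[site, ]
        if (nrow(m$edges) > 0) {
          for (e in seq_len(nrow(m$edges))) {
            i <- m$edges[e, 1]; j <- m$edges[e, 2]
            if (i == site && assigned[j]) loc <- loc + m$J[[e]][, s[j]]
            if (j == site && assigned[i]) loc <- loc + m$J[[e]][s[i], ]
          }
        }
        logits[k, ] <- -loc / cfg$temperature
      }
      p <- geometric_mean_combine(logits, weights)
      s[site] <- sample.int(A, 1, prob = p)
      assigned[site] <- TRUE
    }
    s
  }
  if (is.null(cfg$seed)) body() else withr::with_seed(cfg$seed, body())
}
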