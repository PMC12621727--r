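#' Network configuration
#'
#' Architecture of the toy graph network that maps a feature graph to a
#' Potts model: a stack of message-passing (MPNN-style) encoder layers
#' followed by decoder layers *without* a causal mask — the decoder sees
#' the whole structure at once, since the output is an energy model rather
#' than an autoregressive factorization. The default is 3 encoder + 3
#' decoder layers at hidden dimension 128; the `"L"` preset deepens the
#' stack to 5 + 5 layers at hidden dimension 256.
#'
#' @param n_encoder_layers,n_decoder_layers layer counts (defaults 3, 3).
#' @param hidden_dim embedding width (default 128).
#' @param alphabet output alphabet.
#' @param preset `NULL` or `"L"` (overrides layers/width).
#' @return A list of class `"network_config"`; `causal_mask` is always
#'   `FALSE`.
#' @export
network_config <- function(n_encoder_layers = 3L, n_decoder_layers = 3L,
                           hidden_dim = 128L, alphabet = make_alphabet(),
                           preset = NULL) {
  if (!is.null(preset)) {
    stopifnot(preset == "L")
    n_encoder_layers <- 5L; n_decoder_layers <- 5L; hidden_dim <- 256L
  }
  stopifnot(n_encoder_layers >= 1, n_decoder_layers >= 1, hidden_dim >= 1)
  structure(list(n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 hidden_dim = as.integer(hidden_dim),
                 alphabet = alphabet, causal_mask = FALSE),
            class = "network_config")
}

#' Initialize network parameters
#'
#' Message-passing weights are drawn once from seeded Gaussians at
#' `1/sqrt(fan_in)` scale and held fixed (a random-features encoder); the
#' Potts readout heads — a node-embedding projection to the `L x A` fields
#' and an edge-embedding projection to `A x A` coupling blocks — start at
#' zero and are the trainable parameters (see [train_potts_net()]).
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; equal seeds give bit-identical parameters.
#' @param feat_cfg the [featurizer_config()] the graphs will come from
#'   (fixes input feature dimensions).
#' @return A list of class `"network_params"` with a forward-pass counter.
#' @export
init_network <- function(cfg, seed = 1L, feat_cfg = featurizer_config()) {
  stopifnot(inherits(cfg, "network_config"))
  H <- cfg$hidden_dim
  A <- cfg$alphabet$size
  d_node <- 6L
  d_edge <- 16L * feat_cfg$rbf_count + 9L
  n_layers <- cfg$n_encoder_layers + cfg$n_decoder_layers
  gmat <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
  }
  weights <- withr::with_seed(seed, {
    list(
      Wn = gmat(d_node, H), bn = stats::rnorm(H, 0, 0.1),
      We = gmat(d_edge, H), be = stats::rnorm(H, 0, 0.1),
      layers = lapply(seq_len(n_layers), function(l) {
        list(Wm = gmat(3L * H, H), bm = numeric(H),
             Wu = gmat(3L * H, H), bu = numeric(H))
      })
    )
  })
  readout <- list(Wh = matrix(0, H, A), bh = numeric(A),
                  Wj = matrix(0, H, A * A), bj = numeric(A * A))
  structure(list(config = cfg, feat_cfg = feat_cfg, seed = as.integer(seed),
                 d_node = d_node, d_edge = d_edge,
                 weights = weights, readout = readout,
                 counter = new.env(parent = emptyenv())),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> layers =", x$config$n_encoder_layers, "+",
      x$config$n_decoder_layers, "| hidden =", x$config$hidden_dim,
      "| forward passes =", forward_pass_count(x), "\n")
  invisible(x)
}

#' @rdname init_network
#' @param params a `network_params` object.
#' @export
forward_pass_count <- function(params) {
  n <- params$counter$n
  if (is.null(n)) 0L else n
}

#' @rdname init_network
#' @export
reset_forward_pass_count <- function(params) {
  params$counter$n <- 0L
  invisible(params)
}

relu <- function(x) (x + abs(x)) / 2

# row-wise layer normalization (no learned affine terms)
layer_norm <- function(x) {
  mu <- rowMeans(x)
  sd <- sqrt(rowMeans((x - mu)^2) + 1e-8)
  (x - mu) / sd
}

# one forward evaluation: node embeddings (L x H) and directed-edge
# embeddings ((L*k) x H, slots column-major over the neighbor table)
net_forward <- function(params, g) {
  w <- params$weights
  if (ncol(g$node_features) != params$d_node ||
      dim(g$edge_features)[3] != params$d_edge) {
    stop("feature graph dimensions do not match the network configuration")
  }
  L <- g$L; k <- ncol(g$neighbors)
  idx_i <- rep(seq_len(L), times = k)
  idx_j <- as.vector(g$neighbors)
  Eflat <- matrix(g$edge_features, L * k, params$d_edge)
  Hn <- sweep(g$node_features %*% w$Wn, 2, w$bn, `+`)
  Ee <- sweep(Eflat %*% w$We, 2, w$be, `+`)
  for (layer in w$layers) {
    cat3 <- cbind(Hn[idx_i, , drop = FALSE], Hn[idx_j, , drop = FALSE], Ee)
    M <- relu(sweep(cat3 %*% layer$Wm, 2, layer$bm, `+`))
    Hn <- layer_norm(Hn + rowsum(M, idx_i, reorder = TRUE) / k)
    cat3 <- cbind(Hn[idx_i, , drop = FALSE], Hn[idx_j, , drop = FALSE], Ee)
    Ee <- layer_norm(Ee + relu(sweep(cat3 %*% layer$Wu, 2, layer$bu, `+`)))
  }
  list(Hn = Hn, Ee = Ee, idx_i = idx_i, idx_j = idx_j)
}

# bookkeeping for mapping directed neighbor slots to undirected edges
edge_bookkeeping <- function(g) {
  L <- g$L; k <- ncol(g$neighbors)
  idx_i <- rep(seq_len(L), times = k)
  idx_j <- as.vector(g$neighbors)
  lo <- pmin(idx_i, idx_j); hi <- pmax(idx_i, idx_j)
  key <- paste(lo, hi, sep = "-")
  ukey <- unique(key)
  edge_id <- match(key, ukey)
  parts <- do.call(rbind, strsplit(ukey, "-", fixed = TRUE))
  edges <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
  list(edges = edges, edge_id = edge_id, forward = idx_i == lo,
       n_dir = as.vector(table(factor(edge_id, levels = seq_along(ukey)))))
}

#' Predict a Potts model from a feature graph
#'
#' A single forward pass: fields come from the node-embedding projection
#' (`L x A`); each undirected graph edge `{i, j}` gets one `A x A`
#' coupling block from a symmetrized edge-embedding projection — the
#' direction-wise projections are transposed into the `(smaller, larger)`
#' axis convention and averaged, so the stored blocks satisfy
#' `J(i,j)[a,b] = J(j,i)[b,a]` exactly.
#'
#' @param params a [init_network()] object.
#' @param g a [featurize()] graph.
#' @return A [potts_model()].
#' @export
predict_potts <- function(params, g) {
  stopifnot(inherits(params, "network_params"),
            inherits(g, "feature_graph"))
  params$counter$n <- forward_pass_count(params) + 1L
  fw <- net_forward(params, g)
  ro <- params$readout
  A <- params$config$alphabet$size
  h <- sweep(fw$Hn %*% ro$Wh, 2, ro$bh, `+`)
  bk <- edge_bookkeeping(g)
  Bflat <- sweep(fw$Ee %*% ro$Wj, 2, ro$bj, `+`)
  J <- vector("list", nrow(bk$edges))
  for (e in seq_along(J)) J[[e]] <- matrix(0, A, A)
  for (slot in seq_along(bk$edge_id)) {
    e <- bk$edge_id[slot]
    B <- matrix(Bflat[slot, ], A, A)   # rows: residue at the source site
    J[[e]] <- J[[e]] + (if (bk$forward[slot]) B else t(B)) / bk$n_dir[e]
  }
  potts_model(h, bk$edges, J, params$config$alphabet)
}

#' Pseudolikelihood loss of a sequence under a Potts model
#'
#' The sitewise negative log conditional likelihood
#' `-(1/L) sum_i log p(s_i | s_{-i})`, where each conditional is the
#' softmax of the negated single-site substitution energies. A zero model
#' gives exactly `log(A)`.
#'
#' @param model a [potts_model()].
#' @param s integer sequence.
#' @return Nonnegative scalar.
#' @export
pseudolikelihood_loss <- function(model, s) {
  s <- check_seq(s, model$alphabet$size, model$L)
  total <- 0
  for (i in seq_len(model$L)) {
    loc <- site_local_energies(model, s, i)
    total <- total + loc[s[i]] + log_sum_exp(-loc)
  }
  total / model$L
}

# gradient of pseudolikelihood loss wrt h (L x A) and per-edge blocks
pll_gradients <- function(model, s) {
  L <- model$L; A <- model$alphabet$size
  gh <- matrix(0, L, A)
  gJ <- lapply(seq_len(nrow(model$edges)), function(k) matrix(0, A, A))
  for (i in seq_len(L)) {
    loc <- site_local_energies(model, s, i)
    cond <- exp(-loc - log_sum_exp(-loc))
    g <- -cond / L
    g[s[i]] <- g[s[i]] + 1 / L
    gh[i, ] <- g
  }
  if (nrow(model$edges) > 0) {
    for (k in seq_len(nrow(model$edges))) {
      i <- model$edges[k, 1]; j <- model$edges[k, 2]
      gJ[[k]][, s[j]] <- gJ[[k]][, s[j]] + gh[i, ]
      gJ[[k]][s[i], ] <- gJ[[k]][s[i], ] + gh[j, ]
    }
  }
  list(gh = gh, gJ = gJ)
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.05).
#' @param epochs full passes over the dataset (default 200).
#' @param batch_size items per gradient step; `NULL` (default) uses the
#'   full dataset per step.
#' @param seed RNG seed for shuffling/validation split.
#' @param weight_decay L2 penalty on the readout weights (default 1e-4).
#' @param validation_fraction fraction of items held out for the
#'   validation-loss history (default 0).
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 200L,
                         batch_size = NULL, seed = 1L, weight_decay = 1e-4,
                         validation_fraction = 0) {
  stopifnot(learning_rate > 0, epochs >= 1, weight_decay >= 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed),
                 weight_decay = weight_decay,
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Train the Potts readout by pseudolikelihood
#'
#' Minimizes the mean [pseudolikelihood_loss()] of [predict_potts()]
#' outputs against the paired sequences with Adam. The message-passing
#' embeddings are fixed, so they are computed once per distinct graph and
#' cached; only the field/coupling readout heads are updated, making the
#' optimization a (regularized) convex fit in a random-feature basis.
#'
#' @param params a [init_network()] object.
#' @param dataset non-empty list of items, each a list with elements
#'   `graph` (a [featurize()] output) and `seq` (integer sequence).
#' @param cfg a [train_config()].
#' @return A list with `params` (trained) and `history` (per-epoch mean
#'   training loss, plus `val_loss` when a validation split is used).
#' @export
train_potts_net <- function(params, dataset, cfg = train_config()) {
  stopifnot(inherits(params, "network_params"), length(dataset) >= 1)
  A <- params$config$alphabet$size
  # cache embeddings and edge bookkeeping per item (encoder is fixed)
  cache <- lapply(dataset, function(item) {
    fw <- net_forward(params, item$graph)
    bk <- edge_bookkeeping(item$graph)
    ndir <- bk$n_dir[bk$edge_id]
    list(Hn = fw$Hn, Ee = fw$Ee, bk = bk, ndir = ndir,
         seq = check_seq(item$seq, A, item$graph$L))
  })
  n <- length(cache)
  split <- withr::with_seed(cfg$seed, {
    n_val <- floor(cfg$validation_fraction * n)
    if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  })
  train_idx <- setdiff(seq_len(n), split)
  ro <- params$readout
  state <- lapply(ro, function(x) list(m = 0 * x, v = 0 * x))
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  item_grads <- function(cc) {
    h <- sweep(cc$Hn %*% ro$Wh, 2, ro$bh, `+`)
    Bflat <- sweep(cc$Ee %*% ro$Wj, 2, ro$bj, `+`)
    J <- vector("list", nrow(cc$bk$edges))
    for (e in seq_along(J)) J[[e]] <- matrix(0, A, A)
    for (slot in seq_along(cc$bk$edge_id)) {
      e <- cc$bk$edge_id[slot]
      B <- matrix(Bflat[slot, ], A, A)
      J[[e]] <- J[[e]] + (if (cc$bk$forward[slot]) B else t(B)) / cc$ndir[slot]
    }
    model <- potts_model(h, cc$bk$edges, J, params$config$alphabet)
    gr <- pll_gradients(model, cc$seq)
    # map the undirected block gradients back to directed slots;
    # potts_model() sorted the edges, so undo that permutation first
    reorder <- order(cc$bk$edges[, 1], cc$bk$edges[, 2])
    gJ_by_edge <- vector("list", length(gr$gJ))
    gJ_by_edge[reorder] <- gr$gJ   # potts_model() sorted the edges
    gB <- matrix(0, nrow(Bflat), ncol(Bflat))
    for (slot in seq_along(cc$bk$edge_id)) {
      e <- cc$bk$edge_id[slot]
      gblk <- gJ_by_edge[[e]] / cc$ndir[slot]
      gB[slot, ] <- as.vector(if (cc$bk$forward[slot]) gblk else t(gblk))
    }
    list(loss = pseudolikelihood_loss(model, cc$seq),
         gWh = crossprod(cc$Hn, gr$gh), gbh = colSums(gr$gh),
         gWj = crossprod(cc$Ee, gB), gbj = colSums(gB))
  }

  eval_loss <- function(idx) {
    mean(vapply(cache[idx], function(cc) item_grads(cc)$loss, 0))
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  batches <- function(idx) {
    if (is.null(cfg$batch_size) || cfg$batch_size >= length(idx)) {
      list(idx)
    } else {
      split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    }
  }
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(train_idx)
      epoch_loss <- 0
      for (batch in batches(idx)) {
        acc <- NULL
        for (ii in batch) {
          gr <- item_grads(cache[[ii]])
          if (is.null(acc)) {
            acc <- gr
          } else {
            for (nm in c("loss", "gWh", "gbh", "gWj", "gbj")) {
              acc[[nm]] <- acc[[nm]] + gr[[nm]]
            }
          }
        }
        nb <- length(batch)
        if (!is.finite(acc$loss)) stop("non-finite training loss")
        epoch_loss <- epoch_loss + acc$loss
        grads <- list(Wh = acc$gWh / nb + cfg$weight_decay * ro$Wh,
                      bh = acc$gbh / nb,
                      Wj = acc$gWj / nb + cfg$weight_decay * ro$Wj,
                      bj = acc$gbj / nb)
        t_step <- t_step + 1
        for (nm in names(grads)) {
          state[[nm]]$m <- b1 * state[[nm]]$m + (1 - b1) * grads[[nm]]
          state[[nm]]$v <- b2 * state[[nm]]$v + (1 - b2) * grads[[nm]]^2
          mhat <- state[[nm]]$m / (1 - b1^t_step)
          vhat <- state[[nm]]$v / (1 - b2^t_step)
          ro[[nm]] <- ro[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epoch_loss / length(idx),
        val_loss = if (length(split)) eval_loss(split) else NA_real_))
    }
  })
  params$readout <- ro
  list(params = params, history = history)
}

#' Recovery of a native sequence from Potts conditionals
#'
#' Fraction of sites where the argmax of the full conditional
#' `p(s_i | s_{-i})` (native context) equals the native residue — the
#' deterministic per-site recovery proxy used on the synthetic datasets.
#'
#' @param model a [potts_model()].
#' @param s the native integer sequence.
#' @return Fraction in `[0, 1]`.
#' @export
conditional_recovery <- function(model, s) {
  s <- check_seq(s, model$alphabet$size, model$L)
  hits <- vapply(seq_len(model$L), function(i) {
    which.min(site_local_energies(model, s, i)) == s[i]
  }, logical(1))
  mean(hits)
}

#' Design an ensemble-averaged Potts model
#'
#' Featurizes every member of the ensemble, predicts a Potts model for
#' each with exactly one forward pass per member (`K` passes total,
#' independent of how many sequences are sampled afterwards), and averages
#' the models with uniform weights.
#'
#' @param params a [init_network()] object.
#' @param e a [structure_ensemble()].
#' @param fcfg a [featurizer_config()].
#' @return A list with `model` (the averaged [potts_model()]) and
#'   `forward_pass_count` (`== K`).
#' @export
design_for_ensemble <- function(params, e, fcfg = featurizer_config()) {
  stopifnot(inherits(e, "structure_ensemble"))
  members <- c(list(e$reference), e$conformers)
  before <- forward_pass_count(params)
  models <- lapply(members, function(s) predict_potts(params, featurize(s, fcfg)))
  list(model = average_models(models),
       forward_pass_count = forward_pass_count(params) - before)
}

#' Save and load network checkpoints
#'
#' Versioned, self-describing checkpoints (config echo, feature
#' dimensions, init seed, all weight arrays) written with `saveRDS`.
#' Round-trips are bit-exact.
#'
#' @param params a [init_network()] object.
#' @param path file path.
#' @export
save_checkpoint <- function(params, path) {
  obj <- list(format = "ensdesign_checkpoint", version = "1",
              config = params$config, feat_cfg = params$feat_cfg,
              seed = params$seed, d_node = params$d_node,
              d_edge = params$d_edge, weights = params$weights,
              readout = params$readout)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ensdesign_checkpoint")) {
    stop("not an ensdesign checkpoint: ", path)
  }
  structure(list(config = obj$config, feat_cfg = obj$feat_cfg,
                 seed = obj$seed, d_node = obj$d_node, d_edge = obj$d_edge,
                 weights = obj$weights, readout = obj$readout,
                 counter = new.env(parent = emptyenv())),
            class = "network_params")
}
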