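#' Specify an end-to-end design job
#'
#' One job designs `n_sequences` sequences for one input backbone (or
#' ensemble) and writes a FASTA plus a JSON run manifest. Exactly one
#' ensemble mode applies: `"single"` (the input structure alone),
#' `"files"` (explicit conformer PDB paths), `"multimodel"` (all MODELs of
#' the input file), or `"gaussian"` (Gaussian-noise conformers with
#' `gaussian_sigma` and `n_conformers`). The scoring model comes either
#' from a network checkpoint (per-conformer prediction then averaging) or
#' from a raw Potts JSON file (sampled as-is).
#'
#' @param pdb input backbone PDB path.
#' @param ensemble_mode one of `"single"`, `"files"`, `"multimodel"`,
#'   `"gaussian"`.
#' @param ensemble_files conformer PDB paths (mode `"files"`).
#' @param gaussian_sigma,n_conformers Gaussian mode parameters (defaults
#'   1 Angstrom, `K = 16` total).
#' @param checkpoint network checkpoint path or a `network_params` object.
#' @param potts_json raw Potts JSON path (alternative to `checkpoint`;
#'   `pdb` may then be `NULL`).
#' @param sampler,lcp sampler and restraint configs.
#' @param feat_cfg featurizer config for network-backed jobs.
#' @param n_sequences designs to emit (default 8).
#' @param seed integer seed controlling all stochastic stages.
#' @param out output FASTA path.
#' @param manifest output manifest JSON path (default `out` with
#'   `.manifest.json`).
#' @return A list of class `"design_job"`.
#' @export
design_job <- function(pdb = NULL, ensemble_mode = c("single", "files",
                                                     "multimodel", "gaussian"),
                       ensemble_files = NULL, gaussian_sigma = 1.0,
                       n_conformers = 16L, checkpoint = NULL,
                       potts_json = NULL, sampler = sampler_config(),
                       lcp = lcp_config(enabled = FALSE),
                       feat_cfg = featurizer_config(), n_sequences = 8L,
                       seed = 0L, out = "designs.fasta", manifest = NULL) {
  ensemble_mode <- match.arg(ensemble_mode)
  if (is.null(checkpoint) == is.null(potts_json)) {
    stop("provide exactly one of checkpoint or potts_json")
  }
  if (is.null(potts_json) && is.null(pdb)) {
    stop("network-backed jobs need an input pdb")
  }
  if (ensemble_mode == "files" && length(ensemble_files) == 0) {
    stop("ensemble_mode 'files' needs ensemble_files")
  }
  stopifnot(n_sequences >= 1, n_conformers >= 1, gaussian_sigma >= 0)
  if (is.null(manifest)) manifest <- paste0(out, ".manifest.json")
  structure(list(pdb = pdb, ensemble_mode = ensemble_mode,
                 ensemble_files = ensemble_files,
                 gaussian_sigma = gaussian_sigma,
                 n_conformers = as.integer(n_conformers),
                 checkpoint = checkpoint, potts_json = potts_json,
                 sampler = sampler, lcp = lcp, feat_cfg = feat_cfg,
                 n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed), out = out, manifest = manifest),
            class = "design_job")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("design stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run a design job end to end
#'
#' Pipeline: read structure(s), assemble the ensemble, derive one Potts
#' model per conformer and average them (network jobs) or load a raw Potts
#' JSON, sample `n_sequences` with DLMC under the configured restraint,
#' rank by composite energy (best first), and write FASTA plus a JSON
#' manifest recording the config echo, seed, per-design composite
#' energies, `forward_pass_count`, and `ensemble_diversity`. Identical
#' jobs with identical seeds produce identical outputs. Selection by
#' external folding metrics is deliberately downstream of this tool.
#'
#' @param job a [design_job()].
#' @return Invisibly, a list with `seqs`, `energies`, `manifest`.
#' @export
run_design <- function(job) {
  stopifnot(inherits(job, "design_job"))
  diversity <- NA_real_
  fpc <- 0L
  if (!is.null(job$potts_json)) {
    model <- stage("load-potts", read_potts_json(job$potts_json))
    K <- 1L
  } else {
    ensemble <- stage("ensemble", build_job_ensemble(job))
    K <- ensemble$K
    if (K >= 2) diversity <- ensemble_diversity(ensemble)
    params <- stage("checkpoint", {
      if (inherits(job$checkpoint, "network_params")) job$checkpoint
      else load_checkpoint(job$checkpoint)
    })
    des <- stage("predict", design_for_ensemble(params, ensemble, job$feat_cfg))
    model <- des$model
    fpc <- des$forward_pass_count
  }
  cfg <- job$sampler
  cfg$seed <- job$seed
  out <- stage("sample", dlmc_sample(model, job$n_sequences, cfg, job$lcp))
  energies <- apply(out$samples, 1, composite_energy, model = model,
                    lcp = job$lcp)
  ord <- order(energies)
  seqs <- out$samples[ord, , drop = FALSE]
  energies <- energies[ord]
  stage("write", {
    write_fasta_designs(seqs, job$out, model$alphabet, energies,
                        K = K, seed = job$seed)
    manifest <- list(
      tool = "ensdesign", version = "0.1.0",
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = job$seed, ensemble_mode = job$ensemble_mode, K = K,
      n_sequences = job$n_sequences,
      forward_pass_count = fpc,
      ensemble_diversity = diversity,
      energies = energies,
      sampler = unclass(job$sampler), lcp = unclass(job$lcp),
      inputs = list(pdb = job$pdb, potts_json = job$potts_json,
                    ensemble_files = job$ensemble_files,
                    gaussian_sigma = job$gaussian_sigma)
    )
    jsonlite::write_json(manifest, job$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  })
  invisible(list(seqs = seqs, energies = energies,
                 manifest = job$manifest))
}

build_job_ensemble <- function(job) {
  first <- read_backbone_pdb(job$pdb)
  is_single <- inherits(first, "backbone_structure")
  if (job$ensemble_mode == "multimodel") {
    if (is_single) stop("multimodel mode needs a multi-MODEL pdb")
    return(structure_ensemble(first[[1]], first[-1]))
  }
  ref <- if (is_single) first else first[[1]]
  switch(job$ensemble_mode,
    single = structure_ensemble(ref),
    gaussian = gaussian_ensemble(ref, job$gaussian_sigma,
                                 K = job$n_conformers, seed = job$seed),
    files = {
      conf <- lapply(job$ensemble_files, function(p) {
        s <- read_backbone_pdb(p)
        if (inherits(s, "backbone_structure")) s else s[[1]]
      })
      structure_ensemble(ref, conf)
    })
}
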