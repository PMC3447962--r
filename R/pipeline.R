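#' Assemble a pipeline run configuration
#'
#' A run configuration drives [run_full()]: the input structure (a PDB
#' path plus domain map, or a toy-structure recipe), the sampling
#' protocol, the q grid, one experimental curve per condition, and the
#' analysis parameters. Every default is echoed into the run manifest so
#' a run is self-describing.
#'
#' @param structure list: either `list(pdb = path, domain_map = list(...))`
#'   or `list(toy = list(n_domains, atoms_per_domain, linker_length,
#'   seed))`.
#' @param conditions named list/character vector of experimental curve
#'   file paths, one per condition.
#' @param outdir output directory.
#' @param sampler list of [sampler_params()] overrides.
#' @param qgrid list: n, qmin, qmax (default 100 points, 0.01-0.18 1/A).
#' @param mode form-factor mode, "vacuum" or "solvent".
#' @param filter_fraction low-chi2 filter fraction (default 0.05).
#' @param bin_width,prominence_frac P(Rg) histogram parameters.
#' @param n_peaks,k_per_peak,min_rmsd representative selection parameters.
#' @param weight_step ensemble weight grid spacing (default 0.1).
#' @param conformer_source "sampled" (Langevin SBM run; default) or
#'   "hinge" (geometric conformer family, mainly for fast smoke runs).
#' @param n_conformers conformer count for hinge mode.
#' @param n_runs number of independent sampling runs pooled into the
#'   candidate set (default 1). With more than one run, the starts are
#'   spread over a hinge-opened series of the input structure so the pool
#'   covers compact through extended shapes even when a single run would
#'   mix slowly.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(structure, conditions, outdir,
                       sampler = list(), qgrid = list(),
                       mode = "vacuum", filter_fraction = 0.05,
                       bin_width = 0.25, prominence_frac = 0.05,
                       n_peaks = 3, k_per_peak = 4, min_rmsd = 2,
                       weight_step = 0.1, conformer_source = "sampled",
                       n_conformers = 200, n_runs = 1L, seed = 1L) {
  if (filter_fraction <= 0 || filter_fraction >= 1)
    stop("filter_fraction must be in (0, 1)")
  conditions <- as.list(conditions)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    names(conditions) <- paste0("condition", seq_along(conditions))
  for (f in conditions)
    if (!file.exists(f)) stop("experimental curve not found: ", f)
  sp <- utils::modifyList(unclass(sampler_params()), sampler)
  qg <- utils::modifyList(list(n = 100, qmin = 0.01, qmax = 0.18), qgrid)
  structure(list(structure = structure, conditions = conditions,
                 outdir = outdir, sampler = sp, qgrid = qg, mode = mode,
                 filter_fraction = filter_fraction, bin_width = bin_width,
                 prominence_frac = prominence_frac, n_peaks = n_peaks,
                 k_per_peak = k_per_peak, min_rmsd = min_rmsd,
                 weight_step = weight_step,
                 conformer_source = conformer_source,
                 n_conformers = n_conformers, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.PIPELINE_STAGES <- c("topology", "sampling", "profiles", "analysis",
                      "crosstab")

.state_path <- function(outdir, stage) {
  file.path(outdir, "state", paste0(stage, ".rds"))
}

.save_state <- function(obj, outdir, stage) {
  dir.create(file.path(outdir, "state"), showWarnings = FALSE,
             recursive = TRUE)
  p <- .state_path(outdir, stage)
  saveRDS(obj, p, compress = FALSE)
  p
}

.hash_file <- function(p) unname(tools::md5sum(p))

#' Run the full ensemble-analysis pipeline
#'
#' Executes every stage for each condition against one shared conformer
#' pool (the same simulation serves all conditions): build the
#' structure-based topology, sample candidate conformations, compute
#' theoretical profiles, then per condition score with chi2, apply the
#' low-chi2 filter, build P(Rg), select per-peak representatives, search
#' weighted candidate ensembles, and finally assemble the cross-condition
#' fit table. Writes curves (.dat), structures (PDB), tables (TSV) and a
#' YAML manifest with per-stage provenance (parameters, seeds, counts,
#' output hashes) under `config$outdir`. Any stage failure aborts with the
#' stage name; completed stage outputs are preserved for [resume_run()].
#'
#' @param config a [run_config()] (or the path of a YAML config file).
#' @param from internal: first stage to (re)compute; earlier stages are
#'   loaded from saved state.
#' @return list of class `pipeline_result`: per-condition fits, P(Rg)
#'   histograms, representative sets, the cross-table and the manifest.
#' @export
run_full <- function(config, from = "topology") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  from_i <- match(from, .PIPELINE_STAGES)
  if (is.na(from_i)) stop("unknown stage: ", from)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sbmsaxs",
                   config = .config_as_list(config),
                   stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[stage]] <<- list(
      outputs = lapply(outputs, .hash_file), counts = counts)
  }
  run_stage <- function(stage, fun) {
    i <- match(stage, .PIPELINE_STAGES)
    sp <- .state_path(outdir, stage)
    if (i < from_i) {
      if (!file.exists(sp))
        stop("stage '", stage, "': no saved state to resume from")
      return(readRDS(sp))
    }
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .save_state(out, outdir, stage)
    out
  }

  ## stage 1: topology
  topo_st <- run_stage("topology", function() {
    s <- if (!is.null(config$structure$pdb))
      read_pdb(config$structure$pdb, config$structure$domain_map)
    else do.call(toy_multidomain, config$structure$toy)
    topo <- build_topology(s)
    tp <- file.path(outdir, "topology.top")
    write_topology(topo, tp)
    list(structure = s, topo = topo, file = tp)
  })
  note("topology", list(topology = topo_st$file),
       list(n_atoms = topo_st$topo$n_atoms,
            n_contacts = nrow(topo_st$topo$contacts)))

  ## stage 2: sampling (shared pool for all conditions)
  samp_st <- run_stage("sampling", function() {
    cs <- if (identical(config$conformer_source, "hinge")) {
      conformer_family(topo_st$structure, config$n_conformers,
                       mode = "hinge", seed = config$seed)
    } else if (config$n_runs > 1L) {
      starts <- conformer_family(topo_st$structure, config$n_runs,
                                 mode = "hinge", seed = config$seed)
      runs <- lapply(seq_len(config$n_runs), function(i) {
        sp <- do.call(sampler_params, config$sampler)
        sp$seed <- sp$seed + i - 1L
        run_sampling(topo_st$topo, starts$frames[[i]], sp)
      })
      bind_conformations(runs)
    } else {
      run_sampling(topo_st$topo, topo_st$structure,
                   do.call(sampler_params, config$sampler))
    }
    pf <- file.path(outdir, "conformers.pdb")
    write_pdb(cs, pf)
    list(cs = cs, file = pf)
  })
  note("sampling", list(conformers = samp_st$file),
       list(n_conformers = length(samp_st$cs)))

  ## stage 3: theoretical profiles on the shared q grid
  qgrid <- default_qgrid(config$qgrid$n, config$qgrid$qmin,
                         config$qgrid$qmax)
  prof_st <- run_stage("profiles", function() {
    list(curves = profile_set(samp_st$cs, qgrid, config$mode))
  })
  note("profiles", list(), list(n_curves = length(prof_st$curves),
                                n_q = length(qgrid)))

  ## stage 4: per-condition scoring, filtering, P(Rg), picks, fits
  ana_st <- run_stage("analysis", function() {
    lapply(names(config$conditions), function(cond) {
      exp_curve <- read_curve(config$conditions[[cond]])
      if (length(exp_curve$q) != length(qgrid) ||
          max(abs(exp_curve$q - qgrid)) > 1e-9)
        stop("condition '", cond,
             "': experimental grid does not match the configured q grid")
      cset <- score_candidates(samp_st$cs, exp_curve,
                               curves = prof_st$curves)
      kept <- filter_lowest(cset, config$filter_fraction)
      hist <- prg_histogram(kept, config$bin_width,
                            config$prominence_frac)
      reps <- select_representatives(kept, hist,
                                     n_peaks = config$n_peaks,
                                     k_per_peak = config$k_per_peak,
                                     min_rmsd = config$min_rmsd)
      fit <- combination_search(exp_curve, reps,
                                step = config$weight_step)
      # tabular outputs
      ct <- file.path(outdir, paste0(cond, "_chi2.tsv"))
      utils::write.table(
        data.frame(frame = cset$frame_index, rg = cset$rg,
                   chi2 = cset$chi2, scale = cset$scale),
        ct, sep = "\t", row.names = FALSE, quote = FALSE)
      ht <- file.path(outdir, paste0(cond, "_prg.tsv"))
      utils::write.table(
        data.frame(rg_mid = hist$mids, prob = hist$prob),
        ht, sep = "\t", row.names = FALSE, quote = FALSE)
      rp <- file.path(outdir, paste0(cond, "_representatives.pdb"))
      write_pdb(subset_conformations(kept$conformations,
                                     unlist(reps$groups)), rp)
      ft <- file.path(outdir, paste0(cond, "_fit.yaml"))
      yaml::write_yaml(list(condition = cond,
                            members = fit$member_ids,
                            weights = as.numeric(fit$weights),
                            scale = fit$scale, chi2 = fit$chi2,
                            ensembles_evaluated =
                              attr(fit, "n_combinations")), ft)
      list(condition = cond, exp_curve = exp_curve, cset = cset,
           kept = kept, hist = hist, reps = reps, fit = fit,
           files = c(chi2 = ct, prg = ht, representatives = rp,
                     fit = ft))
    })
  })
  for (a in ana_st)
    note(paste0("analysis:", a$condition), as.list(a$files),
         list(n_scored = length(a$cset), n_kept = length(a$kept),
              n_peaks = nrow(a$hist$peaks),
              n_ensembles = attr(a$fit, "n_combinations")))

  ## stage 5: cross-condition fit table
  xtab_st <- run_stage("crosstab", function() {
    fits <- lapply(ana_st, `[[`, "fit")
    names(fits) <- vapply(ana_st, `[[`, character(1), "condition")
    exps <- lapply(ana_st, `[[`, "exp_curve")
    names(exps) <- names(fits)
    xt <- cross_table(fits, exps)
    xf <- file.path(outdir, "cross_table.tsv")
    utils::write.table(xt, xf, sep = "\t", quote = FALSE,
                       col.names = NA)
    list(table = xt, file = xf)
  })
  note("crosstab", list(cross_table = xtab_st$file),
       list(n_conditions = length(ana_st)))

  mf <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  res <- list(conditions = ana_st, cross_table = xtab_st$table,
              manifest = manifest, manifest_file = mf,
              config = config)
  class(res) <- "pipeline_result"
  res
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$conditions <- lapply(out$conditions, as.character)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$conditions), "condition(s)\n")
  for (a in x$conditions) {
    cat(sprintf("  %s: chi2 = %.4g, weights = %s\n", a$condition,
                a$fit$chi2,
                paste(format(a$fit$weights, digits = 3),
                      collapse = ", ")))
  }
  cat("cross-table:\n")
  print(round(x$cross_table, 3))
  invisible(x)
}

#' Resume a pipeline run from a given stage
#'
#' Verifies (by md5) that the saved outputs of every stage before `from`
#' still match the manifest, then recomputes from `from` onward only. A
#' tampered upstream output is refused; resuming a completed run from
#' beyond the last stage is a no-op that returns the stored result.
#'
#' @param manifest_file path to a `manifest.yaml` written by [run_full()].
#' @param from stage name: one of topology, sampling, profiles, analysis,
#'   crosstab; NULL re-verifies only.
#' @param config optional [run_config()] overriding the stored one (e.g.
#'   with a changed weight step when resuming at the analysis stage).
#' @return a `pipeline_result`.
#' @export
resume_run <- function(manifest_file, from = NULL, config = NULL) {
  man <- yaml::read_yaml(manifest_file)
  stored <- man$config
  if (is.null(config)) {
    stored$structure <- stored$structure
    config <- do.call(run_config, stored[setdiff(names(stored), NULL)])
  }
  outdir <- config$outdir
  upto <- if (is.null(from)) length(.PIPELINE_STAGES) + 1L
          else match(from, .PIPELINE_STAGES)
  if (is.na(upto)) stop("unknown stage: ", from)
  # verify upstream outputs
  for (st in names(man$stages)) {
    base <- sub(":.*$", "", st)
    i <- match(base, .PIPELINE_STAGES)
    if (!is.na(i) && i < upto) {
      for (nm in names(man$stages[[st]]$outputs)) {
        h_old <- man$stages[[st]]$outputs[[nm]]
        # locate the file: manifest stores hashes keyed by short names
        f <- .manifest_output_path(outdir, st, nm)
        if (!file.exists(f) || !identical(unname(tools::md5sum(f)), h_old))
          stop("refusing to resume: output '", nm, "' of stage '", st,
               "' is missing or was modified after the recorded run")
      }
    }
  }
  if (is.null(from)) {
    # completed run: recompute nothing, reload final state
    return(run_full(config, from = "crosstab"))
  }
  run_full(config, from = from)
}

.manifest_output_path <- function(outdir, stage, name) {
  cond <- sub("^analysis:", "", stage)
  switch(name,
         topology = file.path(outdir, "topology.top"),
         conformers = file.path(outdir, "conformers.pdb"),
         cross_table = file.path(outdir, "cross_table.tsv"),
         chi2 = file.path(outdir, paste0(cond, "_chi2.tsv")),
         prg = file.path(outdir, paste0(cond, "_prg.tsv")),
         representatives = file.path(outdir,
                                     paste0(cond, "_representatives.pdb")),
         fit = file.path(outdir, paste0(cond, "_fit.yaml")),
         file.path(outdir, name))
}
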