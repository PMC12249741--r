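#' Study configuration
#'
#' Bundles the conditions (one reference, usually the wild type, plus any
#' number of variants, each with one topology and one or more replicate
#' trajectories) and the protocol constants of the comparison: the DCCM
#' difference threshold (0.2), RMSIP subspace size (10), cosine-content PC
#' count (5) and convergence threshold (0.7), FEL binning and temperature
#' (300 K).
#'
#' @param conditions named list; each element is a list with `topology`
#'   (path) and `trajectories` (character vector of paths), or a list with
#'   `trajectory` objects under `traj_objects` (used programmatically and by
#'   the synthetic studies).
#' @param reference name of the reference condition (default `"wild"`).
#' @param selection analysis selection (default `"CA"`).
#' @param dccm_threshold absolute DCCM-difference threshold.
#' @param rmsip_k subspace size for RMSIP.
#' @param cosine_pcs,cosine_threshold convergence criterion: first
#'   `cosine_pcs` cosine contents must all fall below `cosine_threshold`.
#' @param fel_bins,fel_cutoff FEL grid bins per axis and basin depth cutoff
#'   (kcal/mol).
#' @param temperature kelvin.
#' @param run_sasa,run_dssp stage toggles (DSSP needs full backbones).
#' @param seed integer seed recorded in the provenance block.
#' @param out_dir output directory for TSV artifacts (`NULL` = no files).
#' @return object of class `study_config`.
#' @export
study_config <- function(conditions, reference = "wild", selection = "CA",
                         dccm_threshold = 0.2, rmsip_k = 10,
                         cosine_pcs = 5, cosine_threshold = 0.7,
                         fel_bins = 50, fel_cutoff = 1.0, temperature = 300,
                         run_sasa = FALSE, run_dssp = FALSE,
                         seed = 1L, out_dir = NULL) {
  if (length(conditions) < 1) rlang::abort("need at least one condition")
  if (!reference %in% names(conditions)) {
    rlang::abort(paste0("reference condition '", reference, "' not among conditions"))
  }
  structure(list(conditions = conditions, reference = reference,
                 selection = selection, dccm_threshold = dccm_threshold,
                 rmsip_k = rmsip_k, cosine_pcs = cosine_pcs,
                 cosine_threshold = cosine_threshold, fel_bins = fel_bins,
                 fel_cutoff = fel_cutoff, temperature = temperature,
                 run_sasa = run_sasa, run_dssp = run_dssp,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Flat key-value syntax; `conditions` maps condition names to `topology`
#' and `trajectories` entries. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  extra <- setdiff(names(y), known)
  if (length(extra) > 0) {
    rlang::abort(paste("unknown config keys:", paste(extra, collapse = ", ")))
  }
  do.call(study_config, y)
}

load_condition <- function(cond, name) {
  if (!is.null(cond$traj_objects)) {
    return(cond$traj_objects)
  }
  st <- read_structure(cond$topology)
  lapply(seq_along(cond$trajectories), function(i) {
    tr <- read_trajectory(cond$trajectories[[i]], st$topology,
                          label = name, replicate = i)
    tr$ref_xyz <- st$xyz
    tr
  })
}

#' Convergence check for one replicate
#'
#' Runs the essential-dynamics PCA and flags the replicate converged iff the
#' cosine contents of the first `pcs` PCs all fall below `threshold` (high
#' cosine content means the projection looks like random diffusion, i.e.
#' unconverged sampling). An RMSD plateau summary (mean and SD of the final
#' third of the series against the middle third) is attached.
#'
#' @param traj a [trajectory()].
#' @param pcs number of leading PCs to test (default 5).
#' @param threshold cosine-content threshold (default 0.7).
#' @param mask analysis selection.
#' @return tibble with `label`, `replicate`, `converged`, per-PC cosine
#'   contents (`cc1` ...), and plateau columns `rmsd_mid_mean`,
#'   `rmsd_final_mean`, `rmsd_final_sd`.
#' @export
check_convergence <- function(traj, pcs = 5, threshold = 0.7, mask = "CA") {
  es <- essential_dynamics(traj, mask)
  pcs <- min(pcs, ncol(es$projections))
  cc <- vapply(seq_len(pcs), function(i) cosine_content(es, i), numeric(1))
  rs <- rmsd_series(traj, mask)$value
  nf <- length(rs)
  mid <- rs[seq(floor(nf / 3) + 1, floor(2 * nf / 3))]
  fin <- rs[seq(floor(2 * nf / 3) + 1, nf)]
  out <- tibble::tibble(
    label = traj$label, replicate = traj$replicate,
    converged = all(cc < threshold),
    rmsd_mid_mean = mean(mid), rmsd_final_mean = mean(fin),
    rmsd_final_sd = stats::sd(fin)
  )
  for (i in seq_len(pcs)) out[[paste0("cc", i)]] <- cc[i]
  out
}

write_tsv_artifact <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full wild-vs-variant comparison study
#'
#' Per condition and replicate: convergence (cosine content + RMSD plateau),
#' RMSD/Rg (optionally SASA) series, RMSF, DCCM; per condition (replicates
#' averaged): DCCM difference against the reference with detected regions,
#' PCA with RMSIP against the reference, optional DSSP occupancy with
#' deltas, FEL with basin segmentation and a rank-1 basin report.
#' Deterministic given the config and inputs: rerunning yields a
#' byte-identical report body. Stage failures are caught, marked in
#' `$failed`, and do not stop independent stages.
#'
#' @param config a [study_config()].
#' @return object of class `comparison_report` (a nested list; see
#'   [write_report_json()]).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  conds <- names(config$conditions)
  report <- list(provenance = list(
    package = "mdcompare",
    version = as.character(utils::packageVersion("mdcompare")),
    reference = config$reference,
    selection = config$selection,
    seed = config$seed,
    settings = config[c("dccm_threshold", "rmsip_k", "cosine_pcs",
                        "cosine_threshold", "fel_bins", "fel_cutoff",
                        "temperature")]
  ))
  failed <- character()
  trajs <- lapply(conds, function(nm) load_condition(config$conditions[[nm]], nm))
  names(trajs) <- conds
  per_cond <- list()
  dccms <- list(); subspaces <- list(); occupancies <- list()
  for (nm in conds) {
    cc <- list()
    reps <- trajs[[nm]]
    stage <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        failed <<- c(failed, paste0(nm, ":", label, ": ", conditionMessage(e)))
        NULL
      })
    }
    conv <- stage("convergence", dplyr::bind_rows(lapply(
      reps, check_convergence, pcs = config$cosine_pcs,
      threshold = config$cosine_threshold, mask = config$selection)))
    cc$convergence <- conv
    metrics <- stage("metrics", {
      m <- dplyr::bind_rows(lapply(reps, function(tr) {
        out <- dplyr::bind_rows(
          rmsd_series(tr, config$selection),
          rg_series(tr, mask = config$selection)
        )
        if (config$run_sasa) out <- dplyr::bind_rows(out, sasa_series(tr))
        out
      }))
      write_tsv_artifact(m, config$out_dir, paste0(nm, "_metrics"))
      m
    })
    cc$metric_summary <- if (!is.null(metrics)) summarise_metric(metrics)
    rmsf <- stage("rmsf", {
      r <- dplyr::bind_rows(lapply(reps, rmsf_profile, mask = config$selection))
      write_tsv_artifact(r, config$out_dir, paste0(nm, "_rmsf"))
      r
    })
    cc$rmsf <- rmsf
    dc <- stage("dccm", average_dccm(lapply(reps, dccm, mask = config$selection)))
    dccms[[nm]] <- dc
    es <- stage("pca", {
      # pooled PCA over concatenated superposed replicates for the subspace
      pooled <- reps[[1]]
      if (length(reps) > 1) {
        pooled$xyz <- do.call(rbind, lapply(reps, `[[`, "xyz"))
      }
      essential_dynamics(pooled, config$selection)
    })
    subspaces[[nm]] <- es
    if (!is.null(es)) {
      cc$variance_fraction <- es$variance_fraction[1:min(10, length(es$values))]
    }
    if (config$run_dssp) {
      occ <- stage("dssp", {
        tl <- lapply(reps, assign_dssp_trajectory)
        merged <- tl[[1]]
        if (length(tl) > 1) merged$codes <- do.call(rbind, lapply(tl, `[[`, "codes"))
        sse_occupancy(merged)
      })
      occupancies[[nm]] <- occ
      if (!is.null(occ)) {
        cc$sse_overall <- occ$overall
        write_tsv_artifact(occ$per_residue, config$out_dir, paste0(nm, "_sse"))
      }
    }
    felres <- stage("fel", {
      tr <- reps[[1]]
      if (length(reps) > 1) tr$xyz <- do.call(rbind, lapply(reps, `[[`, "xyz"))
      rs <- rmsd_series(tr, config$selection,
                        reference = if (!is.null(tr$ref_xyz)) "input_structure" else "first_frame")
      gs <- rg_series(tr, mask = config$selection)
      g <- fel(rs, gs, n_bins = config$fel_bins, temperature = config$temperature)
      b <- segment_basins(g, config$fel_cutoff)
      ext <- extract_basin(tr, b, rank = 1, mask = config$selection)
      rep1 <- basin_report(ext$trajectory, mask = config$selection,
                           dssp = config$run_dssp && any(tr$topology$residues$complete),
                           sasa = FALSE)
      list(n_basins = nrow(b$basins), basins = b$basins,
           rank1_summary = summarise_metric(rep1$metrics),
           rank1_frames = length(ext$frames),
           rank1_medoid = ext$conformer$medoid_frame_global)
    })
    if (!is.null(felres)) {
      cc$fel <- felres[c("n_basins", "rank1_frames", "rank1_medoid")]
      cc$fel$basins <- felres$basins
      cc$fel$rank1_summary <- felres$rank1_summary
    }
    per_cond[[nm]] <- cc
  }
  # comparisons against the reference
  refnm <- config$reference
  comparisons <- list()
  for (nm in setdiff(conds, refnm)) {
    cmp <- list()
    if (!is.null(dccms[[refnm]]) && !is.null(dccms[[nm]])) {
      d <- dccm_difference(dccms[[refnm]], dccms[[nm]],
                           threshold = config$dccm_threshold)
      regions <- detect_regions(d)
      cmp$dccm_regions <- regions
      cmp$dccm_max_difference <- max(d$matrix)
      if (!is.null(config$out_dir)) {
        write_tsv_artifact(
          tibble::tibble(label = nm, start = regions$start, end = regions$end,
                         score = regions$score),
          config$out_dir, paste0(nm, "_dccm_regions"))
      }
    }
    if (!is.null(subspaces[[refnm]]) && !is.null(subspaces[[nm]])) {
      k <- min(config$rmsip_k, length(subspaces[[refnm]]$values),
               length(subspaces[[nm]]$values))
      cmp$rmsip <- rmsip(subspaces[[refnm]], subspaces[[nm]], k = k)$value
    }
    if (config$run_dssp && !is.null(occupancies[[refnm]]) &&
        !is.null(occupancies[[nm]])) {
      sd_ <- sse_difference(occupancies[[nm]], occupancies[[refnm]])
      cmp$sse_overall_delta <- sd_$overall
      cmp$sse_per_residue_delta <- sd_$per_residue
      write_tsv_artifact(sd_$per_residue, config$out_dir,
                         paste0(nm, "_sse_delta"))
    }
    comparisons[[nm]] <- cmp
  }
  report$conditions <- per_cond
  report$comparisons <- comparisons
  report$failed <- failed
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> reference '", x$provenance$reference, "', ",
      length(x$conditions), " condition(s)\n", sep = "")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat("  ", nm, ": ", sep = "")
    if (!is.null(cmp$rmsip)) cat("RMSIP ", sprintf("%.3f", cmp$rmsip), "; ", sep = "")
    if (!is.null(cmp$dccm_regions) && nrow(cmp$dccm_regions) > 0) {
      cat("DCCM regions ",
          paste(sprintf("%d-%d", cmp$dccm_regions$start, cmp$dccm_regions$end),
                collapse = ", "), sep = "")
    }
    cat("\n")
  }
  if (length(x$failed) > 0) cat("  failed stages:", length(x$failed), "\n")
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' The body is deterministic for a fixed config and inputs (no timestamps),
#' so repeated runs are byte-identical.
#'
#' @param report a [run_study()] result.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
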