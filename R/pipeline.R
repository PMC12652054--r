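# Configuration-driven orchestration of the full analysis. One config (a
# YAML file or an equivalent nested list) drives trajectory analysis and
# assay fits and writes a reproducible report bundle: TSV tables, JSON
# summaries and a manifest recording the config and package version.

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_cts("invalid_input", "config must be a list or YAML path")
  config
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop_cts("validation_error", "config needs out_dir")
  inp <- config$inputs
  if (is.null(inp) && is.null(config$synthetic))
    stop_cts("validation_error", "config needs either `inputs` or `synthetic`")
  for (f in c("topology", "trajectory", "groups", "helix_ranges")) {
    p <- inp[[f]]
    if (!is.null(p) && !file.exists(p))
      stop_cts("validation_error", "input path missing: %s (%s)", f, p)
  }
  for (f in c("inhibition", "dihedral_profiles")) {
    p <- config$assays[[f]]
    if (is.character(p) && !file.exists(p))
      stop_cts("validation_error", "assay path missing: %s (%s)", f, p)
  }
  invisible(config)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages (each toggleable under `config$analyses`): binding-mode
#' classification (summary JSON + per-frame TSV), interaction-prevalence
#' matrix with the 5% mode-inclusion filter (TSV), lactone--ion distance
#' series and per-mode mixture/BIC fits (TSV + JSON), stability series
#' (TSV), sugar-site clusters (JSON), inhibition-curve and competition
#' fits (JSON), dihedral-term fits (JSON + CHARMM stream). Inputs come
#' from `config$inputs` (paths) or, when `config$synthetic` is given, from
#' [generate_system()] with those spec fields. A `manifest.json` records
#' the config, seeds, package version and collected warnings. Outputs are
#' deterministic given config + seeds; on any stage failure the stage name
#' is reported and this run's partial outputs are removed.
#'
#' @param config Nested list or YAML path; see the package vignette.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(read_run_config(config))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  emit <- function(path) { written <<- c(written, path); path }
  seed <- config$seed %||% 1
  stage <- "setup"

  result <- tryCatch(withCallingHandlers({
    # ---- inputs ------------------------------------------------------
    stage <- "load-inputs"
    if (!is.null(config$synthetic)) {
      spec <- do.call(trajectory_spec,
                      c(config$synthetic, list(seed = seed)))
      sys <- generate_system(spec)
      traj <- sys$trajectory; groups <- sys$groups; pairs <- sys$pairs
      ref <- build_reference_frame(sys$structure, sys$helix_ranges,
                                   sys$site_atoms)
      helix_ranges <- sys$helix_ranges
    } else {
      inp <- config$inputs
      rd <- read_trajectory(inp$topology, inp$trajectory, inp$groups,
                            frame_spacing = inp$frame_spacing %||% 1)
      traj <- rd$trajectory; groups <- rd$groups
      helix_ranges <- yaml::read_yaml(inp$helix_ranges)
      ref <- build_reference_frame(traj$topology, helix_ranges,
                                   as.character(unlist(inp$site_atoms)))
      pairs <- lapply(names(groups$partners), function(r) {
        g <- inp$contact_group %||% "hydroxyl_oxygens"
        hbond_pair(paste(g, r, sep = ":"), groups$groups[[g]],
                   groups$partners[[r]]$atoms,
                   hydrogens_b = groups$partners[[r]]$hydrogens)
      })
    }
    on <- function(name) isTRUE(config$analyses[[name]] %||% TRUE)
    crit <- do.call(hbond_criteria, config$hbond %||% list())

    # ---- binding modes ----------------------------------------------
    trace <- NULL
    if (on("binding_modes")) {
      stage <- "binding-modes"
      trace <- classify_binding_modes(traj, groups, ref,
                                      method = config$mode_method %||% "nearest",
                                      seed = seed)
      utils::write.table(
        data.frame(frame = seq_len(nrow(trace$frames)),
                   phi = round(trace$frames$phi, 3), label = trace$frames$label),
        emit(file.path(out_dir, "binding_modes.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_report(list(prevalence = as.list(trace$prevalence),
                             dwell_frames = as.list(trace$dwell),
                             transitions = trace$transitions),
                        emit(file.path(out_dir, "binding_modes.json")))
    }

    # ---- interaction prevalence -------------------------------------
    if (on("hbonds") && !is.null(trace) && length(pairs)) {
      stage <- "interaction-prevalence"
      pm <- interaction_prevalence(traj, trace, pairs, crit,
                                   threshold = config$threshold %||% 0.05)
      tab <- data.frame(pair = rownames(pm$matrix),
                        round(100 * pm$matrix, 1), check.names = FALSE)
      utils::write.table(tab, emit(file.path(out_dir, "interaction_prevalence.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # ---- ion distances + mixtures -----------------------------------
    if (on("ion_distance") && !is.null(trace)) {
      stage <- "ion-distance"
      ds <- ion_distance_series(traj, groups, trace)
      utils::write.table(ds, emit(file.path(out_dir, "ion_distance.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fits <- list()
      for (m in names(which(trace$prevalence[BM_LABELS] >
                            (config$threshold %||% 0.05)))) {
        v <- ds$distance[ds$mode == m]
        if (length(v) >= 10)
          fits[[m]] <- unclass(mixture_fit_bic(v, seed = seed))
      }
      write_json_report(fits, emit(file.path(out_dir, "ion_distance_mixtures.json")))
    }

    # ---- stability ---------------------------------------------------
    if (on("stability")) {
      stage <- "stability"
      al <- helix_ca_labels(traj$topology, helix_ranges)
      ss <- stability_series(traj, groups, ref, align_labels = al)
      utils::write.table(ss, emit(file.path(out_dir, "stability.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # ---- sugar sites -------------------------------------------------
    if (on("sugar_sites") && !is.null(trace) &&
        !is.null(groups$groups$sugar_marker)) {
      stage <- "sugar-sites"
      sg <- sugar_site_clusters(traj, trace, groups, ref, seed = seed)
      write_json_report(lapply(unclass(sg), function(m)
        list(centroids = apply(m$centroids, 1, as.list),
             occupancy = m$occupancy, n = m$n)),
        emit(file.path(out_dir, "sugar_sites.json")))
    }

    # ---- assay fits --------------------------------------------------
    if (!is.null(config$assays$inhibition)) {
      stage <- "inhibition-fit"
      a <- config$assays$inhibition
      d <- utils::read.csv(a$path %||% a)
      attr(d, "E_total") <- a$E_total %||% 0.1
      fit <- fit_inhibition_curve(d, n_species = a$n_species %||% 1,
                                  n_boot = a$n_boot %||% 0, seed = seed)
      write_json_report(list(Kd = fit$model$Kd, fractions = fit$model$fractions,
                             rss = fit$rss, aic = fit$aic, seed = seed),
                        emit(file.path(out_dir, "inhibition_fit.json")))
    }
    if (!is.null(config$assays$competition)) {
      stage <- "relative-affinity"
      a <- config$assays$competition
      ra <- relative_affinity_ratio(a$F_AO, a$F_mix, a$F_ref,
                                    AO_total = a$AO_total %||% 0.2,
                                    X_total = a$X_total %||% 0.2)
      write_json_report(unclass(ra), emit(file.path(out_dir, "relative_affinity.json")))
    }
    if (!is.null(config$assays$dihedral_profiles)) {
      stage <- "dihedral-fit"
      profs <- read_dihedral_profiles(config$assays$dihedral_profiles)
      fit <- fit_dihedral_terms(profs)
      write_json_report(list(rmse = fit$rmse, terms = fit$term_set$terms,
                             offsets = as.list(fit$term_set$offsets)),
                        emit(file.path(out_dir, "dihedral_fit.json")))
      write_charmm_dihedrals(fit$term_set,
                             emit(file.path(out_dir, "dihedral_fit.str")))
    }

    # ---- manifest ----------------------------------------------------
    stage <- "manifest"
    write_json_report(
      list(package = "ctsbind",
           version = as.character(utils::packageVersion("ctsbind")),
           seed = seed, config = config, warnings = warnings_log,
           outputs = basename(written)),
      emit(file.path(out_dir, "manifest.json")))
    stats::setNames(written, basename(written))
  }, warning = function(w) { note(w); invokeRestart("muffleWarning") }),
  error = function(e) {
    unlink(written)
    stop_cts("pipeline_error", "pipeline failed at stage '%s': %s",
             stage, conditionMessage(e))
  })
  invisible(result)
}
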