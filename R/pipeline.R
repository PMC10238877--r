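# End-to-end orchestration: YAML-configured runs of the build -> solve ->
# metrics pipeline and of the agreement-validation pipeline, with a manifest
# (configuration hash, seed, package version) for reproducibility.

#' Read and validate a run configuration
#'
#' @param path Path to a YAML configuration file, or a list already parsed.
#' @return The validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    abort_if(!file.exists(path), paste0("config file not found: ", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    rlang::abort("`path` must be a file path or a list")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$engine <- cfg$engine %||% "reduced"
  abort_if(!cfg$engine %in% c("reduced", "fem3d"),
           paste0("invalid engine: ", cfg$engine, " (use 'reduced' or 'fem3d')"))
  if (!is.null(cfg$validation) && !is.null(cfg$validation$input_csv)) {
    abort_if(!file.exists(cfg$validation$input_csv),
             paste0("paired-measurement CSV not found: ", cfg$validation$input_csv))
  }
  structure(cfg, class = c("run_config", "list"))
}

config_geometry <- function(cfg) {
  g <- cfg$geometry %||% list()
  spec <- bifurcation_spec(
    r_cca = g$r_cca %||% 3.5, r_ica = g$r_ica %||% 2.5, r_eca = g$r_eca %||% 2.0,
    len_cca = g$len_cca %||% 50, len_ica = g$len_ica %||% 60,
    len_eca = g$len_eca %||% 50,
    angle_ica = g$angle_ica %||% 25, angle_eca = g$angle_eca %||% 25)
  surface <- build_bifurcation(spec, resolution = g$resolution %||% 1.2)
  for (st in g$stenoses %||% list()) {
    surface <- apply_stenosis(surface, stenosis_spec(
      branch = st$branch %||% "ica", degree_nascet = st$degree,
      center_s = st$center_s %||% 12, length = st$length %||% 8,
      profile = st$profile %||% "cosine"))
  }
  if (isTRUE(g$flow_extensions)) surface <- add_flow_extensions(surface)
  surface
}

run_manifest <- function(cfg, out_dir, stages) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  list(
    package = "carotidtwin",
    version = as.character(utils::packageVersion("carotidtwin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    engine = cfg$engine,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Run the digital-twin pipeline
#'
#' Builds the parametric geometry, solves it with the configured engine,
#' extracts metrics, and (when configured) runs a hyperemia sweep. All
#' artifacts and a manifest are written to the output directory.
#'
#' @param config A YAML path or configuration list (see the packaged demo
#'   configuration under `inst/extdata/`).
#' @param out_dir Output directory (created if missing); overrides the
#'   configuration's `out_dir`.
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_twin <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(cfg$seed)
  stages <- character(0)

  surface <- config_geometry(cfg)
  stages <- c(stages, "geometry")
  sv <- cfg$solve %||% list()
  inlet <- inlet_profile(sv$v_peak %||% 100, surface$geom$spec$r_cca)
  ocfg <- sv$outlets %||% list(mode = "calibrate")

  if (cfg$engine == "reduced") {
    network <- if (identical(ocfg$mode %||% "calibrate", "explicit")) {
      twin_network(surface, outlets = list(
        ica = windkessel_params(ocfg$R_ica, ocfg$C_ica %||% 0),
        eca = windkessel_params(ocfg$R_eca, ocfg$C_eca %||% 0)))
    } else {
      twin_network(surface,
                   target_mean_pressure = ocfg$target_mean_pressure %||% 90,
                   baseline_flow = ocfg$baseline_flow %||% 600,
                   rc_time_constant = ocfg$rc_time_constant %||% 1.3)
    }
    sol <- solve_reduced_order(network, inlet,
                               duration = sv$duration, dt = sv$dt %||% 0.005)
    utils::write.csv(sol$series, file.path(out_dir, "flow_solution.csv"),
                     row.names = FALSE)
    utils::write.csv(sol$segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    stages <- c(stages, "solve_reduced")
    sweep_cfg <- cfg$sweep %||% list()
    factors <- sweep_cfg$v_peak_factors %||% c(1.0, 1.5, 2.0)
    has_sten <- any(network$segments$kind == "stenosis" &
                      network$segments$branch == "ica")
    if (has_sten && length(factors) >= 3) {
      curve <- hyperemia_sweep(network, (sv$v_peak %||% 100) * sort(factors))
      utils::write.csv(tidy(curve), file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(fit = list(a = curve$a, b = curve$b, r2 = curve$r2),
             levels = tidy(curve)),
        file.path(out_dir, "sweep.json"), auto_unbox = TRUE, digits = NA)
      stages <- c(stages, "sweep")
    }
  } else {
    mesh <- generate_mesh(surface, mesh_params(
      min_edge = cfg$mesh$min_edge %||% 0.08,
      max_edge = cfg$mesh$max_edge %||% 1.2))
    write_mesh_msh(mesh, file.path(out_dir, "twin.msh"))
    stages <- c(stages, "mesh")
    cal <- calibrate_outlet_parameters(
      ocfg$target_mean_pressure %||% 90, ocfg$baseline_flow %||% 600,
      ocfg$rc_time_constant %||% 1.3)
    spl <- split_outlet_resistances(cal$R_total, surface$geom$spec$r_ica,
                                    surface$geom$spec$r_eca)
    sol <- solve_fem3d(mesh, fluid_properties(), inlet,
                       outlets = list(ica = windkessel_params(spl$R_ica),
                                      eca = windkessel_params(spl$R_eca)),
                       time_cfg = fem_time_config(
                         max_steps = sv$max_steps %||% 4000))
    write_mesh_vtu(mesh, file.path(out_dir, "solution.vtu"),
                   point_data = list(velocity = sol$velocity,
                                     pressure = sol$pressure))
    utils::write.csv(sol$outlets, file.path(out_dir, "outlets.csv"),
                     row.names = FALSE)
    stages <- c(stages, "solve_fem3d")
  }
  psv <- extract_psv(sol, "ica",
                     if (cfg$engine == "reduced") "parabolic_from_flow"
                     else "field_max_in_branch")
  utils::write.csv(psv, file.path(out_dir, "psv.csv"), row.names = FALSE)
  stages <- c(stages, "metrics")

  manifest <- run_manifest(cfg, out_dir, stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Run the agreement-validation pipeline
#'
#' Loads (or synthesizes) paired DUS/CFD PSV measurements, applies the
#' probe-offset adjustment to the DUS values, computes the full agreement
#' report, and writes JSON/CSV artifacts plus plot-data tables.
#'
#' @param config A YAML path or configuration list with a `validation`
#'   block: either `input_csv` (columns id, psv_dus, psv_cfd, grade,
#'   radius_mm) or a `cohort` block for synthetic generation; optional
#'   `offset_mm` (default 0.4) and `margin` (default 0.3).
#' @param out_dir Output directory; overrides the configuration.
#' @return The [subgroup_report()] invisibly; artifacts on disk.
#' @export
run_validation <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  vcfg <- cfg$validation %||% list()
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pairs <- if (!is.null(vcfg$input_csv)) {
    raw <- utils::read.csv(vcfg$input_csv, stringsAsFactors = FALSE)
    need <- c("id", "psv_dus", "psv_cfd", "grade", "radius_mm")
    missing_cols <- setdiff(need, names(raw))
    abort_if(length(missing_cols) > 0,
             paste0("paired CSV is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
    bad <- which(!is.finite(raw$psv_dus) | !is.finite(raw$psv_cfd))
    abort_if(length(bad) > 0,
             paste0("paired CSV has non-numeric PSV in row(s): ",
                    paste(utils::head(bad, 5), collapse = ", ")))
    tibble::as_tibble(raw)
  } else {
    cc <- vcfg$cohort %||% list()
    config_obj <- cohort_config(
      n_free = cc$n_free %||% 7, n_mild = cc$n_mild %||% 24,
      n_moderate = cc$n_moderate %||% 6, n_severe = cc$n_severe %||% 0,
      dus_noise_cv = cc$dus_noise_cv %||% 0.1,
      cfd_bias_factor = cc$cfd_bias_factor %||% 1.1,
      cfd_noise_cv = cc$cfd_noise_cv %||% 0.1,
      seed = cfg$seed)
    cohort <- simulate_cohort(config_obj)
    utils::write.csv(cohort[, c("id", "grade", "degree", "true_psv")],
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    yaml::write_yaml(list(
      counts = as.list(config_obj$counts),
      dus_noise_cv = config_obj$dus_noise_cv,
      cfd_bias_factor = config_obj$cfd_bias_factor,
      cfd_noise_cv = config_obj$cfd_noise_cv, seed = config_obj$seed),
      file.path(out_dir, "cohort_params.yaml"))
    simulate_paired_measurements(cohort, config_obj)
  }

  offset <- vcfg$offset_mm %||% 0.4
  pairs$psv_dus <- adjust_dus_psv(pairs$psv_dus, pairs$radius_mm, offset)
  report <- subgroup_report(pairs)
  utils::write.csv(tidy(report), file.path(out_dir, "agreement_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(as.list(glance(report)), list(offset_mm = offset)),
    file.path(out_dir, "agreement_report.json"), auto_unbox = TRUE, digits = NA)
  # plot-data tables for the scatter and Bland-Altman panels
  utils::write.csv(
    data.frame(psv_dus = pairs$psv_dus, psv_cfd = pairs$psv_cfd,
               grade = as.character(pairs$grade)),
    file.path(out_dir, "scatter_data.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(mean_psv = (pairs$psv_cfd + pairs$psv_dus) / 2,
               diff_psv = pairs$psv_cfd - pairs$psv_dus,
               grade = as.character(pairs$grade)),
    file.path(out_dir, "bland_altman_data.csv"), row.names = FALSE)
  manifest <- run_manifest(cfg, out_dir, "validation")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
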