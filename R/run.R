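.require_file <- function(path, what = "input file") {
  if (is.null(path)) stop("missing ", what)
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

#' Read a thermogram CSV (\code{time_s}, \code{heat_flow_ucal_per_s})
#' @param path CSV path.
#' @return data frame.
#' @export
read_thermogram_csv <- function(path) {
  .require_file(path, "thermogram CSV")
  df <- utils::read.csv(path)
  if (!all(c("time_s", "heat_flow_ucal_per_s") %in% names(df)))
    stop(path, ": expected columns time_s, heat_flow_ucal_per_s")
  df
}

#' Read an injection schedule from a YAML or CSV description
#'
#' YAML fields (or CSV columns, one row): \code{injection_ul} (list),
#' \code{spacing_s}, \code{cell_ul}, \code{syringe_lipid_mM},
#' \code{cell_solute_uM}, \code{exclude_first}.
#' @param path file path (.yaml/.yml or .csv).
#' @return an \code{\link{injection_schedule}}.
#' @export
read_schedule <- function(path) {
  .require_file(path, "schedule file")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    s <- yaml::read_yaml(path)
    inj <- unlist(s$injection_ul)
  } else {
    s <- as.list(utils::read.csv(path)[1L, ])
    inj <- as.numeric(strsplit(as.character(s$injection_ul), ";")[[1L]])
  }
  injection_schedule(
    injection_ul = inj,
    spacing_s = as.numeric(s$spacing_s),
    cell_ul = as.numeric(s$cell_ul),
    syringe_lipid_M = as.numeric(s$syringe_lipid_mM) * 1e-3,
    cell_solute_M = as.numeric(s$cell_solute_uM) * 1e-6,
    exclude_first = isTRUE(as.logical(s$exclude_first)))
}

#' Read a melting-curve CSV (\code{temperature_C}, \code{wavenumber_cm1}
#' and optionally \code{replicate})
#' @param path CSV path.
#' @return data frame.
#' @export
read_melting_curve_csv <- function(path) {
  .require_file(path, "melting-curve CSV")
  df <- utils::read.csv(path)
  if (!all(c("temperature_C", "wavenumber_cm1") %in% names(df)))
    stop(path, ": expected columns temperature_C, wavenumber_cm1")
  df
}

#' Read a bioassay CSV (\code{treatment}, \code{root_length_mm} and
#' optionally \code{block}, \code{dish})
#' @param path CSV path.
#' @return data frame.
#' @export
read_bioassay_csv <- function(path) {
  .require_file(path, "bioassay CSV")
  df <- utils::read.csv(path)
  if (!all(c("treatment", "root_length_mm") %in% names(df)))
    stop(path, ": expected columns treatment, root_length_mm")
  df
}

.fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

.write_report <- function(obj, dir, stem, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "memprobe",
               version = as.character(utils::packageVersion("memprobe")),
               config = config)
  json <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(c(lapply(obj, .fmt6), meta), json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  json
}

#' Run one analysis stage from a configuration
#'
#' A single entry point over the analysis stages, suitable for scripting.
#' The configuration (a list or a YAML file path) names the stage and its
#' input files; reports (JSON plus CSV tables) are written to
#' \code{out_dir}, embedding the configuration, package version and seed.
#'
#' Stages and their inputs:
#' \describe{
#'   \item{itc}{\code{thermogram} (CSV), \code{schedule} (YAML/CSV); fits
#'     the partition model.}
#'   \item{ftir}{\code{curve} (CSV) and optionally \code{curve_without}
#'     for a melting-temperature shift.}
#'   \item{traj}{\code{traj} (GRO), \code{selections} (YAML),
#'     \code{observable} (depth/hbonds/angles), optional \code{window_ns},
#'     \code{fold}.}
#'   \item{bioassay}{\code{table} (CSV), optional \code{control},
#'     \code{alpha}.}
#'   \item{synth}{\code{what} (itc/ftir/traj/bioassay), \code{params}
#'     (list passed to the generator), \code{seed}; writes the generated
#'     inputs plus a \code{truth.json}.}
#' }
#'
#' @param config list or YAML file path.
#' @param out_dir output directory (created if absent); overrides
#'   \code{config$out_dir}.
#' @return invisibly, a list with the stage results and the paths written.
#' @export
run_stage <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    .require_file(config, "config file")
    config <- yaml::read_yaml(config)
  }
  stage <- config$stage
  if (is.null(stage) ||
      !stage %in% c("itc", "ftir", "traj", "bioassay", "synth"))
    stop("config$stage must be one of itc, ftir, traj, bioassay, synth")
  dir <- out_dir %||% config$out_dir %||% "."
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  res <- switch(stage,
    itc = {
      tg <- read_thermogram_csv(.require_file(config$thermogram,
                                              "thermogram CSV"))
      sched <- read_schedule(.require_file(config$schedule, "schedule file"))
      heats <- integrate_thermogram(tg, sched,
        dilute_solute = !isTRUE(config$no_dilution))
      fit <- fit_partition(heats, sched)
      utils::write.csv(as.data.frame(heats),
                       file.path(dir, "itc_injections.csv"),
                       row.names = FALSE)
      path <- .write_report(
        list(K_L_per_mol = fit$K, dH_cal_per_mol = fit$dH,
             K_se = fit$K_se, dH_se = fit$dH_se, rss_ucal2 = fit$rss,
             converged = fit$converged),
        dir, "itc_fit", config)
      list(fit = fit, report = path)
    },
    ftir = {
      cur <- read_melting_curve_csv(.require_file(config$curve,
                                                  "melting-curve CSV"))
      fit <- fit_boltzmann(build_melting_curve(cur))
      out <- list(Tm_C = fit$Tm, Tm_se_C = fit$Tm_se, width_C = fit$width,
                  nu_gel_cm1 = fit$nu_gel, nu_fluid_cm1 = fit$nu_fluid,
                  converged = fit$converged)
      if (!is.null(config$curve_without)) {
        cur0 <- read_melting_curve_csv(.require_file(config$curve_without,
                                                     "reference curve CSV"))
        fit0 <- fit_boltzmann(build_melting_curve(cur0))
        dt <- delta_tm(fit, fit0)
        out$delta_Tm_C <- dt$delta_Tm
        out$delta_Tm_se_C <- dt$se
      }
      path <- .write_report(out, dir, "ftir_fit", config)
      list(fit = fit, report = path)
    },
    traj = {
      gro <- read_gro(.require_file(config$traj, "trajectory GRO"))
      traj <- trajectory_system(gro,
        .require_file(config$selections, "selection config"))
      obs <- config$observable %||% "depth"
      tab <- switch(obs,
        depth = as.data.frame(depth_profile(traj)),
        hbonds = {
          hb <- hbond_timeseries(traj, window_ns = config$window_ns)
          attr_wm <- attr(hb, "window_means")
          wm <- as.data.frame(as.list(attr_wm))
          utils::write.csv(wm, file.path(dir, "hbond_window_means.csv"),
                           row.names = FALSE)
          as.data.frame(hb)
        },
        angles = {
          dist <- bond_vector_angles(traj, fold = isTRUE(config$fold))
          nb <- length(dist$bin_edges)
          data.frame(bin_left_deg = dist$bin_edges[-nb],
                     bin_right_deg = dist$bin_edges[-1L],
                     density = dist$density)
        },
        stop("unknown observable: ", obs))
      csv <- file.path(dir, paste0("traj_", obs, ".csv"))
      utils::write.csv(tab, csv, row.names = FALSE)
      path <- .write_report(list(observable = obs, rows = nrow(tab)),
                            dir, paste0("traj_", obs), config)
      list(table = tab, report = path)
    },
    bioassay = {
      tab <- read_bioassay_csv(.require_file(config$table, "bioassay CSV"))
      test <- anova_tukey_cld(tab, control = config$control %||% "Control",
                              alpha = config$alpha %||% 0.05)
      utils::write.csv(as.data.frame(test$summary),
                       file.path(dir, "bioassay_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(cbind(term = rownames(test$anova), test$anova),
                       file.path(dir, "bioassay_anova.csv"),
                       row.names = FALSE)
      path <- .write_report(
        list(alpha = test$alpha, blocked = test$blocked,
             treatment_F = test$anova["treatment", "F value"],
             treatment_p = test$anova["treatment", "Pr(>F)"]),
        dir, "bioassay_test", config)
      list(test = test, report = path)
    },
    synth = {
      what <- config$what %||% stop("config$what is required for synth")
      params <- config$params %||% list()
      params$seed <- config$seed
      gen <- switch(what,
        itc = do.call(gen_itc, params),
        ftir = do.call(gen_melting_curve, params),
        traj = do.call(gen_membrane_traj, params),
        bioassay = do.call(gen_bioassay, params),
        stop("unknown generator: ", what))
      if (what == "itc") {
        utils::write.csv(gen$thermogram,
                         file.path(dir, "thermogram.csv"),
                         row.names = FALSE)
        s <- gen$schedule
        yaml::write_yaml(list(injection_ul = s$injection_ul,
                              spacing_s = s$spacing_s, cell_ul = s$cell_ul,
                              syringe_lipid_mM = s$syringe_lipid_M * 1e3,
                              cell_solute_uM = s$cell_solute_M * 1e6,
                              exclude_first = s$exclude_first),
                         file.path(dir, "schedule.yaml"))
      } else if (what == "ftir") {
        utils::write.csv(gen$curve, file.path(dir, "melting_curve.csv"),
                         row.names = FALSE)
      } else if (what == "traj") {
        write_gro(gen$gro$atoms, gen$gro$frames,
                  file.path(dir, "trajectory.gro"))
        yaml::write_yaml(gen$config, file.path(dir, "selections.yaml"))
      } else {
        utils::write.csv(gen$table, file.path(dir, "bioassay.csv"),
                         row.names = FALSE)
      }
      jsonlite::write_json(gen$truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      list(generated = gen, report = file.path(dir, "truth.json"))
    })
  invisible(c(res, list(out_dir = dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
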