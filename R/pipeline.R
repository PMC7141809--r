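# End-to-end orchestration: validate a declarative config, run the requested
# stages (pore profiling, ion assignment, selectivity, each optionally fed by
# the synthetic generators), and write per-stage CSV/JSON plus a combined
# report with full parameter provenance. No timestamps are written, so
# re-running a config reproduces byte-identical outputs.

#' Validate a pipeline configuration
#'
#' A config is a named list with \code{seed} (integer), \code{output_dir},
#' and any of the stage blocks \code{pore}, \code{assign_ions},
#' \code{selectivity}. Stage blocks may name input files
#' (\code{structure_path}, \code{map_primary_path}/\code{map_partner_path} +
#' \code{model_path}, \code{iv_path}) or omit them to run on synthetic
#' inputs generated under the config seed. All referenced paths must exist.
#'
#' @param config Named list (or path to a JSON file holding one).
#' @return The normalized config, invisibly; errors on any problem.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "ionpore_config_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    abort("config must be a named list", class = "ionpore_config_error")
  }
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$output_dir)) {
    abort("config needs an output_dir", class = "ionpore_config_error")
  }
  path_fields <- c("structure_path", "map_primary_path", "map_partner_path",
                   "model_path", "iv_path")
  for (stage in c("pore", "assign_ions", "selectivity")) {
    blk <- config[[stage]]
    if (is.null(blk)) next
    for (f in intersect(names(blk), path_fields)) {
      if (!is.null(blk[[f]]) && !file.exists(blk[[f]])) {
        abort(paste0("config ", stage, "$", f, " does not exist: ", blk[[f]]),
              class = "ionpore_config_error")
      }
    }
  }
  invisible(config)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (pore profile, ion assignment,
#' selectivity), writing per-stage CSV/JSON into \code{output_dir} and a
#' combined \code{report.json} with the echoed parameters and seed. A stage
#' failure raises an error naming the stage; outputs of completed stages are
#' retained.
#'
#' @param config See \code{\link{validate_run_config}}.
#' @param quiet Suppress stage progress messages.
#' @return The combined report, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) {
    if (!quiet) message("[", stage, "] ", msg)
  }
  report <- list(
    tool = "ionpore",
    version = as.character(utils::packageVersion("ionpore")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("output_dir"))],
    stages = list()
  )
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "ionpore_stage_error", parent = e)
    })
  }

  if (!is.null(config$pore)) {
    report$stages$pore <- run_stage("pore", function() {
      blk <- config$pore
      say("pore", "building structure")
      if (!is.null(blk$structure_path)) {
        structure_tbl <- read_structure(blk$structure_path)
      } else {
        structure_tbl <- make_toy_channel(
          constriction_radius = blk$constriction_radius %||% 1.7,
          seed = config$seed
        )$structure
      }
      step <- blk$step %||% 0.5
      say("pore", "profiling")
      prof <- compute_pore_profile(structure_tbl, step = step,
                                   z_range = blk$z_range,
                                   seed = config$seed)
      prof <- hydrophobicity_annotation(structure_tbl, prof)
      mc <- min_constriction(prof)
      out <- as_tibble(prof)
      out$lining_residues <- vapply(out$lining_residues, paste,
                                    character(1), collapse = ";")
      write.csv(out, file.path(config$output_dir, "pore_profile.csv"),
                row.names = FALSE)
      say("pore", sprintf("min radius %.2f A at z = %.1f", mc$radius, mc$z))
      list(min_radius = mc$radius, min_z = mc$z,
           lining = paste(mc$lining_residues[[1]], collapse = ";"),
           n_samples = nrow(prof))
    })
  }

  if (!is.null(config$assign_ions)) {
    report$stages$assign_ions <- run_stage("assign_ions", function() {
      blk <- config$assign_ions
      if (!is.null(blk$map_primary_path)) {
        map1 <- read_mrc(blk$map_primary_path)
        map2 <- read_mrc(blk$map_partner_path)
        model <- read_structure(blk$model_path)
        thr1 <- blk$threshold_primary %||% 12
        thr2 <- blk$threshold_partner %||% 8
        axis <- NULL
      } else {
        say("assign_ions", "simulating paired maps")
        chan <- make_toy_channel(seed = config$seed)$structure
        sim <- paired_ion_maps(chan,
                               n_ions = blk$n_ions %||% 4,
                               n_waters = blk$n_waters %||% 12,
                               amplitude_ratio = blk$amplitude_ratio %||% 3,
                               seed = config$seed)
        map1 <- sim$map_primary; map2 <- sim$map_partner
        model <- chan
        thr1 <- blk$threshold_primary %||% sim$truth$threshold_primary
        thr2 <- blk$threshold_partner %||% sim$truth$threshold_partner
        axis <- sim$truth$axis
      }
      region <- if (!is.null(axis)) {
        cylinder_region(axis$origin, axis$direction,
                        radius = blk$pore_radius %||% 8)
      } else NULL
      say("assign_ions", "finding peaks")
      p1 <- find_nonprotein_peaks(sigma_scale(map1), model, thr1,
                                  region = region)
      p2 <- find_nonprotein_peaks(sigma_scale(map2), model, thr2,
                                  region = region)
      mt <- match_peaks(p1, p2)
      sites <- classify_sites(mt, p1, p2, axis = axis)
      out <- sites
      write.csv(out, file.path(config$output_dir, "ion_sites.csv"),
                row.names = FALSE)
      n_ion <- sum(sites$classification == "ion")
      say("assign_ions", sprintf("%d ion sites, %d waters", n_ion,
                                 sum(sites$classification == "water")))
      list(n_ion_sites = n_ion,
           n_water_sites = sum(sites$classification == "water"),
           mean_amplitude_ratio =
             mean(sites$amplitude_ratio[sites$classification == "ion"]),
           threshold_primary = thr1, threshold_partner = thr2)
    })
  }

  if (!is.null(config$selectivity)) {
    report$stages$selectivity <- run_stage("selectivity", function() {
      blk <- config$selectivity
      cond <- bi_ionic_condition(
        conc_internal = blk$conc_internal %||% 150,
        conc_external = blk$conc_external %||% 150,
        temperature = blk$temperature %||% 298.15
      )
      if (!is.null(blk$iv_path)) {
        fams <- read_iv(blk$iv_path, condition = cond)
      } else {
        say("selectivity", "simulating I-V family")
        sim <- simulate_iv(cond, true_ratio = blk$true_ratio %||% 9,
                           noise_frac = blk$noise_frac %||% 0.05,
                           seed = config$seed)
        fams <- list(WT = sim$family)
      }
      tab <- selectivity_table(fams)
      write.csv(tab, file.path(config$output_dir, "selectivity.csv"),
                row.names = FALSE)
      say("selectivity", sprintf("%d construct(s) analyzed", nrow(tab)))
      lapply(split(tab, tab$construct), as.list)
    })
  }

  write_stage_json(report, file.path(config$output_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
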