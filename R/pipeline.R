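# Pipeline orchestration: a serializable run configuration and a driver
# that executes the analysis stages in order, writing one JSON report.

#' Build a pipeline run configuration
#'
#' A plain, fully serializable list of stage parameters. Any subset of
#' the stages can be enabled; inputs can be file paths or omitted, in
#' which case the synthetic generators supply them (so every stage runs
#' offline).
#'
#' @param stages character vector drawn from `"mechanics"`, `"helix"`,
#'   `"profiles"`, `"cavities"`.
#' @param traces path to a trace CSV (default `NULL`: a synthetic
#'   ensemble is generated with the parameters below).
#' @param structure path to a PDB/mmCIF model (default `NULL`: a
#'   synthetic stack is built).
#' @param fasta path to a patient FASTA (default `NULL`: the synthetic
#'   patient sequence).
#' @param germline_fasta path to a germline FASTA (default `NULL`: the
#'   synthetic germline template).
#' @param predictor_dir directory of predictor TSVs named
#'   `<Predictor>.tsv` (optional; the consensus score is skipped without
#'   it).
#' @param temperature kelvin (default 300).
#' @param persistence_length,n_traces,length_range,step synthetic
#'   mechanics parameters (defaults 6.7 um, 124, 1-8 um, 0.02 um).
#' @param n_bootstrap bootstrap resamples for the fit uncertainty.
#' @param rise,twist,n_layers helix parameters (defaults 4.8 A, -0.58
#'   deg, 5 layers).
#' @param contact_cutoff heavy-atom contact cutoff (A, default 4.5).
#' @param grid_spacing,probe,min_volume cavity parameters (defaults
#'   0.5 A, 1.4 A, 20 A^3).
#' @param cdr_ranges list of `c(start, end)` CDR ranges or `NULL`.
#' @param seed integer seed used by every stochastic stage.
#' @param out_dir output directory for the report and artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(stages = c("mechanics", "helix", "profiles", "cavities"),
                       traces = NULL, structure = NULL, fasta = NULL,
                       germline_fasta = NULL, predictor_dir = NULL,
                       temperature = 300, persistence_length = 6.7,
                       n_traces = 124, length_range = c(1, 8), step = 0.02,
                       n_bootstrap = 200, rise = 4.8, twist = -0.58,
                       n_layers = 5, contact_cutoff = 4.5,
                       grid_spacing = 0.5, probe = 1.4, min_volume = 20,
                       cdr_ranges = NULL, seed = 42L, out_dir = tempdir()) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(traces, structure, fasta, germline_fasta, predictor_dir)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("run_config: input path does not exist: ", p)
    }
  }
  cfg <- mget(names(formals()), envir = environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order (mechanics, helix, profiles,
#' cavities) and writes `report.json` to the configured output
#' directory. Under a fixed seed the report is reproducible. A stage
#' failure is recorded in the report's `errors` section, the remaining
#' stages still run, and the function signals via the `ok` field.
#'
#' @param config a [run_config()] (or a YAML path readable as one).
#' @return the report, invisibly a list; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("fibrilmetrics")),
    seed = config$seed,
    stages = config$stages)
  errors <- list()

  if ("mechanics" %in% config$stages) {
    res <- tryCatch({
      traces <- if (is.null(config$traces)) {
        generate_trace_ensemble(config$persistence_length, config$n_traces,
                                config$length_range, config$step,
                                seed = config$seed)
      } else {
        read_traces(config$traces)
      }
      obs <- measure_traces(traces)
      fit <- fit_persistence_length(obs, temperature = config$temperature,
                                    n_bootstrap = config$n_bootstrap,
                                    seed = config$seed)
      list(P_um = fit$P_um, P_se_um = fit$P_se_um,
           P_se_boot_um = fit$P_se_boot_um, B_Nm2 = fit$B_Nm2,
           temperature_K = fit$temperature_K, n = fit$n_fibrils,
           converged = fit$converged)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$mechanics <- conditionMessage(res)
    } else {
      report$mechanics <- res
    }
  }

  if ("helix" %in% config$stages) {
    res <- tryCatch({
      sym <- helical_symmetry(config$rise, config$twist)
      geom <- pitch_and_crossover(sym)
      model <- if (is.null(config$structure)) {
        build_stack(generate_beta_arch_layer(91), sym, config$n_layers)
      } else {
        read_structure(config$structure)
      }
      est <- estimate_symmetry(model)
      contacts <- interlayer_contacts(model, cutoff = config$contact_cutoff)
      list(rise = config$rise, twist = config$twist,
           pitch_A = geom$pitch, crossover_A = geom$crossover,
           handedness = geom$handedness,
           estimated_rise = est$rise, estimated_twist = est$twist,
           superposition_rmsd = est$rmsd,
           width_A = measure_width(model, est$axis),
           n_contacts = nrow(contacts),
           n_interlayer_contacts = sum(contacts$offset > 0))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$helix <- conditionMessage(res)
    } else {
      report$helix <- res
    }
  }

  if ("profiles" %in% config$stages) {
    res <- tryCatch({
      pat <- if (is.null(config$fasta)) patient_sequence()
             else read_sequence_fasta(config$fasta)
      germ <- if (is.null(config$germline_fasta)) germline_template()
              else read_sequence_fasta(config$germline_fasta)
      muts <- list_mutations(pat, germ)
      out <- list(
        n_residues = nchar(pat),
        hydropathy_mean = mean(hydropathy_profile(pat)),
        n_mutations = nrow(muts),
        mutation_positions = muts$pos)
      if (!is.null(config$predictor_dir)) {
        hits <- lapply(amyloid_predictors(), function(p) {
          f <- file.path(config$predictor_dir, paste0(p, ".tsv"))
          parse_predictor_output(f, p, nchar(pat))
        })
        prof <- consensus_amyloid_score(hits, pat)
        out$max_amyloid_score <- max(prof$score)
        out$n_score5 <- sum(prof$score == 5)
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$profiles <- conditionMessage(res)
    } else {
      report$profiles <- res
    }
  }

  if ("cavities" %in% config$stages) {
    res <- tryCatch({
      model <- if (is.null(config$structure)) {
        generate_cavity_phantom(phantom_spec(3))
      } else {
        read_structure(config$structure)
      }
      cavs <- find_cavities(model, spacing = config$grid_spacing,
                            probe = config$probe,
                            min_volume = config$min_volume)
      cavs <- lapply(cavs, function(cv) cavity_polarity_report(model, cv))
      list(n_cavities = length(cavs),
           volumes_A3 = vapply(cavs, `[[`, 0, "volume"),
           polarity = vapply(cavs, function(cv) {
             cv$polarity %||% NA_character_
           }, ""))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$cavities <- conditionMessage(res)
    } else {
      report$cavities <- res
    }
  }

  report$errors <- errors
  report$ok <- length(errors) == 0
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(config$out_dir, "report.json"))
  invisible(report)
}
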