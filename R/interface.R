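# Run configuration and command-line entry point ----------------------------

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration with a `params` block (parameter
#' overrides or a `params_file` path) plus subcommand-specific options.
#' Unknown keys are rejected so typos fail loudly. The resolved
#' configuration should be echoed next to every output (the CLI does this
#' automatically) so each artifact is regenerable.
#'
#' @param path configuration file path (.yaml/.yml/.json).
#' @param allowed extra allowed top-level keys beyond the common ones.
#' @return list with `params` (a `ca_params`) and the remaining options.
#' @export
load_run_config <- function(path, allowed = character(0)) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  common <- c("params", "params_file", "out_dir", "seed", "atp", "duration",
              "knockout", "initial_markov", "variant", "grid_from", "grid_to",
              "per_decade", "resolution", "ip3_max", "ca_er_min_frac",
              "n_cells", "p_sensitized", "doses", "noise_sd", "dose_shift")
  unknown <- setdiff(names(cfg), c(common, allowed))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  p <- if (!is.null(cfg$params_file)) read_params(cfg$params_file)
       else if (!is.null(cfg$params)) do.call(model_params, as.list(cfg$params))
       else model_params()
  cfg$params <- p
  cfg$params_file <- NULL
  cfg
}

# minimal --key value argv parser (flags become logical TRUE)
parse_argv <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    } else {
      out[[key]] <- TRUE; i <- i + 1L
    }
  }
  out
}

cli_usage <- function() {
  cat("usage: p2casim <simulate|sweep|bifurcation|features|synth> [--options]\n",
      "  simulate   --atp <M> [--knockout none|p2y2|p2x7] [--pool naive_C1|sensitized_C4]\n",
      "             [--duration s] --out <csv>\n",
      "  sweep      --variant full|p2y2_only|p2x7_naive|p2x7_sensitized\n",
      "             [--from M --to M --per-decade n] --out <csv>\n",
      "  bifurcation [--resolution n] --out <csv>\n",
      "  features   --traces <csv> --out <csv>\n",
      "  synth      [--n n] [--p-sensitized p] [--seed s] --doses <M,M,...> --out <csv>\n",
      "  common:    [--config <yaml|json>] (parameter overrides)\n", sep = "")
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; installed as
#' `inst/cli/p2casim` (run with `Rscript`). Every output CSV gets a JSON
#' sidecar echoing the resolved options.
#'
#' @param argv character vector of command-line arguments.
#' @return exit code (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { cli_usage(); return(invisible(1L)) }
  cmd <- argv[1]
  opts <- tryCatch(parse_argv(argv[-1]), error = function(e) e)
  if (inherits(opts, "error") ||
      !cmd %in% c("simulate", "sweep", "bifurcation", "features", "synth")) {
    cli_usage(); return(invisible(1L))
  }
  p <- if (!is.null(opts$config)) load_run_config(opts$config)$params
       else model_params()
  out <- opts$out
  if (is.null(out)) { cli_usage(); return(invisible(1L)) }
  sidecar <- function(x) jsonlite::write_json(
    c(list(command = cmd), opts), paste0(out, ".meta.json"),
    auto_unbox = TRUE, digits = NA)

  res <- tryCatch(switch(cmd,
    simulate = {
      sim <- run_protocol(protocol(
        ATP = as.numeric(opts$atp),
        duration = as.numeric(opts$duration %||% 120),
        knockout = opts$knockout %||% "none",
        initial_markov = opts$pool %||% "naive_C1"), p)
      export_simulation(sim, out)
    },
    sweep = {
      crv <- sweep_dose_response(
        opts$variant %||% "full",
        dose_grid(as.numeric(opts$from %||% 1e-8),
                  as.numeric(opts$to %||% 1e-2),
                  as.numeric(opts[["per-decade"]] %||% 25)), p)
      export_dose_response(crv, out)
    },
    bifurcation = {
      region <- map_oscillatory_region(
        resolution = as.numeric(opts$resolution %||% 60), p = p)
      export_region(region, out)
    },
    features = {
      traces <- read_traces(opts$traces)
      feats <- do.call(rbind, lapply(traces, function(tr) {
        f <- extract_features(tr)
        f$cell <- tr$meta$cell %||% NA_character_
        f$dose <- tr$meta$dose %||% NA_real_
        f
      }))
      utils::write.csv(feats, out, row.names = FALSE)
    },
    synth = {
      spec <- population_spec(
        n_cells = as.numeric(opts$n %||% 50),
        p_sensitized = as.numeric(opts[["p-sensitized"]] %||% 0),
        seed = as.numeric(opts$seed %||% 1))
      doses <- as.numeric(strsplit(opts$doses, ",")[[1]])
      traces <- generate_population(spec, doses, p)
      write_traces(traces, out)
    }
  ), error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(1L))
  }
  sidecar()
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
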