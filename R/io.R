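#' Load an experiment configuration
#'
#' Reads a YAML file with up to four top-level blocks — `network`,
#' `protocol`, `task` (`kind`, `n`, `m`) and `mode` — validates every
#' field, applies defaults for anything omitted, and rejects unknown keys.
#'
#' @param path YAML file.
#' @return List with `config` ([sorn_config()]), `protocol`
#'   ([sorn_protocol()]), `task` (a `"symbol_sequence"`), `mode`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("network", "protocol", "task", "mode")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  task_spec <- raw$task %||% list(kind = "counting", n = 4, m = 10)
  # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
  names(task_spec)[names(task_spec) %in% c("FALSE", "no")] <- "n"
  bad <- setdiff(names(task_spec), c("kind", "n", "m"))
  if (length(bad))
    stop("unknown task key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  kind <- task_spec$kind %||% "counting"
  n <- task_spec$n %||% 4
  m <- task_spec$m %||% 10
  task <- switch(kind,
                 counting = make_counting_sequence(n, m),
                 motion = ,
                 motion_prediction = ,
                 motion_generation = make_motion_sequence(n, m),
                 stop("unknown task kind: ", kind, call. = FALSE))
  mode <- raw$mode %||%
    (if (identical(kind, "motion_generation")) "generation" else "prediction")

  net_args <- raw$network %||% list()
  allowed <- setdiff(names(formals(sorn_config)), "")
  bad <- setdiff(names(net_args), allowed)
  if (length(bad))
    stop("unknown network key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(net_args$symbols)) net_args$symbols <- task$alphabet
  config <- do.call(sorn_config, net_args)

  prot_args <- raw$protocol %||% list()
  allowed <- setdiff(names(formals(sorn_protocol)), "")
  bad <- setdiff(names(prot_args), allowed)
  if (length(bad))
    stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  protocol <- do.call(sorn_protocol, prot_args)

  list(config = config, protocol = protocol, task = task, mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config A [sorn_config()].
#' @param protocol A [sorn_protocol()].
#' @param task A `"symbol_sequence"`.
#' @param mode `"prediction"` or `"generation"`.
#' @param path Output path.
#' @export
save_config <- function(config, protocol, task, mode, path) {
  net <- unclass(config)
  net$n_inhibitory <- NULL   # derived
  net$n_output <- NULL       # derived from symbols
  prot <- unclass(protocol)
  yaml::write_yaml(list(network = net, protocol = prot,
                        task = list(kind = if (task$task_kind == "motion" &&
                                               mode == "generation")
                                      "motion_generation"
                                    else if (task$task_kind == "motion")
                                      "motion_prediction"
                                    else "counting",
                                    n = task$n, m = task$m),
                        mode = mode),
                   path)
  invisible(path)
}

#' Default initial connection fraction for a network size
#'
#' The best-performing initial E-E connection fractions are 0.05 for 200
#' excitatory neurons and 0.0125 for 400; sizes in between interpolate the
#' implied number of connections per neuron.
#'
#' @param n_excitatory Network size.
#' @return Connection fraction.
#' @export
default_p_c <- function(n_excitatory) {
  if (n_excitatory >= 400) 0.0125
  else if (n_excitatory >= 200) 0.05
  else 0.1
}

#' Run one complete experiment
#'
#' Builds the task and network, trains with the two-stage protocol and
#' evaluates with plasticity off. The single entry point used by the
#' command-line interface, the table reproductions and the acceptance
#' checks.
#'
#' @param task_kind `"counting"`, `"motion_prediction"` or
#'   `"motion_generation"`.
#' @param n Task repetition parameter.
#' @param n_excitatory Network size.
#' @param seed Seed for the run.
#' @param p_c Initial connection fraction; `NULL` for [default_p_c()].
#' @param protocol A [sorn_protocol()].
#' @param eval_steps Scored evaluation steps.
#' @param config_overrides Named list of [sorn_config()] arguments to
#'   override.
#' @param record Passed to [train()].
#' @return List with `report` (an `"eval_report"`), `training`
#'   (`"sorn_training"`), `config`.
#' @export
run_experiment <- function(task_kind, n, n_excitatory, seed,
                           p_c = NULL, protocol = sorn_protocol(),
                           eval_steps = 1000,
                           config_overrides = list(),
                           record = "alternation") {
  task_kind <- match.arg(task_kind,
                         c("counting", "motion_prediction",
                           "motion_generation"))
  task <- if (task_kind == "counting") make_counting_sequence(n, m = 10)
          else make_motion_sequence(n, m = 10)
  mode <- if (task_kind == "motion_generation") "generation" else "prediction"
  if (is.null(p_c)) p_c <- default_p_c(n_excitatory)
  args <- c(list(n_excitatory = n_excitatory, symbols = task$alphabet,
                 p_c = p_c, seed = seed), config_overrides)
  config <- do.call(sorn_config, args)
  net <- init_network(config)
  tr <- train(net, task, protocol, mode = mode, record = record)
  report <- evaluate_network(tr$network, task, steps = eval_steps,
                             mode = mode)
  list(report = report, training = tr, config = config)
}

#' Write a run manifest
#'
#' JSON sidecar with the full configuration echo, seed, package version,
#' per-metric results and artifact paths; re-running from the manifest's
#' configuration and seed reproduces the metrics bit-exactly.
#'
#' @param path Output JSON path.
#' @param config,protocol Configuration of the run.
#' @param results Named list of metric values.
#' @param artifacts Named list of file paths (checkpoint, event log, ...).
#' @export
write_manifest <- function(path, config, protocol, results,
                           artifacts = list()) {
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("sornsp")),
         config = unclass(config), protocol = unclass(protocol),
         results = results, artifacts = artifacts),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Reproduce a benchmark table
#'
#' Re-runs the experiment grid behind one of the four benchmark tables:
#' counting performance (`"table2"`), motion prediction (`"table3"`),
#' motion generation (`"table4"`) or the connection-fraction dynamics
#' under four initializations (`"table5"`). Values are mean +/- sd over
#' `seeds`. With `reduced = TRUE` (default) the grid, protocol and seed
#' count are scaled down so the reproduction runs on a laptop; pass
#' `reduced = FALSE` and a full-size protocol for the complete grids.
#'
#' @param table_id `"table2"`, `"table3"`, `"table4"` or `"table5"`.
#' @param reduced Use the reduced grid and protocol.
#' @param seeds Integer vector of seeds.
#' @param protocol Protocol; defaults to a reduced one when
#'   `reduced = TRUE`.
#' @param n_grid Task sizes; defaults depend on `table_id` and `reduced`.
#' @param n_excitatory Network sizes.
#' @return Data frame in long layout (one row per cell and metric) with
#'   columns `N`, `n` (or `p_c0`), `metric`, `mean`, `sd`.
#' @export
reproduce_table <- function(table_id = c("table2", "table3", "table4",
                                         "table5"),
                            reduced = TRUE, seeds = 1:3,
                            protocol = NULL, n_grid = NULL,
                            n_excitatory = NULL) {
  table_id <- match.arg(table_id)
  if (is.null(protocol))
    protocol <- if (reduced)
      sorn_protocol(stage1_steps = 100, stage2_steps = 2000,
                    alternations = 30)
    else sorn_protocol()
  if (is.null(n_excitatory))
    n_excitatory <- if (reduced) 200 else c(200, 400)

  if (table_id == "table5") {
    if (is.null(n_grid)) n_grid <- if (reduced) c(4, 8) else seq(4, 32, 4)
    p_c0 <- c(0.002, 0.01, 0.1, 0.2)
    rows <- list()
    for (N in n_excitatory) for (p0 in p_c0) {
      vals <- unlist(lapply(seeds, function(s) {
        vapply(n_grid, function(nn) {
          ex <- run_experiment("counting", nn, N, seed = s, p_c = p0,
                               protocol = protocol, eval_steps = 200)
          connection_fraction(ex$training$network)
        }, numeric(1))
      }))
      rel <- (vals - p0) / p0
      rows[[length(rows) + 1]] <-
        data.frame(N = N, p_c0 = p0, metric = "p_c1",
                   mean = mean(vals), sd = stats::sd(vals))
      rows[[length(rows) + 1]] <-
        data.frame(N = N, p_c0 = p0, metric = "rel_change",
                   mean = mean(rel), sd = stats::sd(rel))
    }
    return(do.call(rbind, rows))
  }

  task_kind <- switch(table_id, table2 = "counting",
                      table3 = "motion_prediction",
                      table4 = "motion_generation")
  metrics <- switch(table_id,
                    table2 = c("overall", "counting"),
                    table3 = "overall", table4 = "generation")
  if (is.null(n_grid)) n_grid <- if (reduced) c(4, 8) else c(4, 8, 12, 16, 20)
  rows <- list()
  for (N in n_excitatory) for (nn in n_grid) {
    reps <- lapply(seeds, function(s)
      run_experiment(task_kind, nn, N, seed = s, protocol = protocol,
                     eval_steps = 1000)$report)
    for (metric in metrics) {
      vals <- vapply(reps, function(r) r[[metric]], numeric(1))
      rows[[length(rows) + 1]] <-
        data.frame(N = N, n = nn, metric = metric,
                   mean = 100 * mean(vals), sd = 100 * stats::sd(vals))
    }
  }
  do.call(rbind, rows)
}
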