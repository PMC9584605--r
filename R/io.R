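# Plain-text I/O and the pipeline driver. Tabular formats carry unit-bearing
# headers; parameter sets travel as JSON; every pipeline artifact gets a
# provenance sidecar (config hash, seed, package version).

#' Read / write an EPSC train table
#'
#' CSV with header `stimulus_index, ap_time_s, amplitude_nA` and optional
#' `m_j`, `pr_j`, `charge_pC` columns. Parsing is locale-independent (period
#' decimal mark).
#'
#' @param path File path.
#' @return `read_train()` returns an `epsc_train` tibble.
#' @export
read_train <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        locale = readr::locale(decimal_mark = "."))
  need <- c("stimulus_index", "ap_time_s", "amplitude_nA")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("train table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- epsc_train(df$amplitude_nA, ap_times = df$ap_time_s,
                    charges = df[["charge_pC"]])
  for (col in intersect(c("m_j", "pr_j"), names(df))) out[[col]] <- df[[col]]
  out
}

#' @rdname read_train
#' @param train An `epsc_train`.
#' @export
write_train <- function(train, path) {
  cols <- intersect(c("stimulus_index", "ap_time_s", "amplitude_nA", "m_j",
                      "pr_j", "charge_pC"), names(train))
  readr::write_csv(as_tibble(train)[cols], path)
  invisible(path)
}

#' Read / write a sampled current trace
#'
#' Two-column CSV `time_ms, current_nA`; uniform sampling is enforced on read
#' (maximal relative deviation of the sampling interval 1e-6).
#'
#' @param path File path.
#' @return `read_trace()` returns a tibble `time_ms`, `current_nA`.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        locale = readr::locale(decimal_mark = "."))
  if (!all(c("time_ms", "current_nA") %in% names(df))) {
    abort("trace file needs columns `time_ms` and `current_nA`.")
  }
  .check_trace(df)
  as_tibble(df[c("time_ms", "current_nA")])
}

#' @rdname read_trace
#' @param trace A trace tibble.
#' @export
write_trace <- function(trace, path) {
  .check_trace(trace)
  readr::write_csv(as_tibble(trace)[c("time_ms", "current_nA")], path)
  invisible(path)
}

#' Read / write a model parameter file
#'
#' JSON with top-level keys `model` (`"single_pool"` or `"two_step"`),
#' `params`, `calcium`, `pr_dynamics`; field names match the constructor
#' arguments. Unknown keys are rejected.
#'
#' @param path File path.
#' @return A list with `params`, `calcium`, `pr_dyn` (validated objects) and
#'   `model`.
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("model", "params", "calcium", "pr_dynamics")
  extra <- setdiff(names(doc), allowed)
  if (length(extra) > 0) {
    abort(paste0("unknown key(s) in parameter file: ", paste(extra, collapse = ", ")))
  }
  if (!doc$model %in% c("single_pool", "two_step")) {
    abort("`model` must be \"single_pool\" or \"two_step\".")
  }
  ctor <- if (doc$model == "single_pool") single_pool_params else two_step_params
  list(model = doc$model,
       params = do.call(ctor, as.list(doc$params)),
       calcium = do.call(calcium_dynamics, as.list(doc$calcium)),
       pr_dyn = do.call(pr_dynamics, as.list(doc$pr_dynamics)))
}

#' @rdname read_params
#' @param cfg A list with `model`, `params`, `calcium`, `pr_dyn`.
#' @export
write_params <- function(cfg, path) {
  doc <- list(model = cfg$model,
              params = unclass(cfg$params),
              calcium = unclass(cfg$calcium),
              pr_dynamics = unclass(cfg$pr_dyn))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the generate -> simulate -> analyze pipeline
#'
#' Driven by a config list (or JSON file): a stimulation protocol is built,
#' the chosen model simulated, the train written out and analysed with the
#' three quantal estimators and the descriptive metrics. Every artifact gets a
#' `<name>.provenance.json` sidecar recording the config hash, seed, package
#' version and the analysis defaults actually used.
#'
#' @param config Path to a JSON config or an equivalent list. Keys:
#'   `model` (`"single_pool"`/`"two_step"`), `genotype` (for the shipped
#'   calibrations) or `params_file`, `protocol` (list `n_stimuli`, `rate_hz`),
#'   `mode`, `seed`, `analyses` (subset of `"metrics"`, `"eq"`, `"smn"`,
#'   `"nprf"`), optional `noise_sd_nA`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  allowed <- c("model", "genotype", "params_file", "protocol", "mode", "seed",
               "analyses", "noise_sd_nA")
  extra <- setdiff(names(config), allowed)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (is.null(config$seed)) abort("config must carry a `seed`.")
  if (is.null(config$protocol)) abort("config must carry a `protocol` block.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- if (!is.null(config$params_file)) {
    read_params(config$params_file)
  } else {
    rac1_calibration(model = config$model %||% "single_pool",
                     genotype = config$genotype %||% "control")
  }
  mode <- config$mode %||% "deterministic"
  analyses <- config$analyses %||% c("metrics", "eq", "smn", "nprf")
  prov <- list(config = config, config_hash = rlang::hash(config),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("stpkit")),
               defaults = list(eq_n_points = 4, smn_ss_window = 10,
                               smn_corrected = TRUE, metrics_ss_window = 10))
  paths <- list(train = file.path(out_dir, "train.csv"))

  # resume: reuse an existing train artifact generated under the same config
  train_prov <- file.path(out_dir, "train.provenance.json")
  reuse <- file.exists(paths$train) && file.exists(train_prov) &&
    identical(jsonlite::read_json(train_prov)$config_hash, prov$config_hash)
  if (reuse) {
    train <- read_train(paths$train)
  } else {
    prot <- gen_regular_protocol(config$protocol$n_stimuli, config$protocol$rate_hz)
    train <- simulate_train(prot, cfg$params, cfg$calcium, cfg$pr_dyn,
                            mode = mode, seed = config$seed)
    if (!is.null(config$noise_sd_nA) && config$noise_sd_nA > 0) {
      train <- gen_noisy_train(train, config$noise_sd_nA, seed = config$seed + 1)
    }
    write_train(train, paths$train)
  }

  results <- list()
  if ("metrics" %in% analyses) {
    results$metrics <- as.list(train_metrics(train))
  }
  est <- list()
  if ("eq" %in% analyses) est$eq <- tryCatch(as.list(tidy(eq_estimate(train))),
                                             error = function(e) list(error = conditionMessage(e)))
  if ("smn" %in% analyses) est$smn <- tryCatch(as.list(tidy(smn_estimate(train))),
                                               error = function(e) list(error = conditionMessage(e)))
  if ("nprf" %in% analyses) est$nprf <- tryCatch(as.list(tidy(nprf_estimate(train))),
                                                 error = function(e) list(error = conditionMessage(e)))
  results$estimates <- est
  paths$results <- file.path(out_dir, "analysis.json")
  jsonlite::write_json(results, paths$results, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (p in unlist(paths)) {
    jsonlite::write_json(prov, paste0(sub("\\.[^.]+$", "", p), ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(paths)
}
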