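#' Read and validate a run configuration
#'
#' The run configuration is a YAML file with blocks `fixture`, `hu`,
#' `material`, `load_cases`, `remodeling`, `stimulation`, `dielectric` and
#' `run` (days, seed, snapshot_days, fe settings). Unknown keys are
#' rejected with a schema error listing the offending keys; every block is
#' optional and falls back to the documented defaults.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with constructed parameter
#'   objects: `fixture`, `hu`, `mapping`, `load_cases`, `params`,
#'   `protocol` (or `NULL`), `dielectric`, `days`, `seed`,
#'   `snapshot_days`, `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config not found: ", path),
          class = "osteosim_config_not_found")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("malformed config: ", conditionMessage(e)),
          class = "osteosim_schema_error")
  })
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param raw a configuration list (already parsed).
#' @export
build_run_config <- function(raw = list()) {
  known_blocks <- c("fixture", "hu", "material", "load_cases", "remodeling",
                    "stimulation", "dielectric", "run", "mesh_file",
                    "intact_mesh_file")
  bad <- setdiff(names(raw), known_blocks)
  if (length(bad)) {
    abort(paste0("unknown config block(s): ", paste(bad, collapse = ", ")),
          class = "osteosim_schema_error")
  }
  check_keys <- function(block, fn, name) {
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad)) {
      abort(paste0("unknown key(s) in '", name, "': ",
                   paste(bad, collapse = ", ")),
            class = "osteosim_schema_error")
    }
    block
  }
  fixture <- do.call(femur_fixture_params,
                     check_keys(raw$fixture %||% list(),
                                femur_fixture_params, "fixture"))
  hu_args <- check_keys(raw$hu %||% list(), synthetic_hu_field, "hu")
  mapping <- do.call(material_mapping,
                     check_keys(raw$material %||% list(),
                                material_mapping, "material"))
  load_cases <- if (is.null(raw$load_cases)) {
    default_load_cases()
  } else {
    lapply(raw$load_cases, function(lc) {
      do.call(load_case, check_keys(lc, load_case, "load_cases"))
    })
  }
  rem <- raw$remodeling %||% list()
  for (cl in c("cortical", "cancellous")) {
    if (!is.null(rem[[cl]])) rem[[cl]] <- unlist(rem[[cl]])
  }
  params <- do.call(remodeling_params,
                    check_keys(rem, remodeling_params, "remodeling"))
  protocol <- if (!is.null(raw$stimulation)) {
    do.call(stimulation_protocol,
            check_keys(raw$stimulation, stimulation_protocol, "stimulation"))
  }
  dielectric <- do.call(dielectric_params,
                        check_keys(raw$dielectric %||% list(),
                                   dielectric_params, "dielectric"))
  run <- raw$run %||% list()
  run_keys <- c("days", "seed", "snapshot_days", "output_dir")
  bad <- setdiff(names(run), run_keys)
  if (length(bad)) {
    abort(paste0("unknown key(s) in 'run': ", paste(bad, collapse = ", ")),
          class = "osteosim_schema_error")
  }
  structure(list(
    fixture = fixture, hu = hu_args, mapping = mapping,
    load_cases = load_cases, params = params, protocol = protocol,
    dielectric = dielectric,
    mesh_file = raw$mesh_file, intact_mesh_file = raw$intact_mesh_file,
    days = run$days %||% params$total_days,
    seed = run$seed %||% 1L,
    snapshot_days = unlist(run$snapshot_days) %||% integer(),
    output_dir = run$output_dir %||% "."
  ), class = "run_config")
}
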