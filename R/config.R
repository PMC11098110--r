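# Run configuration: YAML files with defaults, validation, and a stable hash.

#' Default run configuration
#'
#' Nested list of defaults for landscape, species, environment and
#' simulation settings.  Defaults follow the headline parameterization:
#' competition strength `b = 0.2`, mean log-fecundity `mu0 = log(1.1)`,
#' regional-stochasticity variance `sigma_r2 = 0.5`, extinction cap
#' `t_max = 5e5` generations, initial density 1000/3600 per unit area.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    landscape = list(type = "fragmented", L = 60, alpha_e = 3,
                     threshold = 1.1, direction = ">",
                     patch_side = 1, spacing = 3, path = NULL),
    species = list(alpha_d = 1, alpha_c = NULL, b = 0.2),
    env = list(mu0 = log(1.1), sigma_r2 = 0.5, alpha_r = Inf),
    sim = list(generations = 250, t_max = 5e5, reps = 100,
               init_density = 1000 / 3600, seed = 1, m = 2,
               distance_bins = c(2, 20))
  )
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys and out-of-range values are rejected; missing keys are
#' filled from [default_config()].  The strings `"Inf"`/`".inf"` are
#' accepted for infinite scales.  An empty or missing `path` yields the
#' full default configuration.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return validated nested configuration list of class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    for (section in names(raw)) {
      if (!section %in% names(cfg))
        stop(sprintf("unknown config section '%s'", section), call. = FALSE)
      if (!is.list(raw[[section]]))
        stop(sprintf("config section '%s' must be a mapping", section),
             call. = FALSE)
      for (key in names(raw[[section]])) {
        if (!key %in% names(cfg[[section]]))
          stop(sprintf("unknown config key '%s.%s'", section, key),
               call. = FALSE)
        # [key] <- list(...) keeps NULL values instead of deleting the entry
        cfg[[section]][key] <- list(raw[[section]][[key]])
      }
    }
  }
  validate_config(cfg)
}

# coerce "Inf"-like strings, then range-check every field
validate_config <- function(cfg) {
  as_num <- function(x) {
    if (is.character(x) && tolower(x) %in% c("inf", ".inf", "infinity"))
      return(Inf)
    suppressWarnings(as.numeric(x))
  }
  for (k in c("alpha_e", "threshold")) cfg$landscape[[k]] <- as_num(cfg$landscape[[k]])
  for (k in c("alpha_d", "alpha_c", "b"))
    if (!is.null(cfg$species[[k]])) cfg$species[[k]] <- as_num(cfg$species[[k]])
  for (k in c("mu0", "sigma_r2", "alpha_r")) cfg$env[[k]] <- as_num(cfg$env[[k]])
  fail <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  ls <- cfg$landscape
  if (!ls$type %in% c("homogeneous", "fragmented", "grid", "regular_grid", "file"))
    fail(sprintf("landscape.type '%s' unknown", ls$type))
  if (ls$L < 2) fail("landscape.L must be >= 2")
  if (!is.na(ls$alpha_e) && ls$alpha_e <= 0) fail("landscape.alpha_e must be > 0")
  sp <- cfg$species
  if (sp$alpha_d <= 0) fail("species.alpha_d must be > 0 (Inf allowed)")
  if (!is.null(sp$alpha_c) && sp$alpha_c <= 0) fail("species.alpha_c must be > 0")
  if (sp$b < 0) fail("species.b must be >= 0")
  en <- cfg$env
  if (en$sigma_r2 < 0) fail("env.sigma_r2 must be >= 0")
  if (en$alpha_r <= 0) fail("env.alpha_r must be > 0 (Inf allowed)")
  sm <- cfg$sim
  if (sm$reps < 1) fail("sim.reps must be >= 1")
  if (sm$generations < 1) fail("sim.generations must be >= 1")
  if (sm$t_max < 1) fail("sim.t_max must be >= 1")
  if (sm$init_density < 0) fail("sim.init_density must be >= 0")
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save a run configuration to YAML
#'
#' `load_config(save_config(cfg, path))` round-trips to an equal
#' configuration (infinities are serialized as `.inf`).
#'
#' @param cfg a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  # precision 17 makes the double round trip exact
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of a canonical JSON serialization; embedded in result files so any
#' output can be traced to the exact configuration that produced it.
#'
#' @param cfg a configuration list.
#' @return 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                           digits = NA, null = "null")), tf)
  unname(tools::md5sum(tf))
}

#' Build model objects from a configuration
#'
#' @param cfg a [load_config()] result.
#' @return list with `landscape`, `species`, `env` ready for the experiment
#'   drivers.  Landscape construction consumes the global RNG; set the seed
#'   first (the CLI uses `sim.seed`).
#' @export
build_from_config <- function(cfg) {
  ls <- cfg$landscape
  land <- switch(ls$type,
    homogeneous = make_homogeneous(ls$L),
    fragmented = make_fragmented(ls$L, alpha_e = ls$alpha_e,
                                 threshold = ls$threshold,
                                 direction = ls$direction),
    grid = ,
    regular_grid = make_regular_grid(ls$L, ls$patch_side, ls$spacing),
    file = read_landscape(ls$path),
    stop("unsupported landscape.type"))
  sp <- cfg$species
  list(landscape = land,
       species = species_params(alpha_d = sp$alpha_d,
                                alpha_c = sp$alpha_c %||% sp$alpha_d,
                                b = sp$b),
       env = env_params(mu0 = cfg$env$mu0, sigma_r2 = cfg$env$sigma_r2,
                        alpha_r = cfg$env$alpha_r))
}
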