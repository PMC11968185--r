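#' Run configuration: defaults, presets, validation, serialization
#'
#' A run configuration is a named list with blocks `landscape`,
#' `architecture`, `demography`, `coa`, and `statistics`, plus top-level
#' `model` (`"coa"` or `"polygenic"`), `seed`, `output_dir`, and optional
#' `preset`. [load_config()] reads one from a JSON file or resolves a preset
#' name, fills defaults, rejects unknown keys, and validates every field
#' (range errors name the offending field via the domain constructors). The
#' fully resolved configuration is echoed into every output file a run
#' writes, so any run can be reconstructed from its JSON header alone.
#'
#' @name run_config
NULL

config_defaults <- function() {
  list(
    model = "polygenic",
    preset = NULL,
    seed = 1L,
    output_dir = ".",
    landscape = list(family = "power", theta = 20, K_m = 1, K_f = 1,
                     c_m = 0.9, c_f = 0.9, b_m = 1.5, b_f = 1.5),
    architecture = list(L = 10, delta = 1, mu = 5e-6, r_adjacent = 0.5,
                        mode = "autosome", r_sdr = 0.5),
    demography = list(n_per_sex = 1000, generations = 10000, burn_in = NULL,
                      sample_every = 100, sample_size = 100),
    coa = list(mu = 1e-3, kernel_sd = NULL, init_x = 0.3),
    statistics = list(het_threshold = 0.25, window = 0.25,
                      maf_threshold = 0.05, n_permutations = 100))
}

# named presets bundling the canonical scenario parameter sets
config_presets <- function() {
  coa_preset <- function(c, b) {
    cfg <- config_defaults()
    cfg$model <- "coa"
    cfg$landscape[c("theta", "c_m", "c_f", "b_m", "b_f")] <-
      list(2, c, c, b, b)
    cfg$demography$n_per_sex <- 500
    cfg$demography$generations <- 50000
    cfg$demography$sample_size <- 10
    cfg$coa$init_x <- 0.3
    cfg
  }
  poly_preset <- function(c_m, c_f, b) {
    cfg <- config_defaults()
    cfg$landscape[c("c_m", "c_f", "b_m", "b_f")] <- list(c_m, c_f, b, b)
    cfg
  }
  list(
    fig2c = coa_preset(0.9, 1.5),   # diversifying: branching
    fig2d = coa_preset(0.05, 0.5),  # stabilizing: unimodal at z* = 0
    fig2e = coa_preset(0.05, 1.5),  # directional: fixation near an optimum
    fig3a_grid = local({
      cfg <- poly_preset(0.9, 0.9, 1.5)
      cfg$grid <- list(c = c(0.05, 0.3, 0.6, 0.9), b = c(0.5, 0.8, 1.5, 3))
      cfg
    }),
    fig3c = poly_preset(0.85 * 0.3, 0.15 * 0.3, 0.5), # remainder locus
    fig4 = local({
      cfg <- poly_preset(0.6, 0.6, 1.5)
      cfg$grid <- list(c = c(0.3, 0.6), b = c(0.8, 1.5))
      cfg
    }))
}

#' Load and validate a run configuration
#'
#' @param source Path to a JSON configuration file, or the name of a stored
#'   preset (`"fig2c"`, `"fig2d"`, `"fig2e"`, `"fig3a_grid"`, `"fig3c"`,
#'   `"fig4"`). An empty file or `NULL` yields the all-defaults
#'   configuration.
#' @return A validated, fully resolved configuration list (class
#'   `run_config`).
#' @export
load_config <- function(source = NULL) {
  presets <- config_presets()
  if (is.null(source)) {
    cfg <- list()
  } else if (source %in% names(presets)) {
    cfg <- presets[[source]]
    cfg$preset <- source
  } else if (file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
    cfg <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
           else list()
    if (!is.null(cfg$preset)) {
      pname <- cfg$preset
      base <- unclass(load_config(pname))
      cfg <- modify_config(base, cfg[names(cfg) != "preset"])
      cfg$preset <- pname
    }
  } else {
    stop(sprintf("config load error: '%s' is neither a file nor a known preset (%s)",
                 source, paste(names(presets), collapse = ", ")),
         call. = FALSE)
  }
  resolved <- modify_config(config_defaults(), cfg)
  validate_config(resolved)
}

# recursive merge with unknown-key rejection at every level
modify_config <- function(base, new, path = "") {
  if (length(new) == 0) return(base)
  if (is.null(names(new)) || any(names(new) == ""))
    stop(sprintf("config load error: unnamed entry in '%s'", path),
         call. = FALSE)
  for (key in names(new)) {
    if (key == "grid" && path == "") { base[[key]] <- new[[key]]; next }
    if (!key %in% config_keys_at(path))
      stop(sprintf("config load error: unknown key '%s%s'", path, key),
           call. = FALSE)
    if (is.list(new[[key]]) && key %in% c("landscape", "architecture",
                                          "demography", "coa", "statistics")) {
      base[[key]] <- modify_config(base[[key]], new[[key]],
                                   paste0(path, key, "$"))
    } else if (!is.null(new[[key]])) {
      base[[key]] <- new[[key]]
    }
  }
  base
}

config_keys_at <- function(path) {
  d <- config_defaults()
  if (path == "") return(names(d))
  block <- sub("\\$$", "", path)
  keys <- names(d[[block]])
  if (block == "landscape") keys <- c(keys, "sigma_m", "sigma_f")
  keys
}

validate_config <- function(cfg) {
  if (!cfg$model %in% c("coa", "polygenic"))
    stop("config field 'model' must be \"coa\" or \"polygenic\"", call. = FALSE)
  check_scalar(cfg$seed, "seed")
  lb <- cfg$landscape
  lp <- if (identical(lb$family, "gaussian"))
    landscape_pair("gaussian", theta = lb$theta, K_m = lb$K_m, K_f = lb$K_f,
                   sigma_m = lb$sigma_m, sigma_f = lb$sigma_f)
  else
    landscape_pair("power", theta = lb$theta, K_m = lb$K_m, K_f = lb$K_f,
                   c_m = lb$c_m, c_f = lb$c_f, b_m = lb$b_m, b_f = lb$b_f)
  ab <- cfg$architecture
  arch <- architecture(L = ab$L, delta = ab$delta, mu = ab$mu,
                       r_adjacent = ab$r_adjacent, mode = ab$mode,
                       r_sdr = ab$r_sdr)
  dem <- cfg$demography
  check_scalar(dem$n_per_sex, "demography$n_per_sex", lower = 2)
  check_scalar(dem$generations, "demography$generations", lower = 1)
  if (!is.null(dem$burn_in))
    check_scalar(dem$burn_in, "demography$burn_in", lower = 0)
  check_scalar(dem$sample_every, "demography$sample_every", lower = 1)
  check_scalar(dem$sample_size, "demography$sample_size", lower = 1)
  check_scalar(cfg$coa$mu, "coa$mu", lower = 0, upper = 1)
  if (!is.null(cfg$coa$kernel_sd))
    check_scalar(cfg$coa$kernel_sd, "coa$kernel_sd", lower = 0, strict = TRUE)
  check_scalar(cfg$coa$init_x, "coa$init_x",
               lower = -lb$theta / 2, upper = lb$theta / 2)
  st <- cfg$statistics
  check_scalar(st$het_threshold, "statistics$het_threshold", lower = 0,
               upper = 0.5)
  check_scalar(st$maf_threshold, "statistics$maf_threshold", lower = 0,
               upper = 0.5)
  check_scalar(st$n_permutations, "statistics$n_permutations", lower = 1)
  if (cfg$model == "polygenic" && abs(arch$theta - lp$theta) > 1e-9)
    stop(sprintf(
      "landscape$theta (%g) must equal 2*sum(architecture$delta) (%g)",
      lp$theta, arch$theta), call. = FALSE)
  structure(cfg, class = "run_config",
            landscape_obj = lp, architecture_obj = arch)
}

#' Serialize a configuration to JSON
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Materialize domain objects from a run configuration
#'
#' `config_landscape()` and `config_architecture()` return the validated
#' [landscape_pair()] and [architecture()] embedded in a `run_config`;
#' `config_coa()` assembles the corresponding [coa_config()].
#'
#' @param cfg A `run_config` from [load_config()].
#' @return The corresponding domain object.
#' @export
config_landscape <- function(cfg) attr(cfg, "landscape_obj")

#' @rdname config_landscape
#' @export
config_architecture <- function(cfg) attr(cfg, "architecture_obj")

#' @rdname config_landscape
#' @export
config_coa <- function(cfg) {
  coa_config(config_landscape(cfg),
             n_per_sex = cfg$demography$n_per_sex,
             mu = cfg$coa$mu, kernel_sd = cfg$coa$kernel_sd,
             generations = cfg$demography$generations,
             init_x = cfg$coa$init_x,
             sample_every = cfg$demography$sample_every,
             sample_size = cfg$demography$sample_size)
}
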