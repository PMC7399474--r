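# Pipeline configuration and the frame manifest.  Configs are strict JSON:
# unknown keys are rejected (silent unit mistakes -- mm vs cm^-1 -- are the
# dominant failure mode in this domain, so fail fast beats permissive).

config_schema <- list(
  fx = "numeric", phases = "numeric", bands = "character",
  pixel_pitch = "numeric", seed = "numeric",
  reference = c("mu_a", "mu_s_prime", "g", "n"),
  mc = c("mu_a_grid", "mu_s_prime_grid", "n_photons", "g", "n", "max_path"),
  inversion = c("initial_mu_a", "initial_mu_s_prime", "mu_a_bounds",
                "mu_s_prime_bounds", "ftol", "xtol", "max_iter"),
  paths = c("frames_dir", "table_file", "output_dir")
)

#' Default pipeline configuration
#'
#' Mirrors the standard acquisition design: spatial frequencies
#' (0, 0.0333, 0.05, 0.1) mm^-1, phases (0, 120, 240) degrees, the five
#' usable bands, and the forward-model / inversion defaults.
#'
#' @return A `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    fx = c(0, 0.0333, 0.05, 0.1),
    phases = c(0, 120, 240),
    bands = c("BB", "GB", "GG", "GR", "RR"),
    pixel_pitch = 0.1,
    seed = 1,
    reference = list(mu_a = 0.05, mu_s_prime = 1.5, g = 0.8, n = 1.4),
    mc = list(mu_a_grid = signif(exp(seq(log(0.005), log(0.5),
                                         length.out = 14)), 6),
              mu_s_prime_grid = signif(exp(seq(log(0.3), log(5),
                                               length.out = 10)), 6),
              n_photons = 1e6, g = 0.8, n = 1.4, max_path = 4000),
    inversion = list(initial_mu_a = 0.1, initial_mu_s_prime = 1.5,
                     mu_a_bounds = c(0.005, 0.5),
                     mu_s_prime_bounds = c(0.3, 5),
                     ftol = 1e-10, xtol = 1e-6, max_iter = 500),
    paths = list(frames_dir = ".", table_file = "mc_table.json",
                 output_dir = ".")
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration (strict JSON)
#'
#' Unknown keys are rejected by name; module-level invariants (>= 2
#' spatial frequencies, three 0/120/240 phases, positive pixel pitch,
#' valid reference properties) are validated at load time.  Missing keys
#' fall back to [default_config()] values.
#'
#' @param path Path to a JSON config file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A config list (parsed JSON).
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (grp in c("reference", "mc", "inversion", "paths")) {
    if (!is.null(cfg[[grp]])) {
      bad <- setdiff(names(cfg[[grp]]), config_schema[[grp]])
      if (length(bad)) {
        stop("unknown config key(s) in '", grp, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  full <- default_config()
  for (nm in names(cfg)) {
    full[[nm]] <- if (is.list(full[[nm]]) && !is.null(names(cfg[[nm]]))) {
      modifyList(full[[nm]], as.list(cfg[[nm]]))
    } else cfg[[nm]]
  }
  if (length(full$fx) < 2) {
    stop("config must list at least two spatial frequencies ",
         "(separating absorption from scattering requires >= 2 fx)")
  }
  if (!isTRUE(all.equal(sort(as.numeric(full$phases)), c(0, 120, 240)))) {
    stop("phases must be exactly 0, 120, 240 degrees")
  }
  if (any(full$fx < 0) || is.unsorted(full$fx, strictly = TRUE)) {
    stop("fx must be ascending and >= 0 (units: mm^-1)")
  }
  if (full$pixel_pitch <= 0) stop("pixel_pitch must be > 0 (mm per pixel)")
  ref <- full$reference
  optical_properties(ref$mu_a, ref$mu_s_prime, ref$g, ref$n)  # validates
  structure(full, class = "pipeline_config")
}

#' Write a config snapshot next to run outputs
#' @param cfg A `pipeline_config`.
#' @param path Output JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a frame manifest CSV
#'
#' The manifest lists every acquired frame:
#' `sample, band, fx_index, phase_index, path, role` with role `sample`
#' or `reference`.  `read_manifest()` checks factorial completeness
#' (every band x fx x phase combination present once per sample) and,
#' optionally, file existence.
#'
#' @param manifest Data frame with the columns above.
#' @param path CSV path.
#' @param check_files Verify that the referenced frame files exist.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  needed <- c("sample", "band", "fx_index", "phase_index", "path", "role")
  stopifnot(all(needed %in% names(manifest)))
  cols <- c(needed, intersect("exposure", names(manifest)))
  write.csv(manifest[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_files = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample", "band", "fx_index", "phase_index", "path", "role")
  if (!all(needed %in% names(m))) {
    stop("manifest is missing column(s): ",
         paste(setdiff(needed, names(m)), collapse = ", "))
  }
  for (s in unique(m$sample)) {
    ms <- m[m$sample == s, ]
    counts <- table(ms$band, ms$fx_index, ms$phase_index)
    if (any(counts != 1)) {
      stop("manifest is not factorially complete for sample '", s,
           "' (need one frame per band x fx x phase)")
    }
  }
  if (check_files && !all(file.exists(m$path))) {
    stop("manifest references missing file(s): ",
         paste(utils::head(m$path[!file.exists(m$path)], 3), collapse = ", "))
  }
  m
}
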