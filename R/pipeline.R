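# End-to-end processing: frames on disk -> demodulated AC maps ->
# calibrated Rd maps -> per-pixel optical-property maps.

#' Theoretical reference reflectance per (fx, band)
#'
#' Evaluates the forward model at the reference phantom's properties for
#' each band center wavelength and spatial frequency; these are the
#' `Rd_ref` values the calibration step scales by.
#'
#' @param table A [build_table()] reflectance table.
#' @param ref_spec [phantom_spec()] of the reference phantom.
#' @param bands Named list of `band_responsivity` (for center wavelengths).
#' @param fx_list Spatial frequencies.
#' @return Named numeric vector keyed `"fx|band"`.
#' @export
reference_rd <- function(table, ref_spec, bands, fx_list) {
  out <- numeric(0)
  for (bname in names(bands)) {
    l0 <- band_stats(bands[[bname]])$lambda0
    props <- phantom_properties(ref_spec, l0, g = table$metadata$g,
                                n = table$metadata$n)
    rd <- lookup_rd(table, props, fx_list)
    names(rd) <- vapply(fx_list, ref_key, character(1), band = bname)
    out <- c(out, rd)
  }
  out
}

demodulate_manifest <- function(manifest, fx_list) {
  maps <- list()
  for (bname in unique(manifest$band)) {
    for (fi in sort(unique(manifest$fx_index))) {
      sel <- manifest[manifest$band == bname & manifest$fx_index == fi, ]
      sel <- sel[order(sel$phase_index), ]
      if (nrow(sel) != 3) {
        stop("need exactly 3 phases for band ", bname, ", fx index ", fi)
      }
      tri <- phase_triplet(read_frame(sel$path[1]), read_frame(sel$path[2]),
                           read_frame(sel$path[3]),
                           fx = fx_list[fi], band = bname)
      dm <- demodulate(tri)
      # normalize by the recorded exposure so differently exposed
      # acquisitions are comparable (MAC is linear in exposure)
      expo <- if ("exposure" %in% names(sel)) sel$exposure[1] else 1
      dm$mac <- dm$mac / expo
      maps[[ref_key(fx_list[fi], bname)]] <- dm
    }
  }
  maps
}

#' Process one acquisition manifest into optical-property maps
#'
#' Full pipeline: read the sample and reference frames, demodulate each
#' three-phase stack, calibrate sample MAC against the reference MAC and
#' the reference phantom's theoretical reflectance, and invert per pixel
#' for (mu_a, mu_s') maps per band.
#'
#' @param manifest Manifest data frame covering one sample (`role ==
#'   "sample"`) and one reference (`role == "reference"`).
#' @param table A reflectance table.
#' @param fx_list Spatial frequencies, indexed by the manifest's
#'   `fx_index`.
#' @param ref_spec [phantom_spec()] of the reference phantom.
#' @param bands Named list of `band_responsivity` for the acquired bands.
#' @param config An [inversion_config()]; its `fx_subset` selects the
#'   frequencies used in the fit.
#' @param smooth_ref Median-smooth the reference MAC (see [calibrate()]).
#' @return Named list of [fit_image()] `property_map`s, one per band,
#'   with the calibrated Rd maps attached as attribute `rd_maps`.
#' @export
process_acquisition <- function(manifest, table, fx_list, ref_spec, bands,
                                config = inversion_config(),
                                smooth_ref = TRUE) {
  sm <- manifest[manifest$role == "sample", ]
  rm_ <- manifest[manifest$role == "reference", ]
  if (!nrow(sm) || !nrow(rm_)) {
    stop("manifest must contain both sample and reference frames")
  }
  mac_sample <- demodulate_manifest(sm, fx_list)
  mac_ref <- demodulate_manifest(rm_, fx_list)
  rd_ref <- reference_rd(table, ref_spec, bands, fx_list)
  ref <- calibration_reference(mac_ref, rd_ref)
  fx_fit <- config$fx_subset
  out <- list()
  rd_all <- list()
  for (bname in unique(sm$band)) {
    rd_maps <- lapply(fx_fit, function(fx) {
      key <- ref_key(fx, bname)
      if (!key %in% names(mac_sample)) {
        stop("no acquired frames for fx = ", fx, ", band = ", bname)
      }
      calibrate(mac_sample[[key]], ref, smooth_ref = smooth_ref)
    })
    rd_all[[bname]] <- rd_maps
    out[[bname]] <- fit_image(rd_maps, fx_fit, table, config)
  }
  attr(out, "rd_maps") <- rd_all
  out
}

#' Export per-band property maps as float TIFF + CSV summary
#'
#' @param maps Named list of `property_map`s (from
#'   [process_acquisition()]).
#' @param tiff_path Multi-page 32-bit float TIFF output (two pages per
#'   band: mu_a then mu_s').
#' @param csv_path Summary CSV (band, FOV means, percent converged).
#' @export
export_property_maps <- function(maps, tiff_path, csv_path) {
  pages <- list()
  rows <- list()
  for (bname in names(maps)) {
    m <- maps[[bname]]
    pages <- c(pages, list(m$mu_a_map, m$mu_s_prime_map))
    rows[[bname]] <- data.frame(band = bname, fov_mu_a = m$fov_mu_a,
                                fov_mu_s_prime = m$fov_mu_s_prime,
                                pct_converged = 100 * mean(m$converged))
  }
  write_float_tiff(pages, tiff_path)
  write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  invisible(list(tiff = tiff_path, csv = csv_path))
}
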