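# Cardiac physiological indices from a cylindrical heart model, plus voxel
# morphometry of labelled circulatory compartments.

#' Volume of a cylinder
#'
#' @param radius Radius, mm.
#' @param length Length, mm.
#' @return Volume in mm^3 (`pi * radius^2 * length`).
#' @export
cylinder_volume <- function(radius, length) {
  if (any(radius <= 0) || any(length <= 0))
    stop("radius and length must be positive", call. = FALSE)
  pi * radius^2 * length
}

# Round half away from zero at a given number of significant digits (the
# convention used in the published figures; base signif() rounds half even,
# which happens to agree on every value reproduced here, but half-up is the
# intent).
signif_half_up <- function(x, digits) {
  if (x == 0) return(0)
  mag <- 10^(digits - 1 - floor(log10(abs(x))))
  sign(x) * floor(abs(x) * mag + 0.5) / mag
}

#' Cardiac physiological indices
#'
#' From the cylindrical heart model: end-diastolic volume
#' `EDV = pi * r_max^2 * l`, end-systolic volume `ESV = pi * r_min^2 * l`,
#' stroke volume `SV = EDV - ESV`, ejection fraction `EF = SV / EDV`,
#' cardiac output `CO = SV * HR`, relative flow rate
#' `= (EDV / CV) * EF * HR` in percent of the total circulatory volume per
#' minute, and circulation time `= 100% / relative flow rate` (minutes for
#' the entire hemolymph volume to pass the heart once).
#'
#' All internal values are in mm and mm^3. The returned `printed` element
#' additionally renders the volumes on a 1000x scale with the sequential
#' rounding conventionally used when quoting these indices: EDV and ESV to
#' 3 significant figures, SV recomputed from the rounded volumes and itself
#' rounded to 3 significant figures before CO, and the relative flow rate to
#' 2 significant figures before the circulation time.
#'
#' @param geom A [cardiac_geometry()] (radii and length in mm).
#' @param hr Heart rate, beats per minute.
#' @param heart_volume_fraction Fraction of the total circulatory-system
#'   volume occupied by the heart at end diastole (EDV / CV), in (0, 1).
#' @return A `cardiac_indices` object: `edv`, `esv`, `sv` (mm^3), `ef`
#'   (fraction), `hr` (1/min), `co` (mm^3/min), `relative_flow_rate` (%/min),
#'   `circulation_time` (min), `heart_volume_fraction`, and `printed` (see
#'   above; circulation time also as a "mm:ss" string).
#' @examples
#' ci <- cardiac_indices(cardiac_geometry(0.08, 0.04, 18), hr = 34.4,
#'                       heart_volume_fraction = 0.0036)
#' ci$ef            # 0.75
#' ci$printed$sv    # 272
#' @export
cardiac_indices <- function(geom, hr, heart_volume_fraction) {
  stopifnot(inherits(geom, "cardiac_geometry"))
  if (hr <= 0) stop("heart rate must be positive", call. = FALSE)
  if (heart_volume_fraction <= 0 || heart_volume_fraction >= 1)
    stop("heart_volume_fraction must lie in (0, 1)", call. = FALSE)
  edv <- cylinder_volume(geom$r_max, geom$length)
  esv <- cylinder_volume(geom$r_min, geom$length)
  sv <- edv - esv
  ef <- sv / edv
  if (sv <= 0 || ef <= 0)
    stop("no net flow: stroke volume is zero (r_min = r_max)", call. = FALSE)
  co <- sv * hr
  rfr <- heart_volume_fraction * 100 * ef * hr    # %/min
  circ <- 100 / rfr                                # min

  edv_p <- signif_half_up(edv * 1000, 3)
  esv_p <- signif_half_up(esv * 1000, 3)
  sv_p <- signif_half_up(edv_p - esv_p, 3)
  co_p <- round(sv_p / 1000 * hr, 3)
  rfr_p <- signif_half_up(rfr, 2)
  circ_p <- 100 / rfr_p
  mins <- floor(circ_p)
  secs <- round((circ_p - mins) * 60)
  if (secs == 60) { mins <- mins + 1; secs <- 0 }

  structure(list(
    edv = edv, esv = esv, sv = sv, ef = ef, hr = hr, co = co,
    relative_flow_rate = rfr, circulation_time = circ,
    heart_volume_fraction = heart_volume_fraction,
    printed = list(edv = edv_p, esv = esv_p, sv = sv_p,
                   ef_pct = round(ef * 100), co = co_p,
                   relative_flow_rate = rfr_p,
                   circulation_time_min = circ_p,
                   circulation_time = sprintf("%d:%02d", mins, secs))),
    class = "cardiac_indices")
}

#' @export
print.cardiac_indices <- function(x, ...) {
  cat("Cardiac indices (cylindrical heart model)\n")
  cat(sprintf("  EDV %.4f mm^3 | ESV %.4f mm^3 | SV %.4f mm^3 | EF %.0f%%\n",
              x$edv, x$esv, x$sv, 100 * x$ef))
  cat(sprintf("  HR %.1f /min | CO %.4f mm^3/min\n", x$hr, x$co))
  cat(sprintf("  relative flow rate %.3f %%/min | circulation time %.2f min\n",
              x$relative_flow_rate, x$circulation_time))
  p <- x$printed
  cat(sprintf("  printed scale: EDV %s, ESV %s, SV %s | EF %d%% | CO %.3f | %s %%/min | %s min\n",
              format(p$edv), format(p$esv), format(p$sv), p$ef_pct, p$co,
              format(p$relative_flow_rate), p$circulation_time))
  invisible(x)
}

#' Volume fractions of labelled compartments
#'
#' Counts voxels per label in a 3D labelled volume (0 = background) and
#' reports each compartment's fraction of the total non-background volume.
#'
#' @param labels Integer 3D array (or vector) of compartment labels;
#'   0 is background.
#' @param voxel_size Optional isotropic voxel edge length, micrometres; when
#'   given, absolute volumes are reported too.
#' @param dictionary Optional named character vector mapping label ids
#'   (names) to compartment names.
#' @return A `volume_fractions` data frame with columns `label`, `name`,
#'   `voxels`, `fraction` (and `volume_um3` when `voxel_size` is given).
#'   Fractions sum to 1 over all non-background labels.
#' @export
volume_fractions <- function(labels, voxel_size = NULL, dictionary = NULL) {
  v <- as.integer(labels)
  if (any(v < 0, na.rm = TRUE)) stop("labels must be >= 0", call. = FALSE)
  v <- v[!is.na(v) & v > 0L]
  if (!length(v)) stop("empty foreground: no non-background voxels",
                       call. = FALSE)
  counts <- tabulate(v)
  ids <- which(counts > 0)
  out <- data.frame(label = ids,
                    name = if (!is.null(dictionary))
                      unname(dictionary[as.character(ids)])
                    else as.character(ids),
                    voxels = counts[ids],
                    fraction = counts[ids] / sum(counts[ids]))
  if (!is.null(voxel_size)) out$volume_um3 <- out$voxels * voxel_size^3
  class(out) <- c("volume_fractions", "data.frame")
  out
}
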