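#' Helium-ion microscopy point thickness measure
#'
#' One cross-section point measure of lamina thickness with its working
#' distance and nesting identifiers (individual / scale / position), matching
#' the layout of the per-point thickness source tables.
#'
#' @param raw_nm raw measured thickness in nm, > 0.
#' @param working_distance_um working distance d in micrometres, > 0.
#' @param individual_id,scale_id,position_id identifiers.
#' @param treatment treatment / group label.
#' @return object of class `thickness_measure`.
#' @export
thickness_measure <- function(raw_nm, working_distance_um,
                              individual_id = NA, scale_id = NA,
                              position_id = NA, treatment = NA) {
  stopifnot(raw_nm > 0, working_distance_um > 0)
  structure(list(raw_nm = raw_nm, working_distance_um = working_distance_um,
                 individual_id = individual_id, scale_id = scale_id,
                 position_id = position_id, treatment = treatment),
            class = "thickness_measure")
}

#' Reference working distance (micrometres) for the HIM correction
#' @export
HIM_REFERENCE_WD_UM <- 9058

#' Working-distance correction for HIM thickness measures
#'
#' Rescales a raw point measure for slight variations in working distance
#' not captured by the instrument scale bar:
#' \eqn{T_{correct} = T_{raw} \cdot d / 9058\,\mu m}, with d the measured
#' working distance and 9058 um the reference working distance. Linear in
#' both arguments; identity at the reference distance.
#'
#' @param m a [thickness_measure()], or a numeric raw thickness (nm) when
#'   `working_distance_um` is supplied.
#' @param working_distance_um working distance(s), used for numeric input.
#' @param reference_um reference working distance (default 9058).
#' @return corrected thickness in nm.
#' @export
#' @examples
#' correct_working_distance(100, 9058)   # 100
#' correct_working_distance(100, 4529)   # 50
correct_working_distance <- function(m, working_distance_um = NULL,
                                     reference_um = HIM_REFERENCE_WD_UM) {
  if (inherits(m, "thickness_measure")) {
    raw <- m$raw_nm; d <- m$working_distance_um
  } else {
    stopifnot(is.numeric(m), !is.null(working_distance_um))
    raw <- m; d <- working_distance_um
  }
  stopifnot(all(raw > 0), all(d > 0), reference_um > 0)
  raw * d / reference_um
}

#' Worst-case tilt underestimation bound
#'
#' A cross-section viewed at tilt angle t projects to \eqn{T \cos t}, so the
#' underestimate is at most \eqn{T (1 - \cos t)}. With the inflection-point
#' criterion limiting erroneous tilt to 5 degrees, the bound is below 1 nm
#' for all laminae up to 260 nm.
#'
#' @param thickness_nm true thickness in nm.
#' @param max_tilt_deg worst-case tilt from perpendicular, degrees in [0, 90).
#' @return bound in nm.
#' @export
#' @examples
#' tilt_underestimate_bound(260, 5)  # 0.99 nm
tilt_underestimate_bound <- function(thickness_nm, max_tilt_deg) {
  stopifnot(all(max_tilt_deg >= 0), all(max_tilt_deg < 90))
  thickness_nm * (1 - cos(max_tilt_deg * pi / 180))
}

#' Summarize corrected thickness measures by group
#'
#' Applies the working-distance correction and aggregates point measures per
#' treatment: mean, sample SD over point measures (matching "+/- SD"
#' reporting), and nesting counts for downstream hierarchical statistics.
#' Groups falling below the sampling minimum (12 points from 3 scales) are
#' flagged, not dropped.
#'
#' @param measures data.frame with columns `treatment`, `individual_id`,
#'   `scale_id`, `position_id`, `raw_nm`, `working_distance_um` (the
#'   thickness-table CSV schema), or a list of [thickness_measure()].
#' @param min_points,min_scales sampling minima used for the flag.
#' @return data.frame: `treatment`, `mean_nm`, `sd_nm`, `n_individuals`,
#'   `n_scales`, `n_points`, `below_minimum`.
#' @export
summarize_thickness <- function(measures, min_points = 12, min_scales = 3) {
  if (is.list(measures) && !is.data.frame(measures) &&
      all(vapply(measures, inherits, logical(1), "thickness_measure")))
    measures <- do.call(rbind, lapply(measures, function(m)
      as.data.frame(unclass(m), stringsAsFactors = FALSE)))
  need <- c("treatment", "individual_id", "scale_id", "raw_nm",
            "working_distance_um")
  if (!all(need %in% names(measures)))
    stop("missing columns: ", paste(setdiff(need, names(measures)), collapse = ", "))
  measures$corrected_nm <- correct_working_distance(
    measures$raw_nm, measures$working_distance_um)
  out <- do.call(rbind, lapply(split(measures, measures$treatment), function(g) {
    data.frame(treatment = g$treatment[1],
               mean_nm = mean(g$corrected_nm),
               sd_nm = stats::sd(g$corrected_nm),
               n_individuals = length(unique(g$individual_id)),
               n_scales = length(unique(paste(g$individual_id, g$scale_id))),
               n_points = nrow(g))
  }))
  out$below_minimum <- out$n_points < min_points | out$n_scales < min_scales
  if (any(out$below_minimum))
    warning("group(s) below sampling minimum: ",
            paste(out$treatment[out$below_minimum], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / b`: e.g. cover-scale lamina means of 187 vs 107 nm give
#' a ~74 percent increase.
#'
#' @param a,b group means (same units).
#' @return percent difference of `a` relative to `b`.
#' @export
percent_increase <- function(a, b) 100 * (a - b) / b

#' Read / write the thickness-table CSV
#'
#' Columns `treatment, individual_id, scale_id, position_id, raw_nm,
#' working_distance_um`, mirroring the per-point source-data tables.
#'
#' @param path file path.
#' @param measures data.frame in the schema above.
#' @return `read_thickness_csv` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
read_thickness_csv <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  need <- c("treatment", "individual_id", "scale_id", "position_id",
            "raw_nm", "working_distance_um")
  if (!all(need %in% names(d)))
    stop("thickness CSV missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' @rdname read_thickness_csv
#' @export
write_thickness_csv <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
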