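#' Construct an emission spectrum
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param intensity Fluorescence intensities (arbitrary units), same length.
#' @param ligand One of "NMM", "CV", "none".
#' @param excitation_nm Excitation wavelength (393 nm for NMM, 540 nm for
#'   CV in the standard assay); NA if unknown.
#' @param sample_id Sample identifier.
#' @param metadata Free-form list (buffer, PEG percentage, DNA
#'   concentration, ...).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity,
                              ligand = c("none", "NMM", "CV"),
                              excitation_nm = NA_real_,
                              sample_id = "", metadata = list()) {
  ligand <- match.arg(ligand)
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength_nm and intensity must have the same length")
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two points")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength_nm must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 ligand = ligand, excitation_nm = excitation_nm,
                 sample_id = sample_id, metadata = metadata),
            class = "emission_spectrum")
}

#' Mean intensity around a peak wavelength
#'
#' Averages the (piecewise-linearly interpolated) spectrum over the window
#' \[wavelength - half_window, wavelength + half_window\]; the integral is
#' evaluated exactly on the interpolant, with linear interpolation at the
#' window edges. With `half_window = 0` the interpolated point value is
#' returned.
#'
#' @param spectrum An [emission_spectrum()].
#' @param wavelength Query wavelength in nm; the window must lie within the
#'   spectrum's coverage.
#' @param half_window Half-width of the averaging window in nm (default 2).
#' @return Mean intensity over the window.
#' @export
peak_intensity <- function(spectrum, wavelength, half_window = 2) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  w <- spectrum$wavelength_nm; y <- spectrum$intensity
  lo <- wavelength - half_window; hi <- wavelength + half_window
  if (lo < w[1] || hi > w[length(w)])
    stop(sprintf("window [%g, %g] nm outside spectrum coverage [%g, %g] nm",
                 lo, hi, w[1], w[length(w)]))
  if (half_window == 0)
    return(stats::approx(w, y, xout = wavelength)$y)
  knots <- sort(unique(c(lo, hi, w[w > lo & w < hi])))
  vals <- stats::approx(w, y, xout = knots)$y
  area <- sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
  area / (hi - lo)
}

#' Subtract a control spectrum from a sample spectrum
#'
#' The control (e.g. a non-GQ-forming 18-mer, which shows only negligible
#' nonspecific ligand binding) is interpolated onto the sample's wavelength
#' grid and subtracted pointwise; the result is floored at zero.
#'
#' @param spectrum,control [emission_spectrum()] objects with the same
#'   ligand and excitation; the control must cover the sample's wavelength
#'   range.
#' @return A background-subtracted `emission_spectrum`.
#' @export
subtract_background <- function(spectrum, control) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(control, "emission_spectrum"))
  if (spectrum$ligand != control$ligand)
    stop("sample and control ligands differ (", spectrum$ligand, " vs ",
         control$ligand, ")")
  if (is.finite(spectrum$excitation_nm) && is.finite(control$excitation_nm) &&
      spectrum$excitation_nm != control$excitation_nm)
    stop("sample and control excitation wavelengths differ")
  w <- spectrum$wavelength_nm
  cw <- control$wavelength_nm
  if (w[1] < cw[1] || w[length(w)] > cw[length(cw)])
    stop("control spectrum does not cover the sample's wavelength range")
  bg <- stats::approx(cw, control$intensity, xout = w)$y
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - bg, 0)
  out
}

#' Extract NMM/CV peak readouts from a set of spectra
#'
#' Groups spectra by sample and reads the NMM peaks at 610 and 670 nm and
#' the CV peak at 640 nm with [peak_intensity()].
#'
#' @param spectra List of [emission_spectrum()] objects (one NMM and/or one
#'   CV spectrum per sample).
#' @param half_window Averaging half-window in nm passed to
#'   [peak_intensity()].
#' @return Data frame with columns `sample_id`, `nmm_610`, `nmm_670`,
#'   `cv_640` (NA where a channel is missing).
#' @export
ligand_readouts <- function(spectra, half_window = 2) {
  if (length(spectra) == 0L) stop("no spectra supplied")
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  out <- data.frame(sample_id = unique(ids),
                    nmm_610 = NA_real_, nmm_670 = NA_real_,
                    cv_640 = NA_real_, stringsAsFactors = FALSE)
  for (s in spectra) {
    i <- match(s$sample_id, out$sample_id)
    if (s$ligand == "NMM") {
      out$nmm_610[i] <- peak_intensity(s, 610, half_window)
      out$nmm_670[i] <- peak_intensity(s, 670, half_window)
    } else if (s$ligand == "CV") {
      out$cv_640[i] <- peak_intensity(s, 640, half_window)
    }
  }
  out
}

#' Normalize ligand readouts to a reference sample
#'
#' Scales each channel so that the reference sample (the 1-1-1 construct in
#' the standard assay) reads 100 percent, adding `nmm_percent` (from the
#' 610 nm peak) and `cv_percent` (640 nm) columns.
#'
#' @param readouts Data frame from [ligand_readouts()].
#' @param reference_sample_id `sample_id` of the reference.
#' @return `readouts` with percentage columns added/recomputed.
#' @export
normalize_to_reference <- function(readouts, reference_sample_id) {
  i <- match(reference_sample_id, readouts$sample_id)
  if (is.na(i)) stop("reference sample '", reference_sample_id, "' not found")
  ref_nmm <- readouts$nmm_610[i]; ref_cv <- readouts$cv_640[i]
  if (!is.finite(ref_nmm) || ref_nmm <= 0)
    stop("reference NMM 610 nm intensity is zero or missing; normalization undefined")
  if (!is.finite(ref_cv) || ref_cv <= 0)
    stop("reference CV 640 nm intensity is zero or missing; normalization undefined")
  readouts$nmm_percent <- 100 * readouts$nmm_610 / ref_nmm
  readouts$cv_percent <- 100 * readouts$cv_640 / ref_cv
  readouts
}

.cluster_classes <- c("parallel", "antiparallel", "unfolded")

#' Fit cluster centroids from labeled calibration readouts
#'
#' Computes the per-class mean point in the (NMM percent, CV percent)
#' plane from labeled calibration samples, the supervised analogue of the
#' crosshair cluster centres in the dual-ligand scatter plot.
#'
#' @param labeled_points Data frame with columns `nmm_percent`,
#'   `cv_percent` and `class` (every one of parallel, antiparallel,
#'   unfolded must be present).
#' @param metric `"standardized_euclidean"` (default; channels z-scored
#'   with the calibration set's mean and SD so both contribute equally) or
#'   `"euclidean"`.
#' @return An object of class `gq_cluster_model` with the 3 x 2 centroid
#'   matrix, the scaling and the metric.
#' @export
fit_centroids <- function(labeled_points,
                          metric = c("standardized_euclidean", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(labeled_points),
            all(c("nmm_percent", "cv_percent", "class") %in% names(labeled_points)))
  cls <- as.character(labeled_points$class)
  missing <- setdiff(.cluster_classes, unique(cls))
  if (length(missing) > 0L)
    stop("calibration data lacks class(es): ", paste(missing, collapse = ", "))
  cent <- t(vapply(.cluster_classes, function(k) {
    sel <- cls == k
    c(nmm_percent = mean(labeled_points$nmm_percent[sel]),
      cv_percent = mean(labeled_points$cv_percent[sel]))
  }, numeric(2)))
  center <- c(nmm_percent = mean(labeled_points$nmm_percent),
              cv_percent = mean(labeled_points$cv_percent))
  scale_sd <- c(nmm_percent = stats::sd(labeled_points$nmm_percent),
                cv_percent = stats::sd(labeled_points$cv_percent))
  scale_sd[!is.finite(scale_sd) | scale_sd == 0] <- 1
  if (any(duplicated(cent)))
    stop("fitted centroids are not pairwise distinct")
  structure(list(centroids = cent, center = center, scale_sd = scale_sd,
                 metric = metric),
            class = "gq_cluster_model")
}

#' Classify a two-channel readout by nearest centroid
#'
#' @param point Numeric vector `c(nmm_percent, cv_percent)`.
#' @param model A [fit_centroids()] model.
#' @return List with `class` (nearest centroid; ties broken in the fixed
#'   order parallel, antiparallel, unfolded) and the named `distances` to
#'   all three centroids.
#' @export
classify_point <- function(point, model) {
  stopifnot(inherits(model, "gq_cluster_model"))
  p <- as.numeric(point)
  if (length(p) != 2L || any(!is.finite(p)))
    stop("point must be a finite (nmm_percent, cv_percent) pair")
  sc <- if (model$metric == "standardized_euclidean") model$scale_sd else c(1, 1)
  d <- sqrt(((p[1] - model$centroids[, 1]) / sc[1])^2 +
            ((p[2] - model$centroids[, 2]) / sc[2])^2)
  names(d) <- rownames(model$centroids)
  list(class = .cluster_classes[which.min(d)], distances = d)
}

#' Classify many readouts by nearest centroid
#'
#' @param readouts Data frame with `nmm_percent` and `cv_percent` columns.
#' @param model A [fit_centroids()] model.
#' @return `readouts` with a `class` column appended.
#' @export
classify_points <- function(readouts, model) {
  readouts$class <- vapply(seq_len(nrow(readouts)), function(i)
    classify_point(c(readouts$nmm_percent[i], readouts$cv_percent[i]),
                   model)$class, character(1))
  readouts
}

#' Pearson product-moment correlation with input validation
#'
#' Used to quantify agreement between independent GQ assays (e.g. induced
#' ligand fluorescence versus quenching measurements of the same
#' constructs).
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input")
  stats::cor(x, y)
}
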