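#' Compute apparent FRET efficiency from a two-channel trace
#'
#' Apparent FRET is the background-corrected acceptor intensity divided by
#' the background-corrected total intensity,
#' E = (I_A - b_A) / ((I_D - b_D) + (I_A - b_A)). Frames whose corrected
#' total falls at or below `denominator_floor` are marked invalid;
#' efficiencies are clamped to \[-0.1, 1.1\] for histogramming. No gamma,
#' leakage or direct-excitation corrections are applied.
#'
#' @param trace A [simulate_trace()] trace (or any list with `molecule_id`,
#'   `time`, `donor`, `acceptor`).
#' @param background_donor,background_acceptor Per-channel background
#'   intensities subtracted before the ratio.
#' @param denominator_floor Minimum corrected total intensity for a frame
#'   to count (default 10 intensity units).
#' @return An object of class `fret_trace`: `molecule_id`, `time`,
#'   `efficiency`, logical `valid` per frame, and `valid_frames`
#'   (initially the trace length; reduced by
#'   [detect_bleach_and_truncate()]).
#' @export
compute_fret <- function(trace, background_donor = 0, background_acceptor = 0,
                         denominator_floor = 10) {
  if (length(trace$donor) == 0L) stop("empty trace")
  dA <- trace$acceptor - background_acceptor
  dD <- trace$donor - background_donor
  den <- dD + dA
  valid <- is.finite(den) & den > denominator_floor
  e <- rep(NA_real_, length(den))
  e[valid] <- dA[valid] / den[valid]
  e <- pmin(pmax(e, -0.1), 1.1)
  structure(list(molecule_id = trace$molecule_id, time = trace$time,
                 efficiency = e, valid = valid,
                 valid_frames = length(e)),
            class = "fret_trace")
}

#' Select dual-labeled molecules via the red-pulse marker
#'
#' Keeps molecules whose mean acceptor intensity during the initial direct
#' acceptor-excitation (red laser) pulse exceeds
#' `background_mean + k * channel_noise_sd`, removing donor-only
#' molecules before histogramming. When traces carry no red-pulse record,
#' selection can fall back (explicit opt-in) to requiring the mean FRET
#' acceptor signal over the first second above background; because that
#' mean averages away channel noise, its threshold uses the standard
#' error `channel_noise_sd / sqrt(n_frames_averaged)`, keeping the
#' criterion sensitive to low-FRET (duplex) molecules whose acceptor
#' signal is much weaker than under direct excitation.
#'
#' @param dataset A `fret_dataset`.
#' @param background_mean,channel_noise_sd Threshold inputs; default to the
#'   dataset's simulation config.
#' @param k Threshold multiplier (default 5).
#' @param allow_no_redpulse Permit the first-second acceptor fallback when
#'   the red-pulse record is missing (default FALSE).
#' @return List with logical `kept` per molecule, `n_kept`, `n_discarded`
#'   and the `threshold` used.
#' @export
select_dual_labeled <- function(dataset, background_mean = NULL,
                                channel_noise_sd = NULL, k = 5,
                                allow_no_redpulse = FALSE) {
  cfg <- dataset$config
  if (is.null(background_mean)) background_mean <- cfg$background_mean
  if (is.null(channel_noise_sd)) channel_noise_sd <- cfg$channel_noise_sd
  if (is.null(background_mean) || is.null(channel_noise_sd))
    stop("background_mean and channel_noise_sd must be supplied when the dataset carries no config")
  thr <- background_mean + k * channel_noise_sd
  has_red <- vapply(dataset$traces,
                    function(t) !is.null(t$red_pulse_acceptor), logical(1))
  if (!all(has_red)) {
    if (!allow_no_redpulse)
      stop("red-pulse acceptor record missing for ", sum(!has_red),
           " molecule(s); re-run with allow_no_redpulse = TRUE to fall back ",
           "to first-second acceptor selection")
    kept <- vapply(dataset$traces, function(t) {
      if (!is.null(t$red_pulse_acceptor))
        return(mean(t$red_pulse_acceptor) > thr)
      nfirst <- min(length(t$acceptor),
                    max(1L, round(1 / diff(t$time[1:2]))))
      thr_fb <- background_mean + k * channel_noise_sd / sqrt(nfirst)
      mean(t$acceptor[seq_len(nfirst)]) > thr_fb
    }, logical(1))
  } else {
    kept <- vapply(dataset$traces,
                   function(t) mean(t$red_pulse_acceptor) > thr,
                   logical(1))
  }
  list(kept = kept, n_kept = sum(kept), n_discarded = sum(!kept),
       threshold = thr)
}

#' Truncate a FRET trace at photobleaching
#'
#' Sets `valid_frames` to the last frame before the first run of at least
#' `min_run` consecutive frames whose total intensity (donor + acceptor)
#' drops below `background_mean + 3 * channel_noise_sd`, restricting all
#' downstream analysis to the pre-bleach portion of the trace. The total
#' is smoothed with a 3-frame median filter before thresholding so that
#' isolated bright noise frames after the bleach do not delay detection.
#'
#' @param ftrace A [compute_fret()] trace.
#' @param trace The matching raw two-channel trace.
#' @param background_mean,channel_noise_sd Threshold inputs.
#' @param min_run Consecutive sub-threshold frames required (default 3).
#' @return The `fret_trace` with `valid_frames` updated.
#' @export
detect_bleach_and_truncate <- function(ftrace, trace, background_mean,
                                       channel_noise_sd, min_run = 3L) {
  total <- trace$donor + trace$acceptor
  if (length(total) >= 3L) total <- stats::runmed(total, 3L)
  below <- total < background_mean + 3 * channel_noise_sd
  n <- length(below)
  if (n >= min_run) {
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & runs$lengths >= min_run)
    ftrace$valid_frames <- if (length(hit) > 0L) starts[hit[1]] - 1L else n
  } else {
    ftrace$valid_frames <- if (all(below)) 0L else n
  }
  ftrace
}

#' Build a FRET histogram from truncated traces
#'
#' Bins the first `min(frames_per_molecule, valid_frames)` valid frames of
#' each trace into `n_bins` uniform bins over \[-0.1, 1.1\].
#'
#' @param ftraces List of (truncated) `fret_trace` objects.
#' @param frames_per_molecule Frames contributed per molecule (default 10,
#'   i.e. the first second of each trace).
#' @param n_bins Number of bins (default 60).
#' @param n_fields Optional number of imaging fields, recorded as
#'   metadata.
#' @return An object of class `fret_histogram`: `bin_edges`, `bin_centers`,
#'   `counts`, `n_molecules` (contributing at least one frame),
#'   `n_frames`, `n_fields`.
#' @export
build_histogram <- function(ftraces, frames_per_molecule = 10L, n_bins = 60L,
                            n_fields = NA_integer_) {
  if (length(ftraces) == 0L) stop("no traces supplied to build_histogram")
  lo <- -0.1; hi <- 1.1
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  vals <- vector("list", length(ftraces))
  n_mol <- 0L
  for (i in seq_along(ftraces)) {
    ft <- ftraces[[i]]
    k <- min(frames_per_molecule, ft$valid_frames)
    if (k < 1L) next
    idx <- seq_len(k)
    v <- ft$efficiency[idx][ft$valid[idx]]
    v <- v[is.finite(v)]
    if (length(v) > 0L) {
      n_mol <- n_mol + 1L
      vals[[i]] <- v
    }
  }
  v <- unlist(vals, use.names = FALSE)
  if (length(v) == 0L)
    stop("no valid frames available: empty FRET histogram")
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_molecules = n_mol,
                 n_frames = length(v), n_fields = n_fields),
            class = "fret_histogram")
}

.gauss <- function(x, amp, mean, sd) amp * exp(-(x - mean)^2 / (2 * sd^2))

.aicc <- function(rss, n, k) {
  rss <- max(rss, .Machine$double.eps)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Quantify the folded fraction from a FRET histogram
#'
#' Least-squares fit of a two-Gaussian curve to the histogram counts
#' (low-FRET duplex component and high-FRET folded component), with the
#' folded percentage taken as the area of the high-FRET Gaussian over the
#' total fitted area. A single-Gaussian model is also fitted and preferred
#' when it lowers the small-sample-corrected information score (AICc); in
#' that case the folded percentage is 100 or 0 according to whether the
#' single component lies above or below the 0.55 split point.
#'
#' Initialization: means 0.3 and 0.8, SDs 0.08, amplitudes from the
#' histogram mass on either side of 0.55. Constraints: low mean in
#' \[0, 0.55), high mean in (0.55, 1.05\], SDs in \[0.02, 0.25\],
#' amplitudes nonnegative.
#'
#' @param hist A [build_histogram()] result.
#' @param split FRET value separating the two components (default 0.55).
#' @return An object of class `folded_fraction_result`: `folded_percent`,
#'   `fit` (model type, means, SDs, areas, RSS, AICc of both models) and
#'   `n_molecules_used`.
#' @export
fit_folded_fraction <- function(hist, split = 0.55) {
  stopifnot(inherits(hist, "fret_histogram"))
  x <- hist$bin_centers
  y <- as.numeric(hist$counts)
  if (sum(y) == 0) stop("empty FRET histogram")
  bw <- diff(hist$bin_edges[1:2])
  mass_lo <- sum(y[x < split]) * bw
  mass_hi <- sum(y[x >= split]) * bw
  s0 <- 0.08
  amp0 <- function(mass) max(mass / (s0 * sqrt(2 * pi)), 1e-6)
  df <- data.frame(x = x, y = y)

  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        a2 * exp(-(x - m2)^2 / (2 * s2^2)),
      data = df,
      start = list(a1 = amp0(mass_lo), m1 = 0.3, s1 = s0,
                   a2 = amp0(mass_hi), m2 = 0.8, s2 = s0),
      lower = c(a1 = 0, m1 = 0, s1 = 0.02, a2 = 0, m2 = split + 1e-3,
                s2 = 0.02),
      upper = c(a1 = Inf, m1 = split - 1e-3, s1 = 0.25, a2 = Inf, m2 = 1.05,
                s2 = 0.25),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  m0 <- if (mass_hi >= mass_lo) 0.8 else 0.3
  fit1 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - m)^2 / (2 * s^2)),
      data = df,
      start = list(a = amp0(mass_lo + mass_hi), m = m0, s = s0),
      lower = c(a = 0, m = -0.1, s = 0.02),
      upper = c(a = Inf, m = 1.05, s = 0.25),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit2, "error") && inherits(fit1, "error"))
    stop("Gaussian fit did not converge: two-component: ",
         conditionMessage(fit2), "; single-component: ",
         conditionMessage(fit1))

  n <- length(y)
  rss <- function(f) sum(stats::resid(f)^2)
  aicc2 <- if (inherits(fit2, "error")) Inf else .aicc(rss(fit2), n, 7L)
  aicc1 <- if (inherits(fit1, "error")) Inf else .aicc(rss(fit1), n, 4L)

  if (aicc1 < aicc2) {
    cf <- stats::coef(fit1)
    high <- cf[["m"]] > split
    area <- cf[["a"]] * cf[["s"]] * sqrt(2 * pi)
    fit <- list(model = "single_component",
                mean_low = if (high) NA_real_ else cf[["m"]],
                mean_high = if (high) cf[["m"]] else NA_real_,
                sd_low = if (high) NA_real_ else cf[["s"]],
                sd_high = if (high) cf[["s"]] else NA_real_,
                area_low = if (high) 0 else area,
                area_high = if (high) area else 0,
                rss = rss(fit1), aicc_single = aicc1, aicc_two = aicc2)
    pct <- if (high) 100 else 0
  } else {
    cf <- stats::coef(fit2)
    area_lo <- cf[["a1"]] * cf[["s1"]] * sqrt(2 * pi)
    area_hi <- cf[["a2"]] * cf[["s2"]] * sqrt(2 * pi)
    fit <- list(model = "two_component",
                mean_low = cf[["m1"]], mean_high = cf[["m2"]],
                sd_low = cf[["s1"]], sd_high = cf[["s2"]],
                area_low = area_lo, area_high = area_hi,
                rss = rss(fit2), aicc_single = aicc1, aicc_two = aicc2)
    pct <- if (area_lo + area_hi > 0) 100 * area_hi / (area_lo + area_hi)
    else NA_real_
  }
  structure(list(folded_percent = pct, fit = fit,
                 n_molecules_used = hist$n_molecules),
            class = "folded_fraction_result")
}

#' Detect dynamic (reversibly folding) FRET traces
#'
#' Smooths the valid portion of the efficiency series with a 3-frame
#' median filter and counts state transitions with hysteresis: the trace
#' commits to the high or low state only after leaving the `band` on the
#' opposite side from the last committed state for at least
#' `commit_frames` consecutive smoothed frames, so single-frame
#' excursions (noise or residual post-bleach frames) are not counted. A
#' trace is dynamic when it shows at least `min_transitions` committed
#' transitions.
#'
#' @param ftrace A truncated `fret_trace`.
#' @param band Hysteresis band (default `c(0.45, 0.65)`).
#' @param min_valid Minimum valid frames for a trace to be scored
#'   (default 20); shorter traces are excluded from the dynamics
#'   denominator.
#' @param min_transitions Committed transitions required to call a trace
#'   dynamic (default 2).
#' @param commit_frames Consecutive out-of-band smoothed frames required
#'   to commit a state (default 3).
#' @return List with `is_dynamic`, `n_transitions` and `excluded`
#'   (TRUE when the trace is too short to score).
#' @export
classify_dynamic <- function(ftrace, band = c(0.45, 0.65), min_valid = 20L,
                             min_transitions = 2L, commit_frames = 3L) {
  idx <- seq_len(ftrace$valid_frames)
  e <- ftrace$efficiency[idx][ftrace$valid[idx]]
  e <- e[is.finite(e)]
  if (length(e) < min_valid)
    return(list(is_dynamic = NA, n_transitions = NA_integer_,
                excluded = TRUE))
  sm <- if (length(e) >= 3L) stats::runmed(e, 3L) else e
  state <- ifelse(sm > band[2], 1L, ifelse(sm < band[1], -1L, 0L))
  nz <- state[state != 0L]
  n_trans <- 0L
  if (length(nz) > 0L) {
    r <- rle(nz)
    committed <- r$values[r$lengths >= commit_frames]
    if (length(committed) > 1L)
      n_trans <- sum(diff(committed) != 0L)
  }
  list(is_dynamic = n_trans >= min_transitions,
       n_transitions = as.integer(n_trans), excluded = FALSE)
}

#' Run the full smFRET quantitation pipeline on a dataset
#'
#' Computes apparent FRET for every molecule, removes donor-only
#' molecules via the red-pulse marker, truncates traces at
#' photobleaching, builds the FRET histogram from the first
#' `frames_per_molecule` frames of each dual-labeled molecule, fits the
#' two-Gaussian folded fraction and scores dynamic traces. Deterministic
#' given the dataset and settings.
#'
#' @param dataset A `fret_dataset` (simulated or read from a trace store).
#' @param frames_per_molecule,n_bins Histogram settings (defaults 10, 60).
#' @param dual_label_k Red-pulse threshold multiplier (default 5).
#' @param dynamic_band,min_dynamic_frames,min_transitions Dynamics
#'   settings (defaults as in [classify_dynamic()]).
#' @param denominator_floor Passed to [compute_fret()].
#' @param allow_no_redpulse Passed to [select_dual_labeled()].
#' @return An object of class `fret_report`: `folded`
#'   (a `folded_fraction_result`), `dynamics` (`percent_dynamic`,
#'   `n_dynamic`, `n_evaluated`, `n_excluded`, `transition_counts`,
#'   thresholds) and `qc` (molecule/field/selection counts).
#' @export
analyze_dataset <- function(dataset,
                            frames_per_molecule = 10L,
                            n_bins = 60L,
                            dual_label_k = 5,
                            dynamic_band = c(0.45, 0.65),
                            min_dynamic_frames = 20L,
                            min_transitions = 2L,
                            commit_frames = 3L,
                            denominator_floor = 10,
                            allow_no_redpulse = FALSE) {
  if (length(dataset$traces) == 0L) stop("dataset contains no traces")
  cfg <- dataset$config
  bg <- cfg$background_mean
  noise <- cfg$channel_noise_sd
  sel <- select_dual_labeled(dataset, bg, noise, k = dual_label_k,
                             allow_no_redpulse = allow_no_redpulse)
  kept_idx <- which(sel$kept)
  if (length(kept_idx) == 0L) stop("no dual-labeled molecules selected")
  ftraces <- vector("list", length(kept_idx))
  for (j in seq_along(kept_idx)) {
    tr <- dataset$traces[[kept_idx[j]]]
    ft <- compute_fret(tr, bg, bg, denominator_floor = denominator_floor)
    ftraces[[j]] <- detect_bleach_and_truncate(ft, tr, bg, noise)
  }
  n_fields <- length(unique(dataset$field))
  hist <- build_histogram(ftraces, frames_per_molecule, n_bins,
                          n_fields = n_fields)
  folded <- fit_folded_fraction(hist)
  dyn <- lapply(ftraces, classify_dynamic, band = dynamic_band,
                min_valid = min_dynamic_frames,
                min_transitions = min_transitions,
                commit_frames = commit_frames)
  excluded <- vapply(dyn, function(d) isTRUE(d$excluded), logical(1))
  is_dyn <- vapply(dyn[!excluded], function(d) isTRUE(d$is_dynamic),
                   logical(1))
  n_eval <- sum(!excluded)
  dynamics <- list(
    percent_dynamic = if (n_eval > 0) 100 * sum(is_dyn) / n_eval else NA_real_,
    n_dynamic = sum(is_dyn), n_evaluated = n_eval,
    n_excluded = sum(excluded),
    transition_counts = vapply(dyn, function(d)
      if (is.na(d$n_transitions)) NA_integer_ else d$n_transitions,
      integer(1)),
    band = dynamic_band, min_valid_frames = min_dynamic_frames,
    min_transitions = min_transitions)
  qc <- list(n_molecules = length(dataset$traces),
             n_fields = n_fields,
             n_dual_labeled = sel$n_kept,
             n_donor_only_removed = sel$n_discarded,
             dual_label_threshold = sel$threshold,
             histogram_molecules = hist$n_molecules,
             histogram_frames = hist$n_frames)
  structure(list(folded = folded, dynamics = dynamics, qc = qc,
                 histogram = hist),
            class = "fret_report")
}
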