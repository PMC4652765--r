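#' Configuration for simulating smFRET trace datasets
#'
#' Generative parameters for two-channel (donor/acceptor) single-molecule
#' FRET traces of surface-tethered DNA constructs. Each molecule is either
#' donor-only (no active acceptor), statically folded (high-FRET
#' quadruplex, apparent E around 0.8), statically duplexed (low FRET,
#' around 0.3), or dynamic (reversible folding/unfolding modelled as a
#' two-state continuous-time Markov chain discretized exactly per frame).
#' Each molecule has a constant total emission intensity drawn once,
#' additive Gaussian channel noise, a constant per-channel background, and
#' exponentially distributed donor/acceptor photobleaching times. A short
#' direct acceptor-excitation (red laser) pulse at the start of acquisition
#' marks molecules carrying an active acceptor.
#'
#' @param n_molecules Number of molecules to simulate.
#' @param frame_interval Camera frame time in seconds (default 0.1, i.e.
#'   100 ms time resolution).
#' @param n_frames Frames per trace (default 600, one minute).
#' @param folded_fraction Probability that a static dual-labeled molecule
#'   is in the folded (high-FRET) state.
#' @param e_folded,e_duplex Apparent FRET efficiencies of the folded and
#'   duplex states (defaults 0.8 and 0.3).
#' @param total_intensity_mean,total_intensity_sd Per-molecule total
#'   emission intensity distribution (photons/frame; defaults 500 and 50).
#' @param channel_noise_sd Additive Gaussian noise SD per channel per frame
#'   (default 30).
#' @param background_mean Constant background level added to each channel
#'   (default 50).
#' @param donor_only_fraction Fraction of molecules lacking an active
#'   acceptor (default 0.2).
#' @param dynamic_fraction Fraction of dual-labeled molecules showing
#'   reversible folding/unfolding dynamics (default 0).
#' @param k_unfold,k_fold Folded-to-duplex and duplex-to-folded rates in
#'   per-second units for the dynamic subpopulation (defaults 1).
#' @param donor_bleach_mean_s,acceptor_bleach_mean_s Mean photobleaching
#'   times in seconds (defaults 60); `Inf` disables bleaching.
#' @param red_pulse_frames Frames of the direct acceptor-excitation marker
#'   pulse (default 5).
#' @param molecules_per_field Two-element range of molecules per imaging
#'   field of view (default 400-500).
#' @param seed Integer seed making the whole dataset reproducible.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(n_molecules = 1000L,
                             frame_interval = 0.1,
                             n_frames = 600L,
                             folded_fraction = 0.5,
                             e_folded = 0.8,
                             e_duplex = 0.3,
                             total_intensity_mean = 500,
                             total_intensity_sd = 50,
                             channel_noise_sd = 30,
                             background_mean = 50,
                             donor_only_fraction = 0.2,
                             dynamic_fraction = 0,
                             k_unfold = 1,
                             k_fold = 1,
                             donor_bleach_mean_s = 60,
                             acceptor_bleach_mean_s = 60,
                             red_pulse_frames = 5L,
                             molecules_per_field = c(400L, 500L),
                             seed = 1L) {
  cfg <- list(n_molecules = as.integer(n_molecules),
              frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              folded_fraction = folded_fraction,
              e_folded = e_folded, e_duplex = e_duplex,
              total_intensity_mean = total_intensity_mean,
              total_intensity_sd = total_intensity_sd,
              channel_noise_sd = channel_noise_sd,
              background_mean = background_mean,
              donor_only_fraction = donor_only_fraction,
              dynamic_fraction = dynamic_fraction,
              k_unfold = k_unfold, k_fold = k_fold,
              donor_bleach_mean_s = donor_bleach_mean_s,
              acceptor_bleach_mean_s = acceptor_bleach_mean_s,
              red_pulse_frames = as.integer(red_pulse_frames),
              molecules_per_field = as.integer(molecules_per_field),
              seed = as.integer(seed))
  props <- c("folded_fraction", "donor_only_fraction", "dynamic_fraction")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$n_molecules < 1L) stop("n_molecules must be positive")
  if (cfg$frame_interval <= 0) stop("frame_interval must be positive")
  if (cfg$n_frames < 1L) stop("n_frames must be positive")
  if (cfg$k_unfold < 0 || cfg$k_fold < 0) stop("rates must be nonnegative")
  if (cfg$e_folded <= cfg$e_duplex) stop("e_folded must exceed e_duplex")
  if (cfg$channel_noise_sd < 0 || cfg$total_intensity_sd < 0 ||
      cfg$background_mean < 0)
    stop("noise, intensity SD and background must be nonnegative")
  if (length(cfg$molecules_per_field) != 2L ||
      any(cfg$molecules_per_field < 1L) ||
      cfg$molecules_per_field[1] > cfg$molecules_per_field[2])
    stop("molecules_per_field must be an increasing positive range")
  if (cfg$red_pulse_frames < 1L) stop("red_pulse_frames must be positive")
  structure(cfg, class = "trace_sim_config")
}

## Exact one-frame transition probabilities of the two-state chain with
## rates a = k_unfold (folded -> duplex) and b = k_fold (duplex -> folded):
## closed-form matrix exponential of the 2x2 rate matrix.
.markov_step_probs <- function(k_unfold, k_fold, dt) {
  s <- k_unfold + k_fold
  if (s == 0) return(c(p_ff = 1, p_dd = 1, p_folded_stat = 0.5))
  e <- exp(-s * dt)
  c(p_ff = k_fold / s + k_unfold / s * e,
    p_dd = k_unfold / s + k_fold / s * e,
    p_folded_stat = k_fold / s)
}

.sample_state_path <- function(n, p_ff, p_dd, p0_folded) {
  path <- logical(n)
  path[1] <- stats::runif(1) < p0_folded
  u <- stats::runif(n - 1L)
  for (i in seq_len(n - 1L)) {
    path[i + 1L] <- if (path[i]) u[i] < p_ff else u[i] >= p_dd
  }
  path
}

#' Simulate one smFRET trace
#'
#' Draws a molecule class, intensity, bleach times and a per-frame state
#' path, and renders donor/acceptor intensity series plus the
#' red-pulse acceptor marker, with the generating truth attached.
#'
#' @param config A [trace_sim_config()].
#' @param molecule_index Identifier recorded in the trace.
#' @param class Optional class override, one of `"donor_only"`,
#'   `"static_folded"`, `"static_duplex"`, `"dynamic"`; drawn from the
#'   configured fractions when NULL.
#' @param seed Optional seed; when NULL the current RNG stream is used
#'   (as when called from [simulate_dataset()]).
#' @return An object of class `fret_trace_raw`: `time`, `donor`,
#'   `acceptor`, `red_pulse_acceptor` and a `truth` list (`class`,
#'   per-frame `state_path`, bleach frames and the molecule's total
#'   intensity).
#' @export
simulate_trace <- function(config, molecule_index = 1L, class = NULL,
                           seed = NULL) {
  stopifnot(inherits(config, "trace_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_frames
  dt <- config$frame_interval
  if (is.null(class)) {
    u <- stats::runif(2)
    class <- if (u[1] < config$donor_only_fraction) "donor_only"
    else if (u[2] < config$dynamic_fraction) "dynamic"
    else if (stats::runif(1) < config$folded_fraction) "static_folded"
    else "static_duplex"
  }
  class <- match.arg(class, c("donor_only", "static_folded", "static_duplex",
                              "dynamic"))
  I <- max(stats::rnorm(1, config$total_intensity_mean,
                        config$total_intensity_sd), 1)
  bleach_frame <- function(mean_s) {
    if (!is.finite(mean_s) || mean_s <= 0) return(NA_integer_)
    t <- stats::rexp(1, rate = 1 / mean_s)
    f <- floor(t / dt) + 1L          # first frame at/after the bleach time
    if (f > n) NA_integer_ else as.integer(f)
  }
  db <- bleach_frame(config$donor_bleach_mean_s)
  ab <- bleach_frame(config$acceptor_bleach_mean_s)

  e_path <- switch(class,
    donor_only = rep(NA_real_, n),
    static_folded = rep(config$e_folded, n),
    static_duplex = rep(config$e_duplex, n),
    dynamic = {
      p <- .markov_step_probs(config$k_unfold, config$k_fold, dt)
      folded <- .sample_state_path(n, p["p_ff"], p["p_dd"], p["p_folded_stat"])
      ifelse(folded, config$e_folded, config$e_duplex)
    })
  state_path <- switch(class,
    donor_only = rep("donor_only", n),
    static_folded = rep("folded", n),
    static_duplex = rep("duplex", n),
    dynamic = ifelse(e_path == config$e_folded, "folded", "duplex"))

  has_acceptor <- class != "donor_only"
  frames <- seq_len(n)
  acceptor_alive <- has_acceptor & (is.na(ab) | frames < ab)
  donor_alive <- is.na(db) | frames < db

  donor_sig <- ifelse(donor_alive,
                      ifelse(acceptor_alive, I * (1 - e_path), I),
                      0)
  donor_sig[donor_alive & !has_acceptor] <- I
  acceptor_sig <- ifelse(donor_alive & acceptor_alive, I * e_path, 0)
  acceptor_sig[is.na(acceptor_sig)] <- 0   # donor-only molecules
  donor_sig[is.na(donor_sig)] <- I         # donor-only, pre donor bleach

  noise <- function(k) if (config$channel_noise_sd > 0)
    stats::rnorm(k, 0, config$channel_noise_sd) else numeric(k)
  donor <- pmax(donor_sig + config$background_mean + noise(n), 0)
  acceptor <- pmax(acceptor_sig + config$background_mean + noise(n), 0)

  red_on <- has_acceptor && (is.na(ab) || ab > 1L)
  red_sig <- if (red_on) I else 0
  red <- pmax(red_sig + config$background_mean +
                noise(config$red_pulse_frames), 0)

  structure(list(molecule_id = as.integer(molecule_index),
                 time = (frames - 1L) * dt,
                 donor = donor, acceptor = acceptor,
                 red_pulse_acceptor = red,
                 truth = list(class = class, state_path = state_path,
                              donor_bleach_frame = db,
                              acceptor_bleach_frame = ab,
                              total_intensity = I)),
            class = "fret_trace_raw")
}

#' Simulate a full smFRET dataset
#'
#' Simulates `n_molecules` traces, partitions them into imaging fields of
#' view of uniformly drawn size within `molecules_per_field`, and attaches
#' the generating truth. Bit-identical for a given configuration (the seed
#' is part of the configuration).
#'
#' @param config A [trace_sim_config()].
#' @return An object of class `fret_dataset`: list with `traces` (list of
#'   [simulate_trace()] outputs), `config`, `field` (per-molecule field
#'   index) and a `manifest` data frame (`molecule_id`, `field`, `class`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed)
  nm <- config$n_molecules
  lohi <- config$molecules_per_field
  sizes <- integer(0)
  while (sum(sizes) < nm) {
    sizes <- c(sizes, if (lohi[1] == lohi[2]) lohi[1]
               else sample(lohi[1]:lohi[2], 1L))
  }
  field <- rep(seq_along(sizes), sizes)[seq_len(nm)]
  traces <- vector("list", nm)
  for (i in seq_len(nm)) traces[[i]] <- simulate_trace(config, i)
  manifest <- data.frame(
    molecule_id = seq_len(nm),
    field = field,
    class = vapply(traces, function(t) t$truth$class, character(1)),
    stringsAsFactors = FALSE)
  structure(list(traces = traces, config = config, field = field,
                 manifest = manifest),
            class = "fret_dataset")
}

#' Simulate a ligand emission spectrum
#'
#' Renders an idealized NMM spectrum (Gaussian peaks at 610 and 670 nm) or
#' CV spectrum (single Gaussian at 640 nm) on a 550-750 nm grid at 1 nm
#' steps, with peak amplitude proportional to the sample's response level
#' plus additive noise.
#'
#' @param ligand `"NMM"` or `"CV"`.
#' @param response_level Proportion in \[0, 1\] scaling the peak amplitude
#'   (1 corresponds to a fully folded reference construct).
#' @param amplitude Peak amplitude at response level 1 (default 100).
#' @param noise_sd Additive Gaussian noise SD (default 0.5; 0 for an exact
#'   spectrum).
#' @param sample_id Sample identifier.
#' @param seed Optional seed; NULL uses the current RNG stream.
#' @return An [emission_spectrum()].
#' @export
simulate_spectrum <- function(ligand = c("NMM", "CV"), response_level,
                              amplitude = 100, noise_sd = 0.5,
                              sample_id = "", seed = NULL) {
  ligand <- match.arg(ligand)
  if (response_level < 0 || response_level > 1)
    stop("response_level must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  wl <- 550:750
  amp <- amplitude * response_level
  y <- if (ligand == "NMM") {
    amp * exp(-(wl - 610)^2 / (2 * 12^2)) +
      0.6 * amp * exp(-(wl - 670)^2 / (2 * 15^2))
  } else {
    amp * exp(-(wl - 640)^2 / (2 * 15^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(wl), 0, noise_sd)
  emission_spectrum(wl, pmax(y, 0), ligand = ligand,
                    excitation_nm = if (ligand == "NMM") 393 else 540,
                    sample_id = sample_id)
}

#' Simulate a labeled dual-ligand calibration panel
#'
#' Generates NMM and CV spectra for samples drawn from three conformation
#' groups with well-separated response levels (parallel: high NMM / low
#' CV; antiparallel: low NMM / high CV; unfolded: both low), emulating the
#' three-cluster structure of the dual-ligand scatter plot. The first
#' parallel sample plays the role of the fully folded reference construct.
#'
#' @param n_per_class Samples per conformation class (default 8).
#' @param noise_sd Spectral noise SD passed to [simulate_spectrum()].
#' @param seed Integer seed.
#' @return List with `spectra` (list of [emission_spectrum()]), `labels`
#'   (data frame `sample_id`, `class`) and `reference_id`.
#' @export
simulate_ligand_panel <- function(n_per_class = 8L, noise_sd = 0.5,
                                  seed = 1L) {
  set.seed(seed)
  ranges <- list(
    parallel = list(nmm = c(0.7, 1.0), cv = c(0.02, 0.10)),
    antiparallel = list(nmm = c(0.05, 0.20), cv = c(0.60, 0.95)),
    unfolded = list(nmm = c(0.01, 0.08), cv = c(0.01, 0.08)))
  spectra <- list(); ids <- character(0); cls <- character(0)
  for (k in names(ranges)) {
    for (j in seq_len(n_per_class)) {
      id <- sprintf("%s_%02d", k, j)
      nmm_r <- if (k == "parallel" && j == 1L) 1.0
        else stats::runif(1, ranges[[k]]$nmm[1], ranges[[k]]$nmm[2])
      cv_r <- stats::runif(1, ranges[[k]]$cv[1], ranges[[k]]$cv[2])
      spectra[[length(spectra) + 1L]] <-
        simulate_spectrum("NMM", nmm_r, noise_sd = noise_sd, sample_id = id)
      spectra[[length(spectra) + 1L]] <-
        simulate_spectrum("CV", cv_r, noise_sd = noise_sd, sample_id = id)
      ids <- c(ids, id); cls <- c(cls, k)
    }
  }
  list(spectra = spectra,
       labels = data.frame(sample_id = ids, class = cls,
                           stringsAsFactors = FALSE),
       reference_id = "parallel_01")
}

#' Packaged simulation configurations for the calibration constructs
#'
#' Returns a [trace_sim_config()] whose ground-truth folded fraction is
#' the measured dsDNA folded percentage of the construct (from the
#' packaged calibration map): CMYC 92 percent, 1-3-3 86, 1-4-4 66,
#' 1-5-5 58 and (TTA)3 0.
#'
#' @param construct One of "CMYC", "1-3-3", "1-4-4", "1-5-5", "TTA3".
#' @param n_molecules,seed Passed to [trace_sim_config()].
#' @param ... Further overrides passed to [trace_sim_config()].
#' @return A `trace_sim_config`.
#' @export
gq_fixture_config <- function(construct = c("CMYC", "1-3-3", "1-4-4",
                                            "1-5-5", "TTA3"),
                              n_molecules = 5000L, seed = 7L, ...) {
  construct <- match.arg(construct)
  loops <- switch(construct,
                  "CMYC" = c(1L, 2L, 1L),
                  "1-3-3" = c(1L, 3L, 3L),
                  "1-4-4" = c(1L, 4L, 4L),
                  "1-5-5" = c(1L, 5L, 5L),
                  "TTA3" = c(3L, 3L, 3L))
  ff <- predict_ds_folded_fraction(loops) / 100
  trace_sim_config(n_molecules = n_molecules, folded_fraction = ff,
                   seed = seed, ...)
}
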