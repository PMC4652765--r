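fake_trace <- function(donor, acceptor, dt = 0.1) {
  structure(list(molecule_id = 1L, time = (seq_along(donor) - 1) * dt,
                 donor = donor, acceptor = acceptor,
                 red_pulse_acceptor = rep(1000, 5),
                 truth = NULL),
            class = "fret_trace_raw")
}

test_that("apparent FRET follows the acceptor-over-total definition", {
  ft <- compute_fret(fake_trace(rep(500, 10), rep(500, 10)))
  expect_equal(ft$efficiency, rep(0.5, 10))
  ft0 <- compute_fret(fake_trace(rep(500, 10), rep(0, 10)))
  expect_equal(ft0$efficiency, rep(0, 10))
  # background subtraction enters both numerator and denominator
  ftb <- compute_fret(fake_trace(rep(150, 5), rep(450, 5)),
                      background_donor = 50, background_acceptor = 50)
  expect_equal(ftb$efficiency, rep(0.8, 5))
  # frames at/below the denominator floor are invalid
  ftf <- compute_fret(fake_trace(c(500, 4), c(500, 5)))
  expect_equal(ftf$valid, c(TRUE, FALSE))
  expect_true(is.na(ftf$efficiency[2]))
  # clamping to [-0.1, 1.1]
  ftc <- compute_fret(fake_trace(c(-100), c(400)))
  expect_equal(ftc$efficiency, 1.1)
  expect_error(compute_fret(fake_trace(numeric(0), numeric(0))), "empty")
})

test_that("noiseless simulated traces invert to the configured state value", {
  cfg <- noiseless_config(n_molecules = 1, folded_fraction = 1, n_frames = 30)
  tr <- simulate_trace(cfg, seed = 3)
  ft <- compute_fret(tr, cfg$background_mean, cfg$background_mean)
  expect_equal(ft$efficiency, rep(cfg$e_folded, 30))
})

test_that("red-pulse selection separates donor-only molecules perfectly", {
  cfg <- trace_sim_config(n_molecules = 400, n_frames = 5,
                          donor_only_fraction = 0.3, seed = 17)
  d <- simulate_dataset(cfg)
  sel <- select_dual_labeled(d)
  expect_equal(sel$kept, d$manifest$class != "donor_only")
  expect_equal(sel$n_kept + sel$n_discarded, 400L)
})

test_that("kept fraction tracks the dual-labeled rate binomially", {
  cfg <- trace_sim_config(n_molecules = 5000, n_frames = 2,
                          donor_only_fraction = 0.3, seed = 23)
  d <- simulate_dataset(cfg)
  sel <- select_dual_labeled(d)
  expect_lt(abs(sel$n_kept - 3500), 3 * sqrt(5000 * 0.3 * 0.7))
})

test_that("missing red-pulse record errors unless the fallback is enabled", {
  cfg <- trace_sim_config(n_molecules = 20, n_frames = 15,
                          donor_only_fraction = 0.5, seed = 5)
  d <- simulate_dataset(cfg)
  for (i in seq_along(d$traces)) d$traces[[i]]$red_pulse_acceptor <- NULL
  expect_error(select_dual_labeled(d), "allow_no_redpulse")
  sel <- select_dual_labeled(d, allow_no_redpulse = TRUE)
  expect_equal(sel$kept, d$manifest$class != "donor_only")
})

test_that("bleach truncation finds the truth bleach frame", {
  cfg <- trace_sim_config(n_molecules = 1, n_frames = 600, seed = 6,
                          folded_fraction = 1, donor_only_fraction = 0,
                          acceptor_bleach_mean_s = Inf)
  # force a donor bleach near frame 200 by resampling until one lands there
  set.seed(42)
  repeat {
    tr <- simulate_trace(cfg, class = "static_folded")
    db <- tr$truth$donor_bleach_frame
    if (!is.na(db) && db > 150 && db < 450) break
  }
  ft <- compute_fret(tr, cfg$background_mean, cfg$background_mean)
  ft <- detect_bleach_and_truncate(ft, tr, cfg$background_mean,
                                   cfg$channel_noise_sd)
  expect_lt(abs(ft$valid_frames - (db - 1)), 4)
  # no-bleach trace keeps every frame
  cfg2 <- trace_sim_config(n_molecules = 1, n_frames = 100, seed = 6,
                           folded_fraction = 1, donor_only_fraction = 0,
                           donor_bleach_mean_s = Inf,
                           acceptor_bleach_mean_s = Inf)
  tr2 <- simulate_trace(cfg2, class = "static_folded", seed = 9)
  ft2 <- detect_bleach_and_truncate(
    compute_fret(tr2, cfg2$background_mean, cfg2$background_mean),
    tr2, cfg2$background_mean, cfg2$channel_noise_sd)
  expect_equal(ft2$valid_frames, 100L)
  # an all-dark trace truncates to zero frames
  dark <- fake_trace(rnorm(50, 50, 30), rnorm(50, 50, 30))
  ftd <- detect_bleach_and_truncate(compute_fret(dark, 50, 50), dark, 50, 30)
  expect_equal(ftd$valid_frames, 0L)
})

test_that("histograms bin the first frames of each molecule", {
  cfg <- noiseless_config(n_molecules = 2, folded_fraction = 1, n_frames = 30)
  tr <- simulate_trace(cfg, seed = 1)
  ft <- compute_fret(tr, 0, 0)
  h <- build_histogram(list(ft), frames_per_molecule = 10)
  expect_equal(sum(h$counts), 10L)
  expect_equal(h$n_molecules, 1L)
  bin_of <- findInterval(0.8, h$bin_edges)
  expect_equal(h$counts[bin_of], 10L)
  # 50/50 noiseless mixture: two bins with equal counts
  cfg0 <- noiseless_config(n_molecules = 1, folded_fraction = 0, n_frames = 30)
  ft0 <- compute_fret(simulate_trace(cfg0, seed = 2), 0, 0)
  h2 <- build_histogram(list(ft, ft0), frames_per_molecule = 10)
  expect_equal(sum(h2$counts > 0), 2L)
  expect_equal(unname(h2$counts[h2$counts > 0]), c(10L, 10L))
  expect_error(build_histogram(list()), "no traces")
})

test_that("exact two-Gaussian curves are decomposed to optimizer tolerance", {
  edges <- seq(-0.1, 1.1, length.out = 61)
  x <- (edges[-1] + edges[-61]) / 2
  curve <- 700 * exp(-(x - 0.3)^2 / (2 * 0.07^2)) +
    300 * exp(-(x - 0.8)^2 / (2 * 0.07^2))
  h <- structure(list(bin_edges = edges, bin_centers = x,
                      counts = curve, n_molecules = 100L, n_frames = 1000L,
                      n_fields = 1L),
                 class = "fret_histogram")
  res <- fit_folded_fraction(h)
  expect_equal(res$fit$model, "two_component")
  # equal widths: area ratio equals amplitude ratio 300/1000
  expect_equal(res$folded_percent, 30, tolerance = 0.1)
  expect_equal(res$fit$mean_low, 0.3, tolerance = 1e-3)
  expect_equal(res$fit$mean_high, 0.8, tolerance = 1e-3)
  expect_lt(abs(res$fit$area_high / (res$fit$area_low + res$fit$area_high) -
                0.3), 1e-3)
})

test_that("pure low-FRET data select the single component at zero percent", {
  cfg <- trace_sim_config(n_molecules = 400, folded_fraction = 0,
                          donor_only_fraction = 0, seed = 19)
  rep <- analyze_dataset(simulate_dataset(cfg))
  expect_equal(rep$folded$fit$model, "single_component")
  expect_equal(rep$folded$folded_percent, 0)
  expect_lt(rep$folded$fit$mean_low, 0.55)
})

test_that("folded fraction is recovered and responds monotonically", {
  rec <- vapply(c(0.2, 0.5, 0.8), function(f) {
    cfg <- trace_sim_config(n_molecules = 600, folded_fraction = f,
                            seed = 101)
    analyze_dataset(simulate_dataset(cfg))$folded$folded_percent
  }, numeric(1))
  expect_lt(abs(rec[1] - 20), 6)
  expect_lt(abs(rec[2] - 50), 6)
  expect_lt(abs(rec[3] - 80), 6)
  expect_true(all(diff(rec) > 0))
})

test_that("dynamic traces are detected against the generating state path", {
  cfg <- trace_sim_config(n_molecules = 1, n_frames = 600, k_unfold = 0.5,
                          k_fold = 0.5, dynamic_fraction = 1,
                          donor_only_fraction = 0,
                          donor_bleach_mean_s = Inf,
                          acceptor_bleach_mean_s = Inf, seed = 77)
  set.seed(77)
  found <- 0L
  for (i in 1:10) {
    tr <- simulate_trace(cfg, class = "dynamic")
    ft <- compute_fret(tr, cfg$background_mean, cfg$background_mean)
    ft <- detect_bleach_and_truncate(ft, tr, cfg$background_mean,
                                     cfg$channel_noise_sd)
    res <- classify_dynamic(ft)
    truth_trans <- length(rle(tr$truth$state_path)$values) - 1L
    if (truth_trans >= 4) {
      found <- found + 1L
      expect_true(res$is_dynamic)
      # committed transitions never exceed the true number
      expect_lte(res$n_transitions, truth_trans)
    }
  }
  expect_gt(found, 5L)
})

test_that("static traces are not called dynamic and short traces are excluded", {
  cfg <- trace_sim_config(n_molecules = 1, n_frames = 600, seed = 13,
                          folded_fraction = 1, donor_only_fraction = 0,
                          donor_bleach_mean_s = Inf,
                          acceptor_bleach_mean_s = Inf)
  tr <- simulate_trace(cfg, class = "static_folded", seed = 13)
  ft <- compute_fret(tr, cfg$background_mean, cfg$background_mean)
  ft <- detect_bleach_and_truncate(ft, tr, cfg$background_mean,
                                   cfg$channel_noise_sd)
  res <- classify_dynamic(ft)
  expect_false(res$is_dynamic)
  expect_equal(res$n_transitions, 0L)
  ft$valid_frames <- 10L
  expect_true(classify_dynamic(ft)$excluded)
})

test_that("analyze_dataset is deterministic and reports consistent counts", {
  cfg <- trace_sim_config(n_molecules = 200, seed = 3,
                          folded_fraction = 0.66)
  d <- simulate_dataset(cfg)
  r1 <- analyze_dataset(d)
  r2 <- analyze_dataset(d)
  expect_identical(r1, r2)
  expect_equal(r1$qc$n_dual_labeled + r1$qc$n_donor_only_removed, 200L)
  expect_equal(r1$dynamics$n_evaluated + r1$dynamics$n_excluded,
               r1$qc$n_dual_labeled)
  expect_true(r1$folded$folded_percent >= 0 &&
                r1$folded$folded_percent <= 100)
})
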