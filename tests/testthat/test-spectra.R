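gauss_spec <- function(center, amp, sd = 10, ligand = "NMM", id = "s") {
  wl <- 550:750
  emission_spectrum(wl, amp * exp(-(wl - center)^2 / (2 * sd^2)),
                    ligand = ligand, sample_id = id)
}

test_that("peak_intensity reads constructed peaks and handles edge cases", {
  s <- gauss_spec(610, 100, sd = 12)
  expect_equal(peak_intensity(s, 610), 100, tolerance = 0.01)
  z <- emission_spectrum(550:750, rep(0, 201), ligand = "NMM")
  expect_equal(peak_intensity(z, 640), 0)
  expect_error(peak_intensity(s, 200), "coverage")
  expect_error(peak_intensity(s, 749.5), "coverage")
})

test_that("peak_intensity window mean matches the closed-form ramp integral", {
  # linear ramp sampled every 5 nm: interpolant is the ramp itself, so the
  # window mean over [610, 614] equals the midpoint value f(612)
  wl <- seq(550, 750, by = 5)
  ramp <- emission_spectrum(wl, 2 * wl, ligand = "none")
  expect_equal(peak_intensity(ramp, 612), 2 * 612, tolerance = 1e-12)
  # half_window 0 returns the interpolated point value
  expect_equal(peak_intensity(ramp, 612, half_window = 0), 1224)
})

test_that("background subtraction is pointwise, floored and grid-aware", {
  s <- gauss_spec(610, 100)
  expect_equal(subtract_background(s, s)$intensity, rep(0, 201))
  ctrl <- emission_spectrum(550:750, rep(10, 201), ligand = "NMM")
  d <- subtract_background(s, ctrl)
  expect_equal(peak_intensity(d, 610), 90, tolerance = 0.05)
  expect_true(all(d$intensity >= 0))
  # control on a shifted/coarser grid: equals manual linear interpolation
  wl_c <- seq(549, 751, by = 2)
  ctrl2 <- emission_spectrum(wl_c, 0.5 * wl_c, ligand = "NMM")
  d2 <- subtract_background(s, ctrl2)
  manual <- pmax(s$intensity - approx(wl_c, 0.5 * wl_c,
                                      xout = s$wavelength_nm)$y, 0)
  expect_equal(d2$intensity, manual)
  # but the control must cover the sample range
  short <- emission_spectrum(600:700, rep(1, 101), ligand = "NMM")
  expect_error(subtract_background(s, short), "cover")
  cv <- gauss_spec(640, 50, ligand = "CV")
  expect_error(subtract_background(s, cv), "ligand")
})

test_that("normalization sets the reference to 100 and preserves ratios", {
  spectra <- list(
    simulate_spectrum("NMM", 1.0, noise_sd = 0, sample_id = "ref"),
    simulate_spectrum("CV", 0.5, noise_sd = 0, sample_id = "ref"),
    simulate_spectrum("NMM", 0.5, noise_sd = 0, sample_id = "half"),
    simulate_spectrum("CV", 0.25, noise_sd = 0, sample_id = "half"))
  ro <- normalize_to_reference(ligand_readouts(spectra), "ref")
  expect_equal(ro$nmm_percent[ro$sample_id == "ref"], 100)
  expect_equal(ro$cv_percent[ro$sample_id == "ref"], 100)
  expect_equal(ro$nmm_percent[ro$sample_id == "half"], 50, tolerance = 1e-6)
  expect_equal(ro$cv_percent[ro$sample_id == "half"], 50, tolerance = 1e-6)
  # idempotence: renormalizing a normalized table changes nothing
  expect_equal(normalize_to_reference(ro, "ref"), ro)
  # rank preservation against raw intensities
  expect_equal(order(ro$nmm_percent), order(ro$nmm_610))
  # zero reference is an error
  spectra0 <- list(
    simulate_spectrum("NMM", 0, noise_sd = 0, sample_id = "z"),
    simulate_spectrum("CV", 0, noise_sd = 0, sample_id = "z"))
  expect_error(normalize_to_reference(ligand_readouts(spectra0), "z"),
               "zero or missing")
  expect_error(normalize_to_reference(ro, "nope"), "not found")
})

test_that("centroid fitting averages labeled points per class", {
  pts <- data.frame(
    nmm_percent = c(90, 110, 10, 20, 2, 6),
    cv_percent = c(5, 9, 70, 90, 3, 5),
    class = rep(c("parallel", "antiparallel", "unfolded"), each = 2))
  m <- fit_centroids(pts)
  expect_equal(unname(m$centroids["parallel", ]), c(100, 7))
  expect_equal(unname(m$centroids["antiparallel", ]), c(15, 80))
  expect_equal(unname(m$centroids["unfolded", ]), c(4, 4))
  # duplicating the data leaves centroids unchanged
  m2 <- fit_centroids(rbind(pts, pts))
  expect_equal(m2$centroids, m$centroids)
  expect_error(fit_centroids(pts[pts$class != "unfolded", ]), "lacks")
})

test_that("nearest-centroid classification respects ties and metric", {
  pts <- data.frame(nmm_percent = c(100, 0, 0),
                    cv_percent = c(0, 100, 0),
                    class = c("parallel", "antiparallel", "unfolded"))
  m <- fit_centroids(pts, metric = "euclidean")
  expect_equal(classify_point(c(100, 0), m)$class, "parallel")
  # equidistant from parallel and antiparallel: fixed order prefers parallel
  expect_equal(classify_point(c(50, 50), m)$class, "parallel")
  res <- classify_point(c(0, 0), m)
  expect_equal(res$class, "unfolded")
  expect_named(res$distances, c("parallel", "antiparallel", "unfolded"))
})

test_that("standardized classification is invariant to common rescaling", {
  set.seed(3)
  pts <- data.frame(
    nmm_percent = c(rnorm(10, 100, 5), rnorm(10, 15, 5), rnorm(10, 5, 2)),
    cv_percent = c(rnorm(10, 8, 3), rnorm(10, 80, 6), rnorm(10, 5, 2)),
    class = rep(c("parallel", "antiparallel", "unfolded"), each = 10))
  m <- fit_centroids(pts)
  query <- cbind(runif(20, 0, 120), runif(20, 0, 100))
  base <- apply(query, 1, function(p) classify_point(p, m)$class)
  for (scale in c(0.2, 3.7)) {
    pts2 <- pts
    pts2$nmm_percent <- pts2$nmm_percent * scale
    pts2$cv_percent <- pts2$cv_percent * scale
    m2 <- fit_centroids(pts2)
    rescaled <- apply(query * scale, 1,
                      function(p) classify_point(p, m2)$class)
    expect_equal(rescaled, base)
  }
})

test_that("three-blob simulation is classified in full agreement with truth", {
  set.seed(11)
  n <- 100
  blob <- function(mx, my, sx, sy, cls)
    data.frame(nmm_percent = rnorm(n, mx, sx), cv_percent = rnorm(n, my, sy),
               class = cls)
  pts <- rbind(blob(100, 8, 6, 3, "parallel"),
               blob(15, 80, 5, 6, "antiparallel"),
               blob(5, 5, 2, 2, "unfolded"))
  model <- fit_centroids(pts)
  # centroids land within sampling error of the generating means
  expect_equal(unname(model$centroids["parallel", ]), c(100, 8),
               tolerance = 0.05)
  got <- classify_points(pts, model)$class
  expect_equal(got, pts$class)
})

test_that("pearson_correlation matches hand-computed values and properties", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  # by hand: centered cross products 4, variances 5 each -> r = 4/5
  expect_equal(pearson_correlation(x, y), 0.8)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, y), pearson_correlation(y, x))
  # affine invariance with positive slope
  expect_equal(pearson_correlation(3 * x + 2, y), 0.8)
  expect_error(pearson_correlation(x, c(1, 1, 1, 1)), "zero variance")
  expect_error(pearson_correlation(x, y[1:3]), "equal length")
  expect_error(pearson_correlation(x[1:2], y[1:2]), "at least 3")
})
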