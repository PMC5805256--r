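fake_tooth <- function(A, B, tooth_area, triangle_area,
                       L_teeth = 1, L2m = 10) structure(
  list(peak_index = 2, left_valley_index = 1, right_valley_index = 3,
       A = A, B = B, tooth_area = tooth_area, triangle_area = triangle_area,
       L_teeth = L_teeth, L_teeth2midrib = L2m), class = "tooth_measurement")

test_that("teeth detection is empty on smooth outlines and monotone in threshold", {
  m <- disc_mask(301, 151, 151, 130)
  sig <- ccd_ebp(trace_boundary(m), incircle_centroid(m))
  cons <- consolidate_extrema(sig)
  tt <- detect_teeth(sig, cons)
  expect_length(tt$teeth_peaks, 0)

  an <- cached_analysis("serrate", leaf_spec(teeth_count = 40,
          teeth_waveform = "saw", teeth_amplitude = 0.085, elongation = 1.45,
          apex_type = "acuminate", base_type = "rounded", vein_stripe = TRUE))
  n1 <- length(detect_teeth(an$signature, an$consolidated, small_threshold = 1)$teeth_peaks)
  n2 <- length(detect_teeth(an$signature, an$consolidated, small_threshold = 2)$teeth_peaks)
  n4 <- length(detect_teeth(an$signature, an$consolidated, small_threshold = 4)$teeth_peaks)
  expect_gte(n1, n2)
  expect_gte(n2, n4)
})

test_that("teeth on a lobed margin exclude the lobe tips", {
  spec <- leaf_spec(n_lobes = 5, lobe_amplitude = 0.1, teeth_count = 40,
                    teeth_waveform = "triangular", teeth_amplitude = 0.08,
                    elongation = 1.05, apex_type = "rounded", base_type = "rounded")
  leaf <- generate_leaf(spec)
  bin <- binarize(leaf$image)
  ct <- trace_boundary(bin); cen <- incircle_centroid(bin)
  sig <- ccd_ebp(ct, cen); cons <- consolidate_extrema(sig)
  tt <- detect_teeth(sig, cons)
  # the tooth riding each lobe tip merges with the large-threshold peak and
  # is excluded by the set difference, leaving teeth_count - n_lobes
  expect_equal(length(tt$teeth_peaks), 35, tolerance = 2 / 35)
})

test_that("ripples ratio matches the XOR pixel oracle and flags toothed margins", {
  disc <- disc_mask(301, 151, 151, 120)
  rr <- ripples_ratio(disc, smoothing_radius = 12)
  expect_lt(as.numeric(rr), 0.01)
  sm <- attr(rr, "smoothed")
  expect_identical(as.numeric(rr), sum(xor(disc, sm)) / sum(disc))

  an <- cached_analysis("serrate", leaf_spec(teeth_count = 40,
          teeth_waveform = "saw", teeth_amplitude = 0.085, elongation = 1.45,
          apex_type = "acuminate", base_type = "rounded", vein_stripe = TRUE))
  rr_t <- ripples_ratio(an$bin, an$centroid$incircle_radius / 8)
  expect_gt(as.numeric(rr_t), 0.01)

  expect_error(ripples_ratio(matrix(FALSE, 10, 10)), "empty mask")
})

test_that("ripples ratio is approximately scale covariant", {
  small <- disc_mask(201, 101, 101, 70) |
    (disc_mask(201, 101, 31, 8))        # disc with one bump
  big <- disc_mask(401, 201, 201, 140) |
    (disc_mask(401, 201, 61, 16))
  r1 <- as.numeric(ripples_ratio(small, smoothing_radius = 10))
  r2 <- as.numeric(ripples_ratio(big, smoothing_radius = 20))
  expect_equal(r1, r2, tolerance = 0.2)
})

test_that("tooth measurement recovers analytic flank and area geometry", {
  # isoceles triangular tooth on a straight baseline
  seg <- rbind(c(0, 0), c(5, -12), c(10, 0))
  base <- cbind(seq(10, 40, by = 1), 0)
  ct <- fake_contour(rbind(seg, base))
  tm <- measure_tooth(ct, peak = 2, left_valley = 1, right_valley = 3,
                      midrib_axis = list(p0 = c(0, 20), p1 = c(100, 20)))
  expect_identical(tm$A, tm$B)
  expect_equal(tm$L_teeth, 12)
  expect_equal(tm$triangle_area, 60)
  expect_equal(tm$L_teeth2midrib, 20)

  # right-leaning saw tooth: peak displaced toward the right valley
  seg2 <- rbind(c(0, 0), c(8, -12), c(10, 0), base)
  tm2 <- measure_tooth(fake_contour(seg2), 2, 1, 3)
  expect_gt(tm2$A, tm2$B)

  # semicircular tooth: area ratio pi/2 on a dense rasterised arc
  th <- seq(pi, 0, length.out = 200)
  r <- 30
  arc <- cbind(50 + r * cos(th), -r * sin(th))
  ct3 <- fake_contour(rbind(arc, cbind(seq(81, 120), 0)))
  tm3 <- measure_tooth(ct3, peak = which.min(arc[, 2]), left_valley = 1,
                       right_valley = nrow(arc))
  expect_equal(tm3$tooth_area / tm3$triangle_area, pi / 2, tolerance = 0.1)

  expect_error(measure_tooth(fake_contour(cbind(1:40, 1:40)), 2, 1, 3),
               "degenerate tooth")
})

test_that("diminutive thresholds follow the 1/16 and 1/8 rules", {
  d1 <- diminutive_test(fake_tooth(1, 1, 1, 1, L_teeth = 1, L2m = 20))
  expect_equal(d1$ratio_dt, 0.05)
  expect_true(d1$diminutive); expect_false(d1$lobe_scale)

  d2 <- diminutive_test(fake_tooth(1, 1, 1, 1, L_teeth = 1, L2m = 10))
  expect_false(d2$diminutive); expect_false(d2$lobe_scale)

  d3 <- diminutive_test(fake_tooth(1, 1, 1, 1, L_teeth = 2, L2m = 10))
  expect_true(d3$lobe_scale)

  expect_error(diminutive_test(fake_tooth(1, 1, 1, 1, L2m = 0)), "positive")
})

test_that("tooth types split on flank equality then triangularity", {
  expect_identical(tooth_type(fake_tooth(1.8, 1, 1, 1)), "type1")
  expect_identical(tooth_type(fake_tooth(1, 1, 0.97, 1)), "type2")
  expect_identical(tooth_type(fake_tooth(1, 1, 1.5, 1)), "type3")
})

test_that("margin classes are recovered for representative margins", {
  m <- disc_mask(301, 151, 151, 130)
  sig <- ccd_ebp(trace_boundary(m), incircle_centroid(m))
  cons <- consolidate_extrema(sig)
  bin <- structure(list(mask = m, width = 301, height = 301, source_path = NULL),
                   class = "binary_leaf")
  mf <- classify_margin(bin, trace_boundary(m), sig, cons)
  expect_identical(mf$margin_class, "entire")

  an_s <- cached_analysis("serrate", leaf_spec(teeth_count = 40,
            teeth_waveform = "saw", teeth_amplitude = 0.085, elongation = 1.45,
            apex_type = "acuminate", base_type = "rounded", vein_stripe = TRUE))
  expect_identical(an_s$margin$margin_class, "serrate")
  expect_identical(an_s$margin$tooth_type, "type1")

  an_cl <- analyze_leaf(generate_leaf(leaf_spec(teeth_count = 56,
             teeth_waveform = "rounded", teeth_amplitude = 0.022,
             elongation = 1.4, apex_type = "acute", base_type = "rounded",
             vein_stripe = TRUE)))
  expect_identical(an_cl$margin$margin_class, "crenulate")
  expect_true(an_cl$margin$diminutive)
})

test_that("every reported tooth satisfies 0 < ratio_dt <= 1/8", {
  set.seed(23)
  for (i in 1:6) {
    spec <- leaf_spec(teeth_count = sample(c(36, 40, 56), 1),
                      teeth_waveform = sample(c("saw", "rounded", "triangular"), 1),
                      teeth_amplitude = runif(1, 0.03, 0.09),
                      elongation = runif(1, 1.2, 1.6),
                      apex_type = "rounded", base_type = "rounded",
                      rotation = runif(1, 0, 360), vein_stripe = TRUE)
    an <- analyze_leaf(generate_leaf(spec))
    for (tm in an$margin$per_tooth) {
      r <- tm$L_teeth / tm$L_teeth2midrib
      expect_gt(r, 0)
      expect_lte(r, 1 / 8)
    }
  }
})
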