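test_that("the signature is the per-point centroid distance", {
  m <- disc_mask(121, 61, 61, 40)
  ct <- trace_boundary(m)
  cen <- incircle_centroid(m)
  sig <- ccd_ebp(ct, cen, m)
  expect_equal(length(sig$dist), ct$n)
  expect_true(all(abs(sig$dist - 40) <= 1.5))
  # direct per-point re-evaluation
  ref <- sqrt((ct$points[, 1] - cen$cx)^2 + (ct$points[, 2] - cen$cy)^2)
  expect_identical(sig$dist, ref)

  # axis-aligned square: distances range from s (edge midpoints) to s*sqrt(2)
  sq <- matrix(FALSE, 101, 101); sq[21:81, 21:81] <- TRUE
  cts <- trace_boundary(sq); cens <- incircle_centroid(sq)
  sigs <- ccd_ebp(cts, cens)
  expect_equal(min(sigs$dist), 30, tolerance = 0.05)
  expect_equal(max(sigs$dist), 30 * sqrt(2), tolerance = 0.05)

  expect_error(ccd_ebp(ct, structure(list(cx = 1, cy = 1, incircle_radius = 1),
                                     class = "leaf_centroid"), m),
               "invalid centroid")
})

test_that("angle-sampled CCD picks one point per interval; CCD-EBP keeps all", {
  an <- cached_analysis("lobed", lobed_spec())
  cs <- ccd_sampled(an$contour, an$centroid, interval = 10)
  expect_length(cs$indices, 36)
  expect_length(unique(cs$indices), 36)
  expect_equal(length(an$signature$dist), an$contour$n)
})

test_that("delta-threshold extrema detection matches hand-checkable signals", {
  expect_equal(nrow(find_extrema(rep(7, 50), 2, cyclic = FALSE)$peaks), 0)
  expect_equal(nrow(find_extrema(rep(7, 50), 2, cyclic = FALSE)$valleys), 0)

  x <- 50 + 30 * sin(seq(0, 8 * pi, length.out = 400))
  ex <- find_extrema(x, 15, cyclic = FALSE)
  expect_equal(nrow(ex$peaks), 4)
  expect_equal(nrow(ex$valleys), 4)

  # small bump is threshold-dependent
  b <- c(rep(0, 20), seq(0, 10, length.out = 10), seq(10, 0, length.out = 10),
         rep(0, 20), 30, rep(0, 5))
  expect_equal(nrow(find_extrema(b, 15, cyclic = FALSE)$peaks), 1)  # only the 30 spike
  expect_equal(nrow(find_extrema(b, 5, cyclic = FALSE)$peaks), 2)   # bump reported too
})

test_that("find_extrema equals the exhaustive reference scan on random arrays", {
  set.seed(101)
  deltas <- c(0.5, 1, 2, 5, 10)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    x <- cumsum(stats::rnorm(n, sd = sample(c(0.5, 2, 5), 1)))
    for (d in deltas) {
      got <- find_extrema(x, d, cyclic = FALSE)
      ref <- oracle_extrema(x, d)
      expect_identical(as.integer(got$peaks[, "index"]), sort(ref$peaks),
                       info = sprintf("peaks rep=%d d=%g", rep, d))
      expect_identical(as.integer(got$valleys[, "index"]), sort(ref$valleys),
                       info = sprintf("valleys rep=%d d=%g", rep, d))
    }
  }
})

test_that("peaks and valleys strictly alternate on cyclic signatures", {
  set.seed(7)
  for (rep in 1:20) {
    spec <- leaf_spec(n_lobes = sample(3:8, 1), lobe_amplitude = runif(1, 0.12, 0.22),
                      elongation = runif(1, 1.05, 1.4),
                      apex_type = "rounded", base_type = "rounded",
                      rotation = runif(1, 0, 360))
    leaf <- generate_leaf(spec)
    bin <- binarize(leaf$image)
    sig <- ccd_ebp(trace_boundary(bin), incircle_centroid(bin))
    for (d in c(5, 15, 35)) {
      ex <- find_extrema(sig, d)
      np <- nrow(ex$peaks); nv <- nrow(ex$valleys)
      if (np == 0 || nv == 0) next
      expect_equal(np, nv)
      ev <- rbind(cbind(ex$peaks[, "index"], 1), cbind(ex$valleys[, "index"], 2))
      ev <- ev[order(ev[, 1]), , drop = FALSE]
      expect_true(all(diff(ev[, 2]) != 0))   # types alternate around the contour
    }
  }
})

test_that("threshold consolidation takes the first mode and its positions", {
  expect_equal(leafmorph:::mode_first(c(5, 5, 5, 5, 5)), 5)
  expect_equal(leafmorph:::mode_first(c(7, 5, 5, 4, 4)), 5)  # first-encounter tie-break
  expect_equal(leafmorph:::mode_first(c(3, 9, 9, 3)), 3)

  an <- cached_analysis("lobed", lobed_spec())
  cons <- an$consolidated
  expect_equal(cons$mod_peak, 5)
  expect_equal(cons$mod_valley, 5)
  expect_equal(length(cons$peak_positions), 5)
  counts <- count_lobes_sinuses(cons)
  expect_equal(counts$lobes, 5)
  expect_equal(counts$sinuses, 5)
})

test_that("a near-circular outline reports zero lobes", {
  m <- disc_mask(221, 111, 111, 100)
  sig <- ccd_ebp(trace_boundary(m), incircle_centroid(m))
  cons <- consolidate_extrema(sig)
  expect_equal(cons$mod_peak, 0)
  expect_equal(cons$mod_valley, 0)
})

test_that("lobe counts are invariant to rotation and scale", {
  base <- analyze_leaf(generate_leaf(lobed_spec(rotation = 0)))
  rot <- analyze_leaf(generate_leaf(lobed_spec(rotation = 37)))
  spec_sc <- lobed_spec(rotation = 37); spec_sc$scale <- 482 / 1.4
  sc <- analyze_leaf(generate_leaf(spec_sc))
  expect_equal(rot$counts$lobes, base$counts$lobes)
  expect_equal(sc$counts$lobes, base$counts$lobes)
  expect_equal(sc$counts$sinuses, base$counts$sinuses)
})
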