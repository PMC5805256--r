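test_that("vertex angles follow the law of cosines and conserve the full turn", {
  # 4 maxima at square corners about the centroid: four right angles
  pts <- rbind(c(10, 0), c(0, 10), c(-10, 0), c(0, -10)) + 50
  fan <- build_vertex_fan(1:4, fake_contour(pts), fake_centroid(50, 50))
  expect_equal(fan$angles, rep(90, 4), tolerance = 1e-9)

  # equilateral triangle: three 120-degree angles
  a <- c(90, 210, 330) * pi / 180
  tri <- cbind(50 + 20 * cos(a), 50 - 20 * sin(a))
  fan3 <- build_vertex_fan(1:3, fake_contour(tri), fake_centroid(50, 50))
  expect_equal(fan3$angles, rep(120, 3), tolerance = 1e-9)

  expect_error(build_vertex_fan(1, fake_contour(pts), fake_centroid(50, 50)),
               "insufficient maxima")

  # on a real lobed leaf the angles sum to a full turn
  an <- cached_analysis("lobed", lobed_spec())
  fan5 <- build_vertex_fan(an$consolidated$peak_positions, an$contour, an$centroid)
  expect_equal(sum(fan5$angles), 360, tolerance = 0.5)
})

test_that("north/south split and median pole selection follow the region rule", {
  # five maxima; the wrap vertex (k5-k1) spans the apex with the large angle
  a <- c(90, 162, 234, 306, 18)  # degrees, contour (clockwise) order
  gaps <- c(72, 72, 72, 72, 72)
  # construct so vertex angles are c(40,40,40,40,200)-like: squeeze k1..k5
  ang <- c(0, 40, 80, 120, 160) * pi / 180
  pts <- cbind(100 + 30 * cos(ang), 100 - 30 * sin(ang))
  fan <- build_vertex_fan(1:5, fake_contour(pts), fake_centroid(100, 100))
  expect_equal(fan$angles, c(40, 40, 40, 40, 160), tolerance = 1e-6)
  fan <- split_north_south(fan)
  expect_identical(fan$region_labels, c(rep("south", 4), "north"))
  expect_identical(which(fan$north_members), c(1L, 5L))       # flanking maxima
  expect_identical(which(fan$south_members), c(2L, 3L, 4L))   # after subtraction
  poles <- select_poles(fan)
  expect_identical(sort(poles$NP), c(1L, 5L))  # even membership: two middle points
  expect_identical(poles$SP, 3L)               # odd membership: single median

  # all-equal angles are degenerate
  sq <- rbind(c(10, 0), c(0, 10), c(-10, 0), c(0, -10)) + 50
  fsq <- build_vertex_fan(1:4, fake_contour(sq), fake_centroid(50, 50))
  expect_error(split_north_south(fsq), "degenerate fan")
})

test_that("pole regions span the flanking minima or fall back to a fixed fraction", {
  n <- 400
  ct <- fake_contour(cbind(seq_len(n), seq_len(n)))
  reg <- extract_pole_regions(ct, NP = 140, SP = 340,
                              minima = c(100, 180, 300, 380))
  expect_identical(reg$part_np, 100:180)
  expect_identical(reg$part_sp, 300:380)
  expect_equal(reg$np_point, 140)

  # no minima: fixed fraction of the contour centred on the pole
  reg2 <- extract_pole_regions(ct, NP = 140, SP = 340, minima = integer(0),
                               frac = 1 / 8)
  expect_equal(length(reg2$part_np), 2 * floor(n / 16) + 1)
  expect_true(140 %in% reg2$part_np)
})

test_that("pole regions never overlap across random synthetic leaves", {
  set.seed(31)
  for (i in 1:25) {
    spec <- leaf_spec(n_lobes = sample(c(0, 3, 5, 7), 1),
                      elongation = runif(1, 1.1, 1.8),
                      apex_type = sample(c("acute", "rounded", "acuminate"), 1),
                      base_type = sample(c("cuneate", "rounded"), 1),
                      rotation = runif(1, 0, 360), vein_stripe = TRUE)
    an <- analyze_leaf(generate_leaf(spec))
    expect_length(intersect(an$poles$part_np, an$poles$part_sp), 0)
  }
})

test_that("mid-vein width separates base from apex and drives alignment", {
  leaf <- generate_leaf(leaf_spec(apex_type = "acute", base_type = "rounded",
                                  vein_stripe = TRUE, rotation = 113))
  an <- analyze_leaf(leaf)
  w <- an$poles$vein_widths
  expect_true(all(is.finite(w)))
  ap <- an$contour$points[an$poles$apex_point, ]
  expect_lt(sqrt(sum((ap - leaf$truth$apex_point)^2)), 40)

  # a grayscale leaf with no vein ridge is undetectable
  flat <- generate_leaf(leaf_spec(apex_type = "acute", base_type = "rounded"))
  bin <- binarize(flat$image)
  cen <- incircle_centroid(bin)
  expect_error(
    measure_midvein_width(flat$image, bin$mask,
                          c(cen$cx, cen$cy), c(0, 1), round(cen$incircle_radius)),
    "vein undetectable")
})

test_that("apex/base assignment is orientation invariant", {
  set.seed(17)
  rots <- runif(8, 0, 360)
  pts <- lapply(rots, function(r) {
    leaf <- generate_leaf(leaf_spec(apex_type = "acuminate", base_type = "rounded",
                                    elongation = 1.5, vein_stripe = TRUE,
                                    rotation = r))
    an <- analyze_leaf(leaf)
    sqrt(sum((an$contour$points[an$poles$apex_point, ] - leaf$truth$apex_point)^2))
  })
  expect_true(mean(unlist(pts) < 40) >= 0.95)
})

test_that("CCG samples one point per interval angle with analytic gradients", {
  # right half of a circle about the region centroid
  th <- seq(0, pi, length.out = 361)   # semicircle, tip at the top
  r <- 80
  pts <- cbind(200 + r * cos(rev(th)), 200 - r * sin(rev(th)))
  cg <- ccg(pts, tip_xy = c(200, 200 - r), theta = 15)
  expect_identical(cg$angles, seq(0, 90, by = 15))
  expect_equal(nrow(cg$points), 7)
  expect_length(cg$gradients, 6)
  aa <- seq(0, 90, by = 15) * pi / 180
  ref <- abs(diff(sin(aa)) / diff(cos(aa)))
  expect_equal(cg$gradients, ref, tolerance = 0.05)

  # mirror symmetry: the left side gives the same gradients with mirrored order
  pts_m <- cbind(400 - pts[, 1], pts[, 2])
  cg_m <- ccg(pts_m[nrow(pts_m):1, ], tip_xy = c(200, 200 - r), theta = 15)
  expect_equal(cg_m$gradients, ref, tolerance = 0.05)

  # a ray with no nearby boundary point is reported
  expect_error(ccg(pts[1:60, ], tip_xy = c(200, 200 - r), theta = 15),
               "incomplete CCG")
})

test_that("apex types are recovered from flank angle and curvature", {
  an_ac <- analyze_leaf(generate_leaf(leaf_spec(apex_type = "acuminate",
                         base_type = "rounded", vein_stripe = TRUE)))
  expect_identical(an_ac$apex$label, "acuminate")
  expect_lt(an_ac$apex$apex_angle, 45)

  an_a <- analyze_leaf(generate_leaf(leaf_spec(apex_type = "acute",
                        apex_flank_angle = 70, base_type = "rounded",
                        vein_stripe = TRUE)))
  expect_identical(an_a$apex$label, "acute")
  expect_true(an_a$apex$apex_angle >= 45 && an_a$apex$apex_angle <= 90)

  an_r <- analyze_leaf(generate_leaf(leaf_spec(apex_type = "rounded",
                        base_type = "cuneate", elongation = 1.4,
                        vein_stripe = TRUE)))
  expect_identical(an_r$apex$label, "rounded")
})

test_that("base types are recovered, including the cordate notch", {
  an_c <- analyze_leaf(generate_leaf(leaf_spec(base_type = "cordate",
                        apex_type = "rounded", elongation = 1.3,
                        vein_stripe = TRUE)))
  expect_identical(an_c$base$label, "cordate")
  expect_gt(an_c$base$notch_depth, 6)

  an_k <- analyze_leaf(generate_leaf(leaf_spec(base_type = "cuneate",
                        apex_type = "acute", vein_stripe = TRUE)))
  expect_identical(an_k$base$label, "cuneate")

  an_r <- analyze_leaf(generate_leaf(leaf_spec(base_type = "rounded",
                        apex_type = "acute", elongation = 1.4,
                        vein_stripe = TRUE)))
  expect_identical(an_r$base$label, "rounded")
})
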