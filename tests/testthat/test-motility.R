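test_that("push-pull protrusion sites are uniform over the front half", {
  ct <- circle_contour(80, 0.5, c(0.25, 0))
  elig <- front_half_nodes(ct)
  # all eligible nodes lie right of the centroid (outward normal has +x)
  ctr <- contour_centroid(ct)
  expect_true(all(ct$x[elig, 1] > ctr[1]))
  set.seed(42)
  draws <- replicate(10000, place_protrusion_m1(ct))
  expect_true(all(draws %in% elig))
  tab <- table(factor(draws, levels = elig))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("protrusion choice is reproducible under a fixed seed", {
  ct <- circle_contour(80, 0.5)
  set.seed(7); a <- replicate(20, place_protrusion_m1(ct))
  set.seed(7); b <- replicate(20, place_protrusion_m1(ct))
  expect_identical(a, b)
})

test_that("rear-squeezing protrusion pairs are 15-45 degrees apart on the front", {
  ct <- circle_contour(120, 0.5, c(0.25, 0))
  ctr <- contour_centroid(ct)
  th <- atan2(ct$x[, 2] - ctr[2], ct$x[, 1] - ctr[1])
  set.seed(9)
  for (i in 1:300) {
    ms <- place_protrusions_m2(ct)
    expect_true(ms[1] != ms[2])
    dth <- abs(atan2(sin(th[ms[1]] - th[ms[2]]), cos(th[ms[1]] - th[ms[2]])))
    sep <- dth * 180 / pi
    expect_gte(sep, 15 - 2)   # node rounding: 360/120 = 3 deg resolution
    expect_lte(sep, 45 + 2)
    # index offset spans 5..15 nodes at 3 degrees per node
    idx <- min((ms[2] - ms[1]) %% 120, (ms[1] - ms[2]) %% 120)
    expect_gte(idx, 4); expect_lte(idx, 16)
  }
})

test_that("contact detection returns the nearest node inside the threshold", {
  lat <- list(x = rbind(c(0, 0), c(0.5, 0), c(0.05, 0.001)))
  eps <- 0.02
  expect_true(is.na(detect_contact(c(0.2, 0.2), lat, 2 * eps)))   # all at 3 eps+
  expect_equal(detect_contact(c(-0.038, 0), lat, 2 * eps), 1)     # 1.9 eps
  # two nodes inside the threshold: the nearer one wins
  expect_equal(detect_contact(c(0.03, 0), lat, 2 * eps), 3)       # node 3 closer
  expect_equal(detect_contact(c(0.01, 0), lat, 2 * eps), 1)
  # exact tie broken by lower id
  lat2 <- list(x = rbind(c(0.01, 0), c(-0.01, 0)))
  expect_equal(detect_contact(c(0, 0), lat2, 2 * eps), 1)
  # excluded nodes are invisible: the other (in-range) node is returned
  expect_equal(detect_contact(c(0.01, 0), lat2, 2 * eps, exclude = 1L), 2)
  expect_error(detect_contact(c(0, 0), lat, 0), "positive")
})

test_that("equilibrium check is a monotone threshold on the maximum speed", {
  expect_true(check_equilibrium(rep(0, 5), 0.02))
  expect_false(check_equilibrium(c(0.001, 0.022), 0.02))
  u <- matrix(c(0.01, 0, 0, 0.015), 2, 2)
  expect_true(check_equilibrium(u, 0.02))
  # monotone: passing at t1 implies passing at any larger threshold
  sp <- runif(10, 0, 0.05)
  t1 <- 0.03
  if (check_equilibrium(sp, t1)) expect_true(check_equilibrium(sp, 0.1))
})

test_that("cortex arcs split at the tips with the rear strictly longer", {
  ct <- circle_contour(120, 0.5)
  arcs <- cortex_arcs(ct, 10, 25)
  expect_gt(length(arcs$rear), length(arcs$front))
  expect_equal(sort(c(arcs$rear, arcs$front, 10, 25)), 1:120)
  expect_true(all(arcs$front == 11:24))
  # wrap-around tips
  arcs2 <- cortex_arcs(ct, 115, 8)
  expect_true(all(c(116:120, 1:7) %in% arcs2$front))
  expect_error(cortex_arcs(ct, 5, 5), "distinct")
})

test_that("nucleus bending rigidity is gated by phase in computational mode", {
  expect_equal(nucleus_bending_rigidity("computational", 0.05, "PROTRUDING"), 0.05)
  expect_equal(nucleus_bending_rigidity("computational", 0.05, "BOUND_CONTRACTING"), 0)
  expect_equal(nucleus_bending_rigidity("computational", 0.05, "EQUILIBRATING"), 0)
  for (ph in c("RELAXED", "PROTRUDING", "BOUND_CONTRACTING"))
    expect_equal(nucleus_bending_rigidity("physical", 0.05, ph), 0.05)
  expect_equal(nucleus_bending_rigidity("none", 0.05, "PROTRUDING"), 0)
})
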