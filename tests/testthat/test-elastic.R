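test_that("tension follows k (|tau| - r) on circles", {
  # resting circle: |tau| = 1, r = 1 -> zero tension
  ct <- circle_contour(40, radius = 0.5)
  expect_equal(tension(ct), rep(0, 40))
  # uniformly inflated to twice the rest radius: |tau| = 2 -> tension 1
  infl <- contour(2 * ct$x, ct$ref, k = 1, r = 1)
  expect_equal(tension(infl), rep(1, 40))
  # active rear tension: rest length 0.1 on a resting circle -> 0.9
  act <- contour(ct$x, ct$ref, k = 1, r = 0.1)
  expect_equal(tension(act), rep(0.9, 40))
})

test_that("tension rejects degenerate geometry", {
  x <- circle_contour(10)$x
  x[2, ] <- x[1, ]
  expect_error(tension(contour(x, circle_contour(10)$x)), "degenerate")
})

test_that("elastic force density matches the closed form on scaled circles", {
  # rest radius 0.5 inflated to radius 1: inward force density of
  # magnitude T * rho / R0^2 = 4, no tangential component
  for (n in c(40, 80, 160)) {
    ct <- circle_contour(n, radius = 0.5)
    infl <- contour(2 * ct$x, ct$ref)
    Fd <- elastic_force_density(infl)
    ctr <- contour_centroid(infl)
    rad <- t(apply(infl$x, 1, function(p) (p - ctr) / sqrt(sum((p - ctr)^2))))
    radial <- rowSums(Fd * rad)
    tangential <- Fd - radial * rad
    expect_equal(radial, rep(-4, n), tolerance = 1e-8)
    expect_lt(max(abs(tangential)), 1e-10)
  }
})

test_that("elastic force density telescopes to zero total force", {
  set.seed(11)
  th <- sort(runif(30, 0, 2 * pi))
  x <- cbind(cos(th) * (1 + 0.3 * sin(3 * th)), sin(th))
  ct <- contour(x, circle_contour(30, 0.5)$x, k = runif(30, 0.5, 2),
                r = runif(30, 0.5, 1))
  Fd <- elastic_force_density(ct)
  ds <- stokescell:::node_ref_spacing(ct$ref)
  expect_lt(max(abs(colSums(Fd * ds))), 1e-12)
})

test_that("protrusion force density has the three-level structure and zero sum", {
  ct <- circle_contour(80, 0.5)
  p <- protrusion(10, f0 = 1, normal = c(1, 0))
  Fd <- protrusion_force_density(ct, p)
  expect_equal(Fd[10, ], c(1, 0))
  expect_equal(Fd[9, ], c(0.5, 0))
  expect_equal(Fd[11, ], c(0.5, 0))
  others <- setdiff(1:80, 9:11)
  expect_true(all(abs(Fd[others, 1] + 2 / 77) < 1e-15))
  expect_equal(colSums(Fd), c(0, 0), tolerance = 1e-13)
  # all vectors parallel to the fixed normal
  expect_true(all(Fd[, 2] == 0))
  # zero net force for any N and f0
  for (n in c(5, 17, 120)) {
    pf <- protrusion_force_density(circle_contour(n), protrusion(3, 7.5, c(0, 1)))
    expect_equal(colSums(pf), c(0, 0), tolerance = 1e-12)
  }
  expect_error(protrusion_force_density(circle_contour(4), p), "at least 5")
})

test_that("wrap-around indexing keeps the protrusion neighbourhood intact", {
  ct <- circle_contour(12)
  Fd <- protrusion_force_density(ct, protrusion(1, 2, c(1, 0)))
  expect_equal(Fd[12, 1], 1)   # neighbour across the seam
  expect_equal(Fd[2, 1], 1)
})

test_that("bending force vanishes at the preferred circle and for Kb = 0", {
  ct <- circle_contour(40, radius = 0.5, Kb = 0.05)
  expect_equal(bending_force_density(ct), matrix(0, 40, 2), tolerance = 1e-12)
  # rigid motions of the preferred circle are also force-free
  rot <- cbind(ct$x[, 1] * cos(0.3) - ct$x[, 2] * sin(0.3) + 1,
               ct$x[, 1] * sin(0.3) + ct$x[, 2] * cos(0.3) - 2)
  expect_equal(bending_force_density(contour(rot, ct$ref, Kb = 0.05)),
               matrix(0, 40, 2), tolerance = 1e-10)
  expect_equal(bending_force_density(contour(2 * ct$x, ct$ref, Kb = 0)),
               matrix(0, 40, 2))
})

test_that("bending force is minus the gradient of the curvature energy", {
  # finite-difference oracle on the discrete energy
  n <- 24
  ct <- circle_contour(n, radius = 0.5, Kb = 0.03)
  set.seed(3)
  x <- ct$x + 0.02 * matrix(rnorm(2 * n), n, 2)
  pert <- contour(x, ct$ref, Kb = 0.03)
  energy <- function(xm) {
    ip1 <- c(2:n, 1); im1 <- c(n, 1:(n - 1))
    L <- sum(stokescell:::seg_ref_spacing(ct$ref))
    ds <- L / n
    D2r <- (ct$ref[ip1, ] - 2 * ct$ref + ct$ref[im1, ]) / ds^2
    c0 <- sqrt(rowSums(D2r^2))            # preferred curvature of the
    D2 <- (xm[ip1, ] - 2 * xm + xm[im1, ]) / ds^2   # reference circle
    cm <- sqrt(rowSums(D2^2))
    0.03 / 2 * sum((cm - c0)^2) * ds
  }
  Fd <- bending_force_density(pert)
  h <- 1e-7
  L <- sum(stokescell:::seg_ref_spacing(ct$ref)); ds <- L / n
  for (j in c(1, 7, 15)) {
    for (d in 1:2) {
      xp <- x; xp[j, d] <- xp[j, d] + h
      xm <- x; xm[j, d] <- xm[j, d] - h
      grad <- (energy(xp) - energy(xm)) / (2 * h)
      expect_equal(Fd[j, d], -grad / ds, tolerance = 1e-4)
    }
  }
})

test_that("radial perturbation of a circle is opposed by a force linear in Kb", {
  n <- 40
  base <- circle_contour(n, 0.5)
  x <- base$x
  ctr <- c(0, 0)
  dirv <- x[5, ] / sqrt(sum(x[5, ]^2))
  x[5, ] <- x[5, ] + 1e-3 * dirv
  f1 <- bending_force_density(contour(x, base$x, Kb = 0.05))
  f2 <- bending_force_density(contour(x, base$x, Kb = 0.10))
  expect_lt(sum(f1[5, ] * dirv), 0)          # restoring
  expect_equal(f2[5, ], 2 * f1[5, ], tolerance = 1e-6)  # linear in Kb
})

test_that("contour area and centroid are exact on simple shapes", {
  sq <- contour(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_equal(contour_area(sq), 2)
  expect_equal(contour_centroid(sq), c(1, 0.5))
})
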