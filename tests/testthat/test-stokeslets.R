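test_that("zero forces give zero velocity and pressure everywhere", {
  set.seed(1)
  src <- cbind(runif(7), runif(7))
  sol <- fluid_solution(point_forces(src, matrix(0, 7, 2)), epsilon = 0.02)
  tg <- cbind(runif(11, -1, 2), runif(11, -1, 2))
  expect_equal(velocity_at(sol, tg), matrix(0, 11, 2))
  expect_equal(pressure_at(sol, tg), rep(0, 11))
})

test_that("velocity and pressure are superpositions of per-force fields", {
  set.seed(2)
  src <- cbind(runif(6), runif(6))
  f1 <- matrix(rnorm(12), 6, 2)
  f2 <- matrix(rnorm(12), 6, 2)
  tg <- cbind(runif(9, -1, 2), runif(9, -1, 2))
  s12 <- fluid_solution(point_forces(src, f1 + f2), 0.03)
  s1 <- fluid_solution(point_forces(src, f1), 0.03)
  s2 <- fluid_solution(point_forces(src, f2), 0.03)
  expect_equal(velocity_at(s12, tg), velocity_at(s1, tg) + velocity_at(s2, tg),
               tolerance = 1e-12)
  expect_equal(pressure_at(s12, tg), pressure_at(s1, tg) + pressure_at(s2, tg),
               tolerance = 1e-12)
})

test_that("velocity is finite at and around source points", {
  src <- matrix(c(0.3, -0.2), 1, 2)
  sol <- fluid_solution(point_forces(src, matrix(c(2, 1), 1, 2)), 0.02)
  line <- cbind(seq(0.3 - 0.1, 0.3 + 0.1, length.out = 401), -0.2)
  u <- velocity_at(sol, line)
  expect_true(all(is.finite(u)))
  # continuity across the source: neighbouring samples stay close
  expect_lt(max(abs(diff(u[, 1]))), 0.05 * max(abs(u[, 1])))
})

test_that("far field matches the singular 2D Stokeslet within 1% at r = 100 eps", {
  eps <- 0.02
  f <- c(1.3, -0.4)
  sol <- fluid_solution(point_forces(matrix(0, 1, 2), matrix(f, 1, 2)), eps)
  # independent singular Stokeslet with the same outer screening length
  singular <- function(x, f, L0 = 10) {
    r <- sqrt(sum(x^2))
    (1 / (4 * pi)) * (f * log(L0 / r) + sum(f * x) * x / r^2)
  }
  for (th in c(0.3, 1.2, 2.5, 4.4)) {
    x <- 100 * eps * c(cos(th), sin(th))
    u <- velocity_at(sol, matrix(x, 1, 2))[1, ]
    us <- singular(x, f)
    expect_lt(sqrt(sum((u - us)^2)) / sqrt(sum(us^2)), 0.01)
  }
})

test_that("regularized fields satisfy the forced Stokes equations", {
  # independent oracle: finite differences of the returned fields must
  # reproduce mu Lap(u) - grad p + f phi_eps = 0 and div u = 0
  eps <- 0.05
  f <- c(1.3, -0.4)
  src <- matrix(c(0.2, -0.1), 1, 2)
  sol <- fluid_solution(point_forces(src, matrix(f, 1, 2)), eps)
  h <- 1e-4
  pt <- c(0.27, 0.02)
  gu <- function(p) velocity_at(sol, matrix(p, 1, 2))[1, ]
  gp <- function(p) pressure_at(sol, matrix(p, 1, 2))[1]
  lapu <- (gu(pt + c(h, 0)) + gu(pt - c(h, 0)) + gu(pt + c(0, h)) +
           gu(pt - c(0, h)) - 4 * gu(pt)) / h^2
  gradp <- c(gp(pt + c(h, 0)) - gp(pt - c(h, 0)),
             gp(pt + c(0, h)) - gp(pt - c(0, h))) / (2 * h)
  r2 <- sum((pt - src[1, ])^2)
  phi <- 3 * eps^3 / (2 * pi * (r2 + eps^2)^2.5)
  resid <- lapu - gradp + f * phi
  expect_lt(max(abs(resid)), 1e-4 * max(abs(gradp)))
  divu <- (gu(pt + c(h, 0))[1] - gu(pt - c(h, 0))[1] +
           gu(pt + c(0, h))[2] - gu(pt - c(0, h))[2]) / (2 * h)
  expect_lt(abs(divu), 1e-5)
})

test_that("pressure kernel has the parity and compression structure", {
  eps <- 0.03
  sol <- fluid_solution(point_forces(matrix(0, 1, 2), matrix(c(1, 0), 1, 2)),
                        eps)
  pts <- cbind(c(0.4, -0.4, 0.15, -0.15), c(0.2, 0.2, -0.3, -0.3))
  p <- pressure_at(sol, pts)
  expect_equal(p[1], -p[2], tolerance = 1e-12)
  expect_equal(p[3], -p[4], tolerance = 1e-12)
  # two opposing forces approaching each other raise pressure in between
  d <- 0.4
  src2 <- rbind(c(-d / 2, 0), c(d / 2, 0))
  f2 <- rbind(c(1, 0), c(-1, 0))
  sol2 <- fluid_solution(point_forces(src2, f2), eps)
  xs <- seq(-1.2, 1.2, length.out = 241)
  p2 <- pressure_at(sol2, cbind(xs, 0))
  inner <- abs(xs) < d / 2 - 0.05
  outer <- abs(xs) > d / 2 + 0.05
  expect_gt(mean(p2[inner]), max(p2[outer]))
})

test_that("doubling viscosity halves velocities at fixed forces", {
  set.seed(4)
  src <- cbind(runif(5), runif(5)); f <- matrix(rnorm(10), 5, 2)
  tg <- cbind(runif(6), runif(6))
  u1 <- velocity_at(fluid_solution(point_forces(src, f), 0.02, viscosity = 1), tg)
  u2 <- velocity_at(fluid_solution(point_forces(src, f), 0.02, viscosity = 2), tg)
  expect_equal(u1, 2 * u2, tolerance = 1e-12)
})

test_that("mobility matrix is symmetric, isotropic on-site, and PSD", {
  M1 <- mobility_matrix(matrix(c(0.4, -0.1), 1, 2), 0.02)
  expect_equal(M1[1, 1], M1[2, 2])
  expect_equal(M1[1, 2], 0)
  expect_gt(M1[1, 1], 0)

  set.seed(5)
  L <- cbind(runif(50, 0, 4), runif(50, -2, 2))
  M <- mobility_matrix(L, 0.02)
  expect_equal(M, t(M), tolerance = 1e-12)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(abs(ev)))
  # applying M to stacked forces reproduces velocity_at
  f <- matrix(rnorm(100), 50, 2)
  u <- velocity_at(fluid_solution(point_forces(L, f), 0.02), L)
  uM <- matrix(M %*% as.vector(t(f)), ncol = 2, byrow = TRUE)
  expect_equal(u, uM, tolerance = 1e-10)
})

test_that("epsilon must be positive", {
  pf <- point_forces(matrix(0, 1, 2), matrix(1, 1, 2))
  expect_error(fluid_solution(pf, epsilon = 0), "epsilon")
  expect_error(fluid_solution(pf, epsilon = -1), "epsilon")
})

test_that("field maps are gridded with zero fields for zero forces", {
  sol <- fluid_solution(point_forces(matrix(0, 1, 2), matrix(0, 1, 2)), 0.02)
  fm <- field_map(sol, c(-1, 1), c(-1, 1), n = 10)
  expect_equal(nrow(fm), 100)
  expect_true(all(fm$u == 0 & fm$v == 0 & fm$p == 0 & fm$speed == 0))
  tmp <- tempfile(fileext = ".tsv")
  write_field_map(fm, tmp)
  back <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back$x, fm$x)
})
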