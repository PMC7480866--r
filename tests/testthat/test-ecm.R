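test_that("Delaunay edges of canonical configurations", {
  tri <- delaunay_edges(rbind(c(0, 0), c(1, 0), c(0.4, 1)))
  expect_equal(nrow(tri), 3)
  quad <- delaunay_edges(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(quad), 5)   # square plus one diagonal
  expect_error(delaunay_edges(cbind(0:4, 0:4)), "collinear")
})

test_that("Delaunay triangulation satisfies planarity and empty circumcircles", {
  set.seed(21)
  for (rep in 1:3) {
    p <- cbind(runif(25, 0, 4), runif(25, -2, 2))
    e <- delaunay_edges(p)
    expect_lte(nrow(e), 3 * 25 - 6)
    tris <- stokescell:::delaunay_triangles(p)
    # brute-force oracle: no point strictly inside any circumcircle
    ok <- TRUE
    for (t in seq_len(nrow(tris))) {
      for (q in setdiff(seq_len(25), tris[t, ])) {
        if (stokescell:::in_circumcircle(p, tris[t, ], q)) ok <- FALSE
      }
    }
    expect_true(ok)
  }
})

test_that("lattice generation is seeded, in-box, and respects the exclusion", {
  lat1 <- generate_ecm(30, seed = 7)
  lat2 <- generate_ecm(30, seed = 7)
  expect_identical(lat1$x0, lat2$x0)
  expect_identical(lat1$edges, lat2$edges)
  lat3 <- generate_ecm(30, seed = 8)
  expect_false(identical(lat1$x0, lat3$x0))
  expect_true(all(lat1$x0[, 1] >= 0 & lat1$x0[, 1] <= 4))
  expect_true(all(lat1$x0[, 2] >= -2 & lat1$x0[, 2] <= 2))
  d2excl <- sqrt((lat1$x0[, 1] - 0.25)^2 + lat1$x0[, 2]^2)
  expect_true(all(d2excl >= lat1$exclusion$radius))
  dm <- as.matrix(dist(lat1$x0)); diag(dm) <- Inf
  expect_gte(min(dm), 0.15)
})

test_that("generation fails gracefully when the box cannot host the nodes", {
  expect_error(generate_ecm(50, box = c(0, 0.5, 0, 0.5), exclusion = NULL,
                            min_spacing = 0.2, seed = 1, max_tries = 500),
               "failed")
})

test_that("pinning makes the initial lattice exactly force-free", {
  lat <- generate_ecm(40, seed = 3)
  f <- ecm_force(lat)
  # machine scale: tether stiffness times one ulp of the stored reference
  expect_lt(max(abs(f)), 1e-10)
  # symmetric star: the center node's neighbour vectors cancel, so its
  # tether reference coincides with its position
  star <- structure(list(x0 = rbind(c(0, 0), c(1, 0), c(-1, 0),
                                    c(0, 1), c(0, -1)),
                         edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
                         k_ecm = 50, k_tether = 50),
                    class = "ecm_lattice")
  ref <- compute_pinning(star)
  expect_equal(ref[1, ], c(0, 0), tolerance = 1e-14)
  expect_false(isTRUE(all.equal(ref[2, ], star$x0[2, ])))
  expect_lt(max(abs(ecm_force(structure(c(star, list(ref = ref)),
                                        class = "ecm_lattice"),
                              x = star$x0))), 1e-12)
})

test_that("rigid translation of the lattice is penalized by the tethers", {
  lat <- generate_ecm(25, seed = 5)
  d <- c(0.3, -0.2)
  f <- ecm_force(lat, x = sweep(lat$x0, 2, d, "+"))
  expect_equal(f, matrix(rep(-lat$k_tether * d, each = 25), 25, 2),
               tolerance = 1e-10)
})

test_that("displacing one node yields the restoring spring-plus-tether force", {
  lat <- generate_ecm(25, seed = 6)
  i <- 4
  deg <- sum(lat$edges == i)
  delta <- c(0.01, -0.02)
  x <- lat$x0; x[i, ] <- x[i, ] + delta
  f <- ecm_force(lat, x = x)
  expect_equal(f[i, ], -(lat$k_ecm * deg + lat$k_tether) * delta,
               tolerance = 1e-10)
  # pairwise spring forces are equal and opposite: the displaced node's
  # neighbours pick up exactly the reaction
  nb <- setdiff(unique(as.vector(lat$edges[rowSums(lat$edges == i) > 0, ])), i)
  expect_equal(colSums(f[nb, , drop = FALSE]), lat$k_ecm * deg * delta,
               tolerance = 1e-10)
})

test_that("spacing statistics report both nearest-neighbour and edge length", {
  lat <- generate_ecm(60, seed = 9)
  sp <- lattice_spacing(lat)
  expect_true(sp$mean_nn > 0 && sp$mean_edge >= sp$mean_nn)
})

test_that("lattice tables round-trip through files", {
  lat <- generate_ecm(15, seed = 11)
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  write_ecm(lat, nf, ef)
  back <- read_ecm(nf, ef)
  expect_equal(back$x0, lat$x0, tolerance = 1e-12)
  expect_equal(back$ref, lat$ref, tolerance = 1e-12)
  expect_equal(back$edges[, 1], lat$edges[, 1])
  expect_lt(max(abs(ecm_force(back))), 1e-10)
})
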