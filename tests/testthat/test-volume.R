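test_that("capture-simplex volume matches the closed form and rejection", {
  net <- two_pop()
  v <- simplex_volume(net, 7)
  expect_equal(v$value, 49 / 2.4, tolerance = 1e-12)
  expect_identical(v$method, "analytic")
  net1 <- energetic_network(matrix(1, 1, 1), 1, 1)
  expect_equal(simplex_volume(net1, 1)$value, 1)
  # homogeneity: doubling Q multiplies by 2^S
  expect_equal(simplex_volume(net, 14)$value, 2^2 * simplex_volume(net, 7)$value)
  # rejection oracle: hit fraction of the simplex in its bounding box
  set.seed(1)
  n <- 2e4
  U <- cbind(stats::runif(n, 0, 7), stats::runif(n, 0, 7 / 1.2))
  hit <- mean(U %*% net$N0 <= 7)
  expect_close(hit * 7 * (7 / 1.2), v$value, 4 * 7 * (7 / 1.2) / sqrt(n))
})

test_that("exact polytope volume handles cubes, simplices and empties", {
  cube <- hpolytope(rbind(-diag(3), diag(3)), c(rep(0, 3), rep(1, 3)))
  expect_equal(polytope_volume_exact(cube)$value, 1, tolerance = 1e-10)
  net <- two_pop()
  expect_equal(polytope_volume_exact(capture_domain(net, 7))$value,
               simplex_volume(net, 7)$value, tolerance = 1e-9)
  emp <- hpolytope(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                   c(0, -1, 1, 0))
  expect_equal(polytope_volume_exact(emp)$value, 0)
})

test_that("exact volumes agree with rejection sampling on random bodies", {
  for (d in 2:4) {
    for (seed in 1:3) {
      poly <- random_box_cut(d, k = 3, seed = 10 * d + seed)
      ve <- polytope_volume_exact(poly)$value
      vr <- rejection_volume(interpolyquad(poly),
                             box_envelope(rep(0, d), rep(1, d)),
                             n = 4e4, seed = seed)
      expect_close(ve, vr$value, 4 * vr$standard_error + 1e-9)
    }
  }
})

test_that("hit-and-run samples are uniform and always feasible", {
  sq <- interpolyquad(hpolytope(rbind(-diag(2), diag(2)), c(0, 0, 1, 1)))
  X <- hit_and_run(sq, 1e4, seed = 1)
  expect_true(all(body_contains(sq, X, tol = 1e-10)))
  # componentwise means of U[0,1]^2 within 4 SE (sd = 1/sqrt(12))
  se <- 1 / sqrt(12) / sqrt(1e4)
  expect_close(mean(X[, 1]), 0.5, 4 * se)
  expect_close(mean(X[, 2]), 0.5, 4 * se)
  # uniform disk: E[r^2] = 1/2 (quadratic-only body plus a loose box)
  disk <- interpolyquad(hpolytope(2 * rbind(-diag(2), diag(2)), rep(2, 4)),
                        quad_constraint(diag(2), c(0, 0), 1))
  Y <- hit_and_run(disk, 1e4, seed = 2)
  expect_true(all(rowSums(Y^2) <= 1 + 1e-10))
  expect_close(mean(rowSums(Y^2)), 0.5, 4 * sqrt(1 / 12) / sqrt(1e4) * 3)
  expect_error(hit_and_run(sq, 10, start = c(2, 2)), "interior")
})

test_that("multiphase volumes match exact volumes across random bodies", {
  # cube cross-check
  cube <- interpolyquad(hpolytope(rbind(-diag(3), diag(3)),
                                  c(rep(0, 3), rep(1, 3))))
  est <- multiphase_volume(cube, samples_per_phase = 5000, seed = 1)
  expect_close(est$value, 1, 3 * est$standard_error)
  # random 2-4 D polytopes, 5% relative agreement
  for (d in 2:4) {
    poly <- random_box_cut(d, k = 2, seed = 20 + d)
    ve <- polytope_volume_exact(poly)$value
    em <- multiphase_volume(interpolyquad(poly),
                            samples_per_phase = 2e4, seed = d)
    expect_lt(abs(em$value - ve) / ve, 0.05)
  }
  # ellipsoid with closed-form area pi/2
  el <- interpolyquad(hpolytope(rbind(-diag(2), diag(2)), rep(2, 4)),
                      quad_constraint(diag(c(4, 1)), c(0, 0), 1))
  ee <- multiphase_volume(el, samples_per_phase = 2e4, seed = 5)
  expect_close(ee$value, pi / 2, 4 * ee$standard_error)
})

test_that("multiphase estimates are seed-deterministic and shift-invariant", {
  poly <- random_box_cut(3, k = 2, seed = 31)
  a <- multiphase_volume(interpolyquad(poly), samples_per_phase = 5000,
                         seed = 42)
  b <- multiphase_volume(interpolyquad(poly), samples_per_phase = 5000,
                         seed = 42)
  expect_identical(a$value, b$value)
  # translation: shift the body by (10, -3, 5)
  shift <- c(10, -3, 5)
  poly2 <- hpolytope(poly$A, poly$b + as.numeric(poly$A %*% shift))
  c2 <- multiphase_volume(interpolyquad(poly2), samples_per_phase = 2e4,
                          seed = 7)
  expect_close(c2$value, polytope_volume_exact(poly)$value,
               4 * c2$standard_error + 0.02 * c2$value)
})

test_that("rejection volume is exact in expectation with binomial error", {
  sq <- interpolyquad(hpolytope(rbind(-diag(2), diag(2)), c(0, 0, 1, 1)))
  env <- box_envelope(c(0, 0), c(1, 1))
  expect_equal(rejection_volume(sq, env, n = 1000, seed = 1)$value, 1)
  half <- interpolyquad(hpolytope(rbind(-diag(2), diag(2), c(1, 1)),
                                  c(0, 0, 1, 1, 1)))
  est <- rejection_volume(half, env, n = 1e4, seed = 2)
  expect_close(est$value, 0.5, 4 * est$standard_error)
  # two-population initialization polytope inside its capture simplex
  net <- two_pop()
  di <- initialization_domain(net, 7)
  er <- rejection_volume(interpolyquad(di), simplex_envelope(net, 7),
                         n = 4e4, seed = 3)
  expect_close(er$value, polytope_volume_exact(di)$value,
               4 * er$standard_error)
})

test_that("polygon-disk clipping reproduces closed-form areas", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  # disk covering the square entirely
  expect_equal(enerfeas:::convex_polygon_disk_area(sq, 10), 1,
               tolerance = 1e-12)
  # quarter disk of radius 0.6 at the corner
  expect_equal(enerfeas:::convex_polygon_disk_area(sq, 0.6),
               pi * 0.36 / 4, tolerance = 1e-12)
  # disk strictly inside a big square
  big <- 10 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  expect_equal(enerfeas:::convex_polygon_disk_area(big, 2), 4 * pi,
               tolerance = 1e-10)
  # disjoint: polygon far from the disk
  far <- sq + 5
  expect_equal(enerfeas:::convex_polygon_disk_area(far, 1), 0,
               tolerance = 1e-10)
  # random triangle against rejection sampling
  set.seed(4)
  tri <- matrix(stats::runif(6, -1.2, 1.2), 3, 2)
  n <- 2e5
  P <- matrix(stats::runif(2 * n, -1.3, 1.3), n, 2)
  inside_tri <- function(P, V) {
    s <- function(a, b, p) (b[1]-a[1])*(p[,2]-a[2]) - (b[2]-a[2])*(p[,1]-a[1])
    d1 <- s(V[1, ], V[2, ], P); d2 <- s(V[2, ], V[3, ], P)
    d3 <- s(V[3, ], V[1, ], P)
    (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  }
  hits <- inside_tri(P, tri) & rowSums(P^2) <= 1
  mc <- mean(hits) * 2.6^2
  expect_close(enerfeas:::convex_polygon_disk_area(tri, 1), mc,
               4 * 2.6^2 * sqrt(mean(hits) / n) + 1e-3)
})
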