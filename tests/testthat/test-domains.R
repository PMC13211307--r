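test_that("capture domain is the supply simplex", {
  net <- two_pop()
  dc <- capture_domain(net, 7)
  V <- polytope_vertices(dc)
  V <- V[order(V[, 1], V[, 2]), ]
  expect_equal(V, rbind(c(0, 0), c(0, 7 / 1.2), c(7, 0)), tolerance = 1e-9)
  # homogeneity: doubling Q doubles every vertex
  V2 <- polytope_vertices(capture_domain(net, 14))
  expect_equal(sort(V2[, 1]), 2 * sort(V[, 1]), tolerance = 1e-9)
  expect_error(capture_domain(net, -1), "positive")
  # S = 1: a segment [0, Q/N0]
  net1 <- energetic_network(matrix(2, 1, 1), 1, 1)
  expect_equal(sort(polytope_vertices(capture_domain(net1, 1))[, 1]),
               c(0, 1))
})

test_that("initialization domain is empty below the critical supply", {
  net <- two_pop()
  expect_equal(polytope_volume_exact(initialization_domain(net, 3))$value, 0)
  di7 <- initialization_domain(net, 7)
  expect_gt(polytope_volume_exact(di7)$value, 0)
  # contains the small-multiplier cone point d + sigma (0.01, 0.01)
  p <- as.numeric(net$d + net$sigma %*% c(0.01, 0.01))
  expect_true(body_contains(di7, p))
  expect_lt(sum(p * net$N0), 7)
})

test_that("empty-community initialization region is s < d inside the simplex", {
  net <- two_pop()
  d0 <- initialization_domain(net, 7, integer(0))
  expect_true(body_contains(d0, c(0.5, 0.5)))
  expect_true(body_contains(d0, 0.99 * net$d))
  expect_false(body_contains(d0, c(1.5, 0.5)))   # s_1 > d_1
  expect_false(body_contains(d0, c(0.5, 2.0)))   # s_2 > d_2
})

test_that("maturation domain adds the steady-state capture cap", {
  net <- two_pop()
  s <- c(4.42, 4.23)            # N* = (1,1): s'N* = 8.65, s'N0 = 9.496
  expect_equal(sum(s * steady_state(net, s)), 8.65, tolerance = 1e-12)
  expect_equal(sum(s * net$N0), 9.496, tolerance = 1e-12)
  expect_false(body_contains(maturation_domain(net, 8.0), s))   # cap binds
  expect_false(body_contains(maturation_domain(net, 9.4), s))   # simplex binds
  expect_true(body_contains(maturation_domain(net, 9.6), s))
  expect_true(body_contains(maturation_domain(net, 15), s))
  # empty community: quadratic inactive, equals initialization domain
  dm0 <- maturation_domain(net, 7, integer(0))
  expect_null(dm0$quad)
  # non-dissipative matrices are refused
  bad <- energetic_network(matrix(c(0.1, 4, 0, 0.1), 2, 2), c(1, 1), c(1, 1))
  expect_error(maturation_domain(bad, 7), "dissipative")
})

test_that("domains nest: maturation within initialization within capture", {
  net <- two_pop()
  for (Q in c(7, 15)) {
    dm <- maturation_domain(net, Q)
    X <- hit_and_run(dm, 1000, seed = 1)
    expect_true(all(body_contains(initialization_domain(net, Q), X,
                                  tol = 1e-9)))
    expect_true(all(body_contains(capture_domain(net, Q), X, tol = 1e-9)))
  }
})

test_that("initialization domains grow monotonically with supply", {
  net <- two_pop()
  d1 <- initialization_domain(net, 5)
  d2 <- initialization_domain(net, 9)
  # only the supply-cap row changes
  expect_equal(d1$A, d2$A)
  expect_equal(d1$b[-length(d1$b)], d2$b[-length(d2$b)])
  X <- hit_and_run(interpolyquad(d1), 300, seed = 4)
  expect_true(all(body_contains(d2, X, tol = 1e-10)))
})

test_that("Chebyshev centers solve the inscribed-ball program", {
  sq <- hpolytope(rbind(-diag(2), diag(2)), c(0, 0, 1, 1))
  cc <- chebyshev_center(sq)
  expect_equal(cc$center, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(cc$radius, 0.5, tolerance = 1e-6)
  # right isoceles simplex: inradius 1/(2 + sqrt(2))
  tri <- hpolytope(rbind(c(-1, 0), c(0, -1), c(1, 1)), c(0, 0, 1))
  expect_equal(chebyshev_center(tri)$radius, 1 / (2 + sqrt(2)),
               tolerance = 1e-6)
  # infeasible rows flag emptiness via radius <= 0
  emp <- hpolytope(rbind(c(1, 0), c(-1, 0)), c(0, -1))
  expect_lte(chebyshev_center(emp)$radius, 0)
})

test_that("interior points strictly satisfy all constraints", {
  sq <- hpolytope(rbind(-diag(2), diag(2)), c(0, 0, 1, 1))
  expect_equal(interior_point(interpolyquad(sq)), c(0.5, 0.5),
               tolerance = 1e-6)
  # inactive disk leaves the Chebyshev center in place
  big <- interpolyquad(sq, quad_constraint(diag(2), c(0, 0), 100))
  expect_equal(interior_point(big), c(0.5, 0.5), tolerance = 1e-6)
  # active disk: returned point feasible for every constraint
  tight <- interpolyquad(sq, quad_constraint(diag(2), c(0, 0), 0.36))
  p <- interior_point(tight)
  expect_true(body_contains(tight, p))
  # empty intersection signals NULL (disk too far from the square)
  off <- interpolyquad(sq, quad_constraint(diag(2), c(-20, -20), -199.99))
  expect_null(interior_point(off))
})

test_that("whitening centers the quadratic and tracks the Jacobian", {
  sq <- hpolytope(rbind(-diag(2), diag(2)), c(2, 2, 2, 2))
  idb <- standardize(interpolyquad(sq, quad_constraint(diag(2), c(0, 0), 4)))
  expect_equal(idb$logdet, 0)
  expect_equal(idb$quad$c, 4)
  # M = diag(4,1): |det T^-1| = 1/2, whitened quadratic is the unit ball
  el <- standardize(interpolyquad(sq, quad_constraint(diag(c(4, 1)),
                                                      c(0, 0), 1)))
  expect_equal(el$logdet, log(2))
  expect_equal(el$quad$M, diag(2))
  expect_equal(el$quad$c, 1)
  expect_error(standardize(interpolyquad(sq,
    quad_constraint(diag(c(1, -1)), c(0, 0), 1))), "positive definite")
})

test_that("whitened and original volumes agree through the Jacobian", {
  net <- two_pop()
  dm <- maturation_domain(net, 15)
  w <- standardize(dm)
  a_orig <- enerfeas:::ipq_area_2d(dm)
  # whitened area via rejection in a box around the whitened body
  set.seed(2)
  V <- polytope_vertices(w$polytope)
  r <- sqrt(w$quad$c)
  lo <- pmin(apply(V, 2, min), -r) - 0.1
  hi <- pmax(apply(V, 2, max), r) + 0.1
  est <- rejection_volume(w, box_envelope(lo, hi), n = 2e5, seed = 3)
  expect_close(est$value * exp(-w$logdet), a_orig,
               4 * est$standard_error * exp(-w$logdet))
})
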