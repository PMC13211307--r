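test_that("probabilities vanish below the critical supply and are nested", {
  net <- two_pop()
  p3 <- feasibility_probability(net, 3.0)
  expect_equal(p3$p_init, 0)
  expect_equal(p3$p_mat, 0)
  p7 <- feasibility_probability(net, 7)
  expect_gte(p7$p_init, p7$p_mat)
  expect_gt(p7$p_init, 0)
})

test_that("raising supply favors initialization but penalizes maturation", {
  net <- two_pop()
  p7 <- feasibility_probability(net, 7)
  p15 <- feasibility_probability(net, 15)
  expect_gt(p15$p_init, p7$p_init)
  expect_lt(p15$p_mat, p7$p_mat)
})

test_that("exact, quadrature and rejection probability routes agree", {
  net <- two_pop()
  for (Q in c(5, 7, 15)) {
    ex <- feasibility_probability(net, Q)
    rj <- feasibility_probability(net, Q, method = "rejection",
                                  samples = 1e5, seed = 1)
    expect_close(ex$p_init, rj$p_init, 4 * rj$se_init + 1e-9)
    expect_close(ex$p_mat, rj$p_mat, 4 * rj$se_mat + 1e-9)
  }
})

test_that("the empty community owns the whole simplex at very low supply", {
  net <- two_pop()
  p <- feasibility_probability(net, 0.5, members = integer(0))
  expect_equal(p$p_init, 1, tolerance = 1e-9)
  expect_equal(p$p_mat, 1, tolerance = 1e-9)
})

test_that("critical supply is the LP infimum and is bounded by d'N0", {
  net <- two_pop()
  expect_equal(critical_supply(net), 3.36, tolerance = 1e-6)
  free <- energetic_network(net$sigma, c(0, 0), net$N0)
  expect_equal(critical_supply(free), 0, tolerance = 1e-9)
  for (seed in 1:5) {
    rn <- random_net(4, seed)
    expect_lte(critical_supply(rn), sum(rn$d * rn$N0) + 1e-9)
  }
  # partial-community cones can open below d'N0
  expect_lt(critical_supply(net, 1), sum(net$d * net$N0))
})

test_that("optimal supply finds the maturation peak", {
  # synthetic curve with a constructed maximum at Q = 5
  Q <- exp(seq(log(1), log(30), length.out = 60))
  cv <- structure(data.frame(Q = Q, p_init = 1,
                             p_mat = exp(-(log(Q) - log(5))^2),
                             se_init = 0, se_mat = 0,
                             method_init = "exact", method_mat = "exact"),
                  class = c("probability_curve", "data.frame"))
  expect_equal(optimal_supply(cv)$Q_opt, 5, tolerance = 0.1)
  # all-zero curve: undefined optimum flag
  cv0 <- cv; cv0$p_mat <- 0
  expect_false(optimal_supply(cv0)$defined)
})

test_that("partition probabilities form a complete partition", {
  net <- two_pop()
  pp <- partition_probabilities(net, 7, n = 4e4, seed = 1)
  expect_equal(nrow(pp), 4)
  expect_equal(sum(pp$p_init), 1, tolerance = 1e-9)
  expect_lt(abs(attr(pp, "unassigned")), 1e-9)
  expect_true(all(pp$p_mat <= pp$p_init + 1e-12))
  # exact route: per-community initialization volumes tile the simplex
  for (seed in c(1, 3)) {
    rn <- random_net(3, seed)
    Q <- 1.5 * sum(rn$d * rn$N0)
    vols <- vapply(communities(3), function(m)
      polytope_volume_exact(initialization_domain(rn, Q, m))$value, 0)
    expect_equal(sum(vols), simplex_volume(rn, Q)$value, tolerance = 1e-7)
  }
})

test_that("Monte Carlo partition table matches exact community volumes", {
  net <- two_pop()
  Q <- 7
  pp <- partition_probabilities(net, Q, n = 1e5, seed = 2)
  vc <- simplex_volume(net, Q)$value
  for (k in seq_len(4)) {
    mem <- which(strsplit(pp$mask[k], "")[[1]] == "1")
    ve <- polytope_volume_exact(initialization_domain(net, Q, mem))$value
    expect_close(pp$p_init[k], ve / vc, 4 * pp$se_init[k] + 1e-9)
  }
})

test_that("partial-community maturation volumes agree across routes", {
  net <- two_pop()
  for (Q in c(2, 5)) {
    dm <- maturation_domain(net, Q, 1)
    rej <- rejection_volume(dm, simplex_envelope(net, Q), n = 1e5, seed = 2)
    mp <- multiphase_volume(enerfeas:::maturation_body_ncoord(net, Q, 1),
                            samples_per_phase = 1e4, seed = 3)
    tol <- 4 * sqrt(rej$standard_error^2 + mp$standard_error^2)
    expect_close(mp$value, rej$value, tol)
  }
})

test_that("average diversity weights sizes by maturation mass", {
  # constructed partitions: only the full community matures
  fake <- data.frame(mask = c("00", "10", "01", "11"), D = c(0, 1, 1, 2),
                     p_init = c(0, 0, 0, 1), p_mat = c(0, 0, 0, 1),
                     se_init = 0, se_mat = 0, n = 1)
  expect_equal(average_diversity(NULL, 1, partition = fake,
                                 normalized = TRUE), 2)
  # uniform maturation over nonempty communities:
  # normalized <D> = S 2^(S-1) / (2^S - 1)
  S <- 3
  cs <- communities(S)
  fake2 <- data.frame(mask = vapply(cs, function(m)
    paste(as.integer(seq_len(S) %in% m), collapse = ""), ""),
    D = lengths(cs), p_init = 0.1, p_mat = 0.1, se_init = 0, se_mat = 0,
    n = 1)
  expect_equal(average_diversity(NULL, 1, partition = fake2,
                                 normalized = TRUE),
               S * 2^(S - 1) / (2^S - 1))
  expect_equal(average_diversity(NULL, 1, partition = fake2),
               0.1 * S * 2^(S - 1))
  # all-zero maturation: undefined
  fake3 <- fake; fake3$p_mat <- 0
  expect_warning(v <- average_diversity(NULL, 1, partition = fake3),
                 "undefined")
  expect_true(is.na(v))
})

test_that("multiphase maturation route agrees with rejection at S = 3", {
  net <- random_net(3, 2)
  Q <- 3 * sum(net$d * net$N0)
  ex <- feasibility_probability(net, Q, samples = 1e4, seed = 5)
  expect_identical(ex$method_mat, "multiphase_mc")
  rj <- feasibility_probability(net, Q, method = "rejection",
                                samples = 1e5, seed = 6)
  expect_close(ex$p_init, rj$p_init, 4 * rj$se_init + 1e-9)
  expect_close(ex$p_mat, rj$p_mat,
               4 * sqrt(ex$se_mat^2 + rj$se_mat^2) + 1e-9)
})
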