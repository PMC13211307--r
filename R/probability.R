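#' Initialization and maturation probabilities
#'
#' Feasibility probabilities are relative volumes: with capture rates
#' uniform on the capture simplex, \code{p_init} is the volume fraction of
#' the initialization domain and \code{p_mat} that of the maturation
#' domain. \code{p_init} uses the exact polytope volume. \code{p_mat} is
#' exact when the quadratic cap is provably inactive (checked by maximizing
#' the quadratic over the polytope's vertices), exact 2-D quadrature for
#' S = 2, and multiphase Monte Carlo otherwise. For partial communities
#' the Monte Carlo runs in multiplier coordinates, where the quadratic
#' block is the principal submatrix of \code{sigma} (convex under
#' dissipativity), with the Jacobian mapping back to capture space.
#'
#' @inheritParams initialization_domain
#' @param method "auto" (default) as described above; "rejection" forces
#'   the rejection-sampling estimate for both probabilities (used as an
#'   independent oracle in tests).
#' @param samples Monte Carlo samples (per phase for multiphase, total for
#'   rejection).
#' @param seed optional RNG seed.
#' @return list of class \code{"probability_point"}: \code{Q},
#'   \code{members}, \code{p_init}, \code{p_mat}, \code{se_init},
#'   \code{se_mat}, \code{method_init}, \code{method_mat}.
#' @export
feasibility_probability <- function(net, Q, members = seq_len(net$S),
                                    method = c("auto", "rejection"),
                                    samples = 2e4, seed = NULL) {
  method <- match.arg(method)
  members <- check_members(net$S, members)
  vC <- simplex_volume(net, Q)$value
  if (method == "rejection") {
    if (!is.null(seed)) set.seed(seed)
    X <- sample_capture_simplex(net, Q, samples)
    di <- initialization_domain(net, Q, members)
    dm <- maturation_domain(net, Q, members)
    ii <- body_contains(di, X, tol = 1e-12)
    mm <- ii & body_contains(dm, X, tol = 1e-12)
    pi_ <- mean(ii); pm <- mean(mm)
    return(prob_point(Q, members,
                      pi_, pm,
                      sqrt(pi_ * (1 - pi_) / samples),
                      sqrt(pm * (1 - pm) / samples),
                      "rejection", "rejection"))
  }
  di <- initialization_domain(net, Q, members)
  vi <- polytope_volume_exact(di)
  p_init <- vi$value / vC
  if (vi$value <= 0)
    return(prob_point(Q, members, 0, 0, 0, 0, "exact", "exact"))
  if (length(members) == 0)
    return(prob_point(Q, members, p_init, p_init, 0, 0, "exact", "exact"))
  dm <- maturation_domain(net, Q, members)
  # vertex max test: quadratic inactive over the whole polytope => D_M = D_I
  V <- polytope_vertices(di)
  qv <- apply(V, 1, function(x) quad_val(dm$quad, x))
  if (max(qv) <= dm$quad$c * (1 + 1e-10))
    return(prob_point(Q, members, p_init, p_init, 0, 0, "exact", "exact"))
  if (net$S == 2) {
    a <- ipq_area_2d(dm)
    return(prob_point(Q, members, p_init, a / vC, 0, 0,
                      "exact", "quadrature"))
  }
  est <- if (length(members) == net$S) {
    multiphase_volume(dm, samples_per_phase = samples, seed = seed)
  } else {
    multiphase_volume(maturation_body_ncoord(net, Q, members),
                      samples_per_phase = samples, seed = seed)
  }
  prob_point(Q, members, p_init, est$value / vC, 0,
             if (is.na(est$standard_error)) 0 else est$standard_error / vC,
             "exact", est$method)
}

prob_point <- function(Q, members, p_init, p_mat, se_init, se_mat,
                       method_init, method_mat) {
  structure(list(Q = Q, members = members, p_init = p_init, p_mat = p_mat,
                 se_init = se_init, se_mat = se_mat,
                 method_init = method_init, method_mat = method_mat),
            class = "probability_point")
}

#' @export
print.probability_point <- function(x, ...) {
  cat("Q = ", format(x$Q, digits = 4),
      ", community {", paste(x$members, collapse = ","), "}: ",
      "p_init = ", format(x$p_init, digits = 4), " (", x$method_init, "), ",
      "p_mat = ", format(x$p_mat, digits = 4), " (", x$method_mat, ")\n",
      sep = "")
  invisible(x)
}

# Maturation body for a partial community expressed in multiplier
# coordinates n (all S of them): polytope {n >= 0, d + B n >= 0,
# (d + B n)'N0 <= Q} with quadratic n_C' sigma_CC n_C + d_C'n_C <= Q.
# Volume in s-space = volume in n-space * |det B|; the Jacobian is carried
# in the body's logdet bookkeeping.
maturation_body_ncoord <- function(net, Q, members) {
  S <- net$S
  B <- support_basis(net, members)
  A <- rbind(-diag(S), -B, as.numeric(crossprod(B, net$N0)))
  b <- c(rep(0, S), net$d, Q - sum(net$d * net$N0))
  M <- matrix(0, S, S)
  if (length(members)) {
    sub <- net$sigma[members, members, drop = FALSE]
    M[members, members] <- (sub + t(sub)) / 2
  }
  v <- numeric(S)
  v[members] <- net$d[members]
  ldetB <- determinant(B, logarithm = TRUE)
  interpolyquad(hpolytope(A, b), quad_constraint(M, v, Q),
                trans = NULL, shift = NULL,
                logdet = -as.numeric(ldetB$modulus))
}

#' Probability curves over a supply grid
#'
#' Evaluates \code{feasibility_probability} over an increasing grid of
#' total-supply values.
#'
#' @inheritParams feasibility_probability
#' @param Q numeric vector of supply values (strictly increasing).
#' @return a data frame of class \code{"probability_curve"} with columns
#'   \code{Q}, \code{p_init}, \code{p_mat}, \code{se_init}, \code{se_mat},
#'   \code{method_init}, \code{method_mat}; the community and network id
#'   are attributes.
#' @export
probability_curve <- function(net, Q, members = seq_len(net$S),
                              method = c("auto", "rejection"),
                              samples = 2e4, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(Q) >= 1, all(diff(Q) > 0), all(Q > 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(Q, function(q)
    feasibility_probability(net, q, members, method, samples, seed = NULL))
  out <- data.frame(
    Q = Q,
    p_init = vapply(rows, `[[`, 0, "p_init"),
    p_mat = vapply(rows, `[[`, 0, "p_mat"),
    se_init = vapply(rows, `[[`, 0, "se_init"),
    se_mat = vapply(rows, `[[`, 0, "se_mat"),
    method_init = vapply(rows, `[[`, "", "method_init"),
    method_mat = vapply(rows, `[[`, "", "method_mat"))
  structure(out, members = check_members(net$S, members), net_id = net$id,
            class = c("probability_curve", "data.frame"))
}

#' @export
plot.probability_curve <- function(x, ...) {
  graphics::plot(x$Q, x$p_init, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "total energy supply Q", ylab = "probability",
                 col = "darkorange", ...)
  graphics::lines(x$Q, x$p_mat, col = "steelblue")
  graphics::legend("topleft", legend = c("initialization", "maturation"),
                   col = c("darkorange", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Critical energy supply
#'
#' The supply level at which the initialization domain first becomes
#' nonempty: the infimum of \code{s'N0} over the closure of the
#' community's feasibility cone intersected with \code{s >= 0}, computed
#' as a linear program over the multipliers. Always satisfies
#' \code{Q_c <= d'N0} (the multiplier origin gives \code{s = d}).
#'
#' @inheritParams initialization_domain
#' @return the critical supply (a nonnegative scalar).
#' @export
critical_supply <- function(net, members = seq_len(net$S)) {
  members <- check_members(net$S, members)
  B <- support_basis(net, members)
  # minimize (d + B n)'N0 over n >= 0, d + B n >= 0
  obj <- as.numeric(crossprod(B, net$N0))
  A <- rbind(-diag(net$S), -B)
  b <- c(rep(0, net$S), net$d)
  res <- solve_lp(obj, A, b, maximize = FALSE)
  if (res$status != "optimal")
    stop("critical-supply LP ", res$status)
  # n = 0 is always feasible (s = d), so Q_c <= d'N0 exactly; clamp away
  # regularized-solver fuzz at the equality case
  dn0 <- sum(net$d * net$N0)
  max(0, min(dn0 + res$value, dn0))
}

#' Optimal energy supply (maturation peak)
#'
#' Locates the supply maximizing the maturation probability. Works from a
#' computed \code{probability_curve}; with \code{refine = TRUE} and a
#' two-population network, the grid argmax is refined by golden-section
#' search on the exact quadrature probability.
#'
#' @param curve a \code{probability_curve}.
#' @param net the network the curve belongs to (needed for refinement).
#' @param refine logical; golden-section refinement (S = 2 only).
#' @return list of class \code{"energetic_regimes"} with \code{Q_opt},
#'   \code{p_mat_at_opt}, and \code{Q_c} when \code{net} is supplied.
#' @export
optimal_supply <- function(curve, net = NULL, refine = FALSE) {
  stopifnot(inherits(curve, "probability_curve"))
  if (all(curve$p_mat <= 0))
    return(structure(list(Q_c = if (!is.null(net)) critical_supply(net),
                          Q_opt = NA_real_, p_mat_at_opt = NA_real_,
                          defined = FALSE), class = "energetic_regimes"))
  i <- which.max(curve$p_mat)
  Q_opt <- curve$Q[i]
  p_opt <- curve$p_mat[i]
  if (refine && !is.null(net) && net$S == 2) {
    f <- function(q) {
      dm <- maturation_domain(net, q)
      ipq_area_2d(dm) / simplex_volume(net, q)$value
    }
    lo <- curve$Q[max(1, i - 1)]
    hi <- curve$Q[min(nrow(curve), i + 1)]
    opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-6 * Q_opt)
    Q_opt <- opt$maximum
    p_opt <- opt$objective
  }
  structure(list(Q_c = if (!is.null(net)) critical_supply(net),
                 Q_opt = Q_opt, p_mat_at_opt = p_opt, defined = TRUE),
            class = "energetic_regimes")
}

#' @export
print.energetic_regimes <- function(x, ...) {
  if (!is.null(x$Q_c))
    cat("critical supply Q_c  =", format(x$Q_c, digits = 4), "\n")
  cat("optimal supply Q_opt =", format(x$Q_opt, digits = 4),
      " (p_mat =", format(x$p_mat_at_opt, digits = 4), ")\n")
  invisible(x)
}

#' Feasibility partition probabilities by Monte Carlo classification
#'
#' Samples capture vectors uniformly in the capture simplex and assigns
#' each to the unique candidate community whose boundary-equilibrium
#' multipliers are all positive (the feasibility partition). Vectorized
#' over all \code{2^S} supports: one S x S solve per support classifies
#' every sample at once. \code{p_init} of a community is the fraction of
#' samples in its cone; \code{p_mat} additionally requires the
#' steady-state capture \code{s'N*_C <= Q}. By construction the
#' \code{p_init} column sums to 1 (partition completeness).
#'
#' @inheritParams capture_domain
#' @param n number of uniform samples.
#' @param seed optional RNG seed.
#' @return data frame with one row per candidate community: \code{mask}
#'   (e.g. "101"), \code{D}, \code{p_init}, \code{p_mat}, \code{se_init},
#'   \code{se_mat}, \code{n}.
#' @export
partition_probabilities <- function(net, Q, n = 2e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- net$S
  if (S > 12) stop("partition enumeration limited to S <= 12")
  X <- sample_capture_simplex(net, Q, n)
  R <- t(X) - net$d                      # S x n residuals s - d
  comms <- communities(S)
  assigned <- rep(FALSE, n)
  out <- vector("list", length(comms))
  for (k in seq_along(comms)) {
    members <- comms[[k]]
    W <- solve(support_basis(net, members))
    Nmat <- W %*% R                      # multipliers for all samples
    ok <- colSums(Nmat > 0) == S
    ok[assigned] <- FALSE
    assigned <- assigned | ok
    pin <- sum(ok) / n
    if (length(members) && any(ok)) {
      sc <- rowSums(X[ok, members, drop = FALSE] *
                    t(Nmat[members, ok, drop = FALSE]))
      pm <- sum(sc <= Q) / n
    } else {
      pm <- pin                          # empty community: cap inactive
    }
    out[[k]] <- data.frame(
      mask = paste(as.integer(seq_len(S) %in% members), collapse = ""),
      D = length(members), p_init = pin, p_mat = pm,
      se_init = sqrt(pin * (1 - pin) / n),
      se_mat = sqrt(pm * (1 - pm) / n), n = n)
  }
  res <- do.call(rbind, out)
  attr(res, "unassigned") <- 1 - sum(res$p_init)
  res
}

#' Average diversity at a supply level
#'
#' The community size expected under the feasibility partition, weighting
#' each nonempty candidate community by its maturation probability. The
#' default is the maturation-mass-weighted sum
#' \code{<D> = sum_C |C| p_mat(C)}: it is unimodal in Q and peaks below
#' the full community's optimal supply, because mid-sized communities are
#' combinatorially numerous and favored at intermediate supply. The
#' alternative \code{normalized = TRUE} divides by the total maturation
#' mass \code{sum_C p_mat(C)}; that ratio saturates toward the
#' slowest-decaying (largest) community size at high supply instead of
#' peaking, so it answers "how large is a maturing community, given one
#' matures" rather than "how much diversity does this supply sustain".
#'
#' @inheritParams partition_probabilities
#' @param normalized logical; divide by the total maturation mass
#'   (default \code{FALSE}).
#' @param partition optionally, a precomputed \code{partition_probabilities}
#'   table for this Q.
#' @return scalar; \code{NA} (with a warning) when every maturation
#'   probability is zero.
#' @export
average_diversity <- function(net, Q, n = 2e4, seed = NULL,
                              normalized = FALSE, partition = NULL) {
  pp <- if (is.null(partition)) partition_probabilities(net, Q, n, seed)
        else partition
  pp <- pp[pp$D > 0, ]
  tot <- sum(pp$p_mat)
  num <- sum(pp$D * pp$p_mat)
  if (tot == 0) {
    warning("all maturation probabilities are zero at Q = ", Q,
            "; average diversity undefined")
    return(NA_real_)
  }
  if (normalized) num / tot else num
}
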