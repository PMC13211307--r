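#' H-representation polytopes
#'
#' A convex polytope stored as \code{{s : A s <= b}}. Strict inequalities
#' arising from feasibility cones (\code{s > 0}, \code{n_i > 0}) are stored
#' as closed rows (boundaries have measure zero for volume purposes) with a
#' \code{strict} flag kept for membership tests.
#'
#' @param A m x S constraint matrix.
#' @param b length-m bound vector.
#' @param strict optional logical vector marking rows that are strict in
#'   the defining inequalities.
#' @return an object of class \code{"hpolytope"}.
#' @export
hpolytope <- function(A, b, strict = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) stop("nrow(A) must equal length(b)")
  if (any(!is.finite(A))) stop("constraint rows must be finite")
  if (is.null(strict)) strict <- rep(FALSE, nrow(A))
  structure(list(A = A, b = b, strict = strict, d = ncol(A)),
            class = "hpolytope")
}

#' @export
print.hpolytope <- function(x, ...) {
  cat("H-polytope in R^", x$d, " with ", nrow(x$A), " constraints\n", sep = "")
  invisible(x)
}

#' Quadratic constraint \{s : s'M s + v's <= c\}
#'
#' Used for the steady-state energy-capture cap: with
#' \code{N*(s) = solve(sigma, s - d)}, the constraint \code{s'N*(s) <= Q}
#' has \code{M} = symmetrized \code{solve(sigma)}, \code{v = -solve(sigma) \%*\% d},
#' \code{c = Q}. \code{M} is positive definite when built from a dissipative
#' full-community map, and positive semidefinite for partial communities in
#' multiplier coordinates.
#'
#' @param M S x S symmetric matrix.
#' @param v length-S linear term.
#' @param c scalar offset.
#' @return an object of class \code{"quad_constraint"}.
#' @export
quad_constraint <- function(M, v, c) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
    stop("'M' must be symmetric")
  M <- (M + t(M)) / 2
  structure(list(M = M, v = as.numeric(v), c = as.numeric(c)[1]),
            class = "quad_constraint")
}

#' Polytope-ellipsoid intersections (InterPolyQuads)
#'
#' The unified body class used by the volume engine: an H-polytope
#' optionally intersected with one convex quadratic constraint, together
#' with bookkeeping for whitening transforms (\code{trans}, \code{shift},
#' \code{logdet}) so volumes can be reported in original coordinates:
#' vol(original) = vol(whitened) * exp(-logdet).
#'
#' @param polytope an \code{hpolytope}.
#' @param quad a \code{quad_constraint} or \code{NULL}.
#' @param trans,shift,logdet whitening bookkeeping (internal).
#' @return an object of class \code{"interpolyquad"}.
#' @export
interpolyquad <- function(polytope, quad = NULL, trans = NULL, shift = NULL,
                          logdet = 0) {
  stopifnot(inherits(polytope, "hpolytope"))
  if (!is.null(quad)) stopifnot(inherits(quad, "quad_constraint"))
  structure(list(polytope = polytope, quad = quad, d = polytope$d,
                 trans = trans, shift = shift, logdet = logdet),
            class = "interpolyquad")
}

#' @export
print.interpolyquad <- function(x, ...) {
  cat("InterPolyQuad in R^", x$d, ": ", nrow(x$polytope$A), " linear rows, ",
      if (is.null(x$quad)) "no" else "one", " quadratic constraint\n", sep = "")
  invisible(x)
}

#' Membership test
#'
#' @param body an \code{hpolytope} or \code{interpolyquad}.
#' @param x point (vector) or matrix of row-points.
#' @param tol absolute tolerance (default 1e-12 for closed rows); strict
#'   rows require strict inequality beyond \code{-tol}.
#' @return logical vector.
#' @export
body_contains <- function(body, x, tol = 1e-12) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  poly <- if (inherits(body, "interpolyquad")) body$polytope else body
  slack <- matrix(poly$b, nrow(x), length(poly$b), byrow = TRUE) -
    x %*% t(poly$A)
  ok <- apply(slack, 1, function(r) all(r >= -tol))
  if (any(poly$strict)) {
    srows <- which(poly$strict)
    ok <- ok & apply(slack[, srows, drop = FALSE], 1,
                     function(r) all(r > tol))
  }
  if (inherits(body, "interpolyquad") && !is.null(body$quad)) {
    q <- body$quad
    val <- rowSums((x %*% q$M) * x) + as.numeric(x %*% q$v)
    ok <- ok & (val <= q$c + tol)
  }
  ok
}

#' Capture domain
#'
#' The simplex of nonnegative capture-rate vectors whose total
#' initialization capture does not exceed the supply:
#' \code{{s : s_i >= 0, sum_i s_i N0_i <= Q}}. Its vertices are the origin
#' and \code{(Q / N0_i) e_i}.
#'
#' @inheritParams steady_state
#' @param Q total energy supply (power), \code{Q > 0}.
#' @return an \code{hpolytope} with S+1 rows.
#' @export
capture_domain <- function(net, Q) {
  if (!is.numeric(Q) || length(Q) != 1 || !is.finite(Q) || Q <= 0)
    stop("'Q' must be a positive number")
  S <- net$S
  hpolytope(A = rbind(-diag(S), net$N0),
            b = c(rep(0, S), Q))
}

#' Initialization domain
#'
#' The subset of the capture domain for which the candidate community's
#' boundary equilibrium is admissible (all multipliers positive): the
#' feasibility cone of the community intersected with \code{s >= 0} and the
#' supply cap \code{s'N0 <= Q}. For the full community the cone rows are
#' \code{solve(sigma) \%*\% (s - d) > 0}. A convex polytope; possibly empty
#' (zero volume).
#'
#' @inheritParams capture_domain
#' @param members member indices of the candidate community; defaults to
#'   the full community.
#' @return an \code{hpolytope} (cone rows flagged strict).
#' @export
initialization_domain <- function(net, Q, members = seq_len(net$S)) {
  members <- check_members(net$S, members)
  S <- net$S
  W <- solve(support_basis(net, members))  # n(s) = W (s - d)
  # rows: -W s <= -W d (n >= 0, strict); -s <= 0; N0's <= Q
  A <- rbind(-W, -diag(S), net$N0)
  b <- c(as.numeric(-W %*% net$d), rep(0, S), Q)
  hpolytope(A, b, strict = c(rep(TRUE, S), rep(length(members) > 0, S), FALSE))
}

#' Maturation domain
#'
#' The initialization domain further intersected with the steady-state
#' energy-capture cap \code{s' N*_C(s) <= Q}. Because the biomass map is
#' affine in \code{s}, the cap is one quadratic constraint; under
#' dissipativity the result is a convex body. For the empty community the
#' cap is inactive (\code{N* = 0}) and the maturation domain equals the
#' initialization domain.
#'
#' @inheritParams initialization_domain
#' @return an \code{interpolyquad}.
#' @export
maturation_domain <- function(net, Q, members = seq_len(net$S)) {
  if (!is_dissipative(net))
    stop("maturation domain requires a dissipative network ",
         "(convexity is otherwise unguaranteed)")
  members <- check_members(net$S, members)
  poly <- initialization_domain(net, Q, members)
  if (length(members) == 0) return(interpolyquad(poly, NULL))
  S <- net$S
  W <- solve(support_basis(net, members))
  P <- diag(as.numeric(seq_len(S) %in% members))
  PW <- P %*% W                       # N*_C(s) = PW (s - d)
  M <- (PW + t(PW)) / 2
  v <- as.numeric(-PW %*% net$d)
  interpolyquad(poly, quad_constraint(M, v, Q))
}

#' Chebyshev center of a polytope
#'
#' Solves the standard linear program maximizing the radius of an inscribed
#' ball. A nonpositive radius signals an empty or lower-dimensional body.
#'
#' @param poly an \code{hpolytope}.
#' @return list with \code{center} and \code{radius}.
#' @export
chebyshev_center <- function(poly) {
  A <- poly$A; b <- poly$b
  norms <- sqrt(rowSums(A^2))
  keep <- norms > 0
  Ar <- cbind(A[keep, , drop = FALSE], norms[keep])
  res <- solve_lp(obj = c(rep(0, poly$d), 1), A = Ar, b = b[keep],
                  maximize = TRUE)
  if (res$status == "unbounded" || (res$status == "failed"))
    stop("Chebyshev LP ", res$status,
         " (is a supply-cap constraint missing?)")
  if (res$status == "infeasible")
    return(list(center = rep(NA_real_, poly$d), radius = -Inf))
  list(center = res$x[seq_len(poly$d)], radius = res$x[poly$d + 1])
}

# Largest ball radius around x0 certified inside the quadratic region
# g(x) = x'Mx + v'x - c <= 0 (conservative bound via the gradient norm and
# the largest curvature).
quad_inner_radius <- function(quad, x0) {
  g0 <- sum(x0 * (quad$M %*% x0)) + sum(quad$v * x0) - quad$c
  if (g0 >= 0) return(0)
  gr <- sqrt(sum((2 * (quad$M %*% x0) + quad$v)^2))
  lmax <- max(eigen((quad$M + t(quad$M)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  if (lmax <= 0) lmax <- 0
  # solve lmax r^2 + gr r + g0 <= 0 for the positive root
  if (lmax == 0) return(if (gr > 0) -g0 / gr else Inf)
  (-gr + sqrt(gr^2 - 4 * lmax * g0)) / (2 * lmax)
}

#' Strictly interior point of an InterPolyQuad
#'
#' Starts from the polytope's Chebyshev center; if it violates the
#' quadratic constraint, bisects toward a point satisfying the quadratic
#' (found by minimizing the quadratic form over the polytope with a
#' projected-gradient pass anchored at the constrained minimizer's
#' direction). Returns \code{NULL} for an (effectively) empty body, which
#' callers interpret as zero volume.
#'
#' @param body an \code{interpolyquad}.
#' @param max_bisect bisection budget.
#' @return numeric point or \code{NULL}.
#' @export
interior_point <- function(body, max_bisect = 200) {
  poly <- body$polytope
  if (nrow(poly$A) == 0) {
    if (is.null(body$quad)) stop("unbounded body: no constraints")
    q <- body$quad
    Msym <- (q$M + t(q$M)) / 2
    x <- tryCatch(as.numeric(-solve(Msym, q$v) / 2), error = function(e) NULL)
    if (is.null(x)) stop("degenerate quadratic: singular M with no polytope")
    if (quad_val(q, x) < q$c) return(x) else return(NULL)
  }
  cc <- chebyshev_center(poly)
  if (!is.finite(cc$radius) || cc$radius <= 0) return(NULL)
  x <- cc$center
  if (is.null(body$quad) || quad_val(body$quad, x) < body$quad$c) return(x)
  # find an anchor satisfying the quadratic: LP minimization of the
  # linearized quadratic around the current point, iterated a few times
  anchor <- quad_feasible_anchor(body)
  if (is.null(anchor)) return(NULL)
  lo <- 0; hi <- 1
  for (k in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    p <- (1 - mid) * x + mid * anchor
    if (quad_val(body$quad, p) < body$quad$c &&
        all(poly$A %*% p <= poly$b - 1e-12)) return(p)
    if (quad_val(body$quad, p) >= body$quad$c) lo <- mid else hi <- mid
  }
  p <- 0.99 * anchor + 0.01 * x
  if (quad_val(body$quad, p) < body$quad$c &&
      all(poly$A %*% p <= poly$b)) p else NULL
}

quad_val <- function(quad, x) {
  sum(x * (quad$M %*% x)) + sum(quad$v * x)
}

# A polytope point with small quadratic value: minimize successive linear
# models of the quadratic over the polytope (Frank-Wolfe steps from the
# Chebyshev center). Returns NULL when no polytope point satisfies the
# quadratic within the iteration budget.
quad_feasible_anchor <- function(body, iters = 30) {
  poly <- body$polytope; q <- body$quad
  x <- chebyshev_center(poly)$center
  best <- x; bestval <- quad_val(q, x)
  for (k in seq_len(iters)) {
    g <- as.numeric(2 * (q$M %*% x) + q$v)
    res <- solve_lp(obj = g, A = poly$A, b = poly$b, maximize = FALSE)
    if (res$status != "optimal") break
    # exact line search on the quadratic along x -> vertex
    dirv <- res$x - x
    a2 <- sum(dirv * (q$M %*% dirv))
    b1 <- sum(dirv * (2 * (q$M %*% x) + q$v))
    t <- if (a2 > 0) max(0, min(1, -b1 / (2 * a2))) else
      if (b1 < 0) 1 else 0
    x <- x + t * dirv
    val <- quad_val(q, x)
    if (val < bestval) { best <- x; bestval <- val }
    if (bestval < q$c) break
  }
  if (bestval < q$c) best else NULL
}

#' Whiten an InterPolyQuad
#'
#' Maps the body to coordinates in which the quadratic constraint is a
#' centered Euclidean ball: complete the square, then transform by the
#' Cholesky factor of \code{M} (for the full-community maturation domain,
#' \code{M} is the symmetrized inverse of \code{sigma}). Records the
#' transform and the log-Jacobian so volume estimates can be mapped back:
#' vol(original) = vol(whitened) * exp(-logdet).
#'
#' @param body an \code{interpolyquad} whose quadratic has positive
#'   definite \code{M}.
#' @return a whitened \code{interpolyquad}; the quadratic becomes
#'   \code{{y : y'y <= r^2}}.
#' @export
standardize <- function(body) {
  if (is.null(body$quad)) {
    return(interpolyquad(body$polytope, NULL, trans = diag(body$d),
                         shift = rep(0, body$d), logdet = 0))
  }
  q <- body$quad
  Msym <- (q$M + t(q$M)) / 2
  ev <- eigen(Msym, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev)))
    stop("quadratic matrix not positive definite (eigenvalue ",
         format(min(ev), digits = 4), "); cannot whiten")
  L <- chol(Msym)                        # Msym = t(L) %*% L
  center <- as.numeric(-solve(Msym, q$v) / 2)
  r2 <- q$c + sum(center * (Msym %*% center))
  if (r2 <= 0) r2 <- 0
  # y = L (x - center);  x = center + solve(L, y)
  Linv <- backsolve(L, diag(body$d))
  A2 <- body$polytope$A %*% Linv
  b2 <- body$polytope$b - as.numeric(body$polytope$A %*% center)
  poly2 <- hpolytope(A2, b2, strict = body$polytope$strict)
  quad2 <- quad_constraint(diag(body$d), rep(0, body$d), r2)
  interpolyquad(poly2, quad2, trans = L, shift = center,
                logdet = sum(log(diag(L))))
}
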