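#' Volume estimates
#'
#' Light container for a volume value with its provenance: exact
#' (polytope decomposition or closed form), multiphase Monte Carlo,
#' rejection sampling, or analytic. \code{standard_error} is \code{NA} for
#' exact results.
#'
#' @param value nonnegative volume.
#' @param standard_error standard error (NA for exact methods).
#' @param method one of "exact", "analytic", "multiphase_mc", "rejection".
#' @param sample_count samples used (NA for exact methods).
#' @param note optional diagnostic note (e.g. degeneracy flags).
#' @return an object of class \code{"volume_estimate"}.
#' @export
volume_estimate <- function(value, standard_error = NA_real_,
                            method = "exact", sample_count = NA_integer_,
                            note = NULL) {
  stopifnot(value >= 0)
  structure(list(value = value, standard_error = standard_error,
                 method = method, sample_count = sample_count, note = note),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat("volume ", format(x$value, digits = 6), " (", x$method,
      if (!is.na(x$standard_error))
        paste0(", se ", format(x$standard_error, digits = 3)),
      ")\n", sep = "")
  invisible(x)
}

#' Capture-simplex volume (closed form)
#'
#' vol(D_C) = Q^S / (S! prod_i N0_i), computed in log space.
#'
#' @inheritParams capture_domain
#' @return a \code{volume_estimate} with method "analytic".
#' @export
simplex_volume <- function(net, Q) {
  if (Q <= 0) stop("'Q' must be positive")
  lv <- net$S * log(Q) - lgamma(net$S + 1) - sum(log(net$N0))
  volume_estimate(exp(lv), method = "analytic")
}

# ---- vertex enumeration ---------------------------------------------------

#' Enumerate the vertices of an H-polytope
#'
#' Basis enumeration: solves every d x d subsystem of active rows and keeps
#' the feasible solutions. Intended for low dimension (d <= 8) and modest
#' row counts; redundant rows are permitted.
#'
#' @param poly an \code{hpolytope}.
#' @param tol feasibility tolerance (relative).
#' @return matrix with one vertex per row (0 rows if empty).
#' @export
polytope_vertices <- function(poly, tol = 1e-9) {
  A <- poly$A; b <- poly$b
  d <- ncol(A); m <- nrow(A)
  if (m < d) stop("fewer rows than dimensions: unbounded body")
  if (choose(m, d) > 5e5)
    stop("vertex enumeration budget exceeded (", m, " rows in ", d, "-D)")
  combs <- utils::combn(m, d, simplify = FALSE)
  verts <- vector("list", length(combs))
  nv <- 0L
  for (idx in combs) {
    Asub <- A[idx, , drop = FALSE]
    v <- tryCatch(solve(Asub, b[idx]), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v))) next
    scale <- pmax(1, abs(b)) + abs(A) %*% abs(v)
    if (all(A %*% v - b <= tol * scale)) {
      nv <- nv + 1L
      verts[[nv]] <- as.numeric(v)
    }
  }
  if (nv == 0L) return(matrix(numeric(0), 0, d))
  V <- do.call(rbind, verts[seq_len(nv)])
  # dedupe within tolerance
  vs <- max(1, max(abs(V)))
  key <- apply(round(V / (vs * 1e-7)), 1, paste, collapse = ",")
  V[!duplicated(key), , drop = FALSE]
}

# ---- exact polytope volume ------------------------------------------------

#' Exact volume of a bounded H-polytope
#'
#' Enumerates vertices, then decomposes the volume recursively: the body is
#' the union of cones from an interior point over its facets, and each
#' facet volume is obtained by eliminating one coordinate against the facet
#' equality (with the appropriate metric correction). Empty or
#' lower-dimensional bodies return volume 0.
#'
#' @param poly an \code{hpolytope}.
#' @return a \code{volume_estimate} with method "exact".
#' @export
polytope_volume_exact <- function(poly) {
  d <- poly$d
  V <- polytope_vertices(poly)
  if (nrow(V) < d + 1)
    return(volume_estimate(0, method = "exact",
                           note = "empty or degenerate"))
  if (affine_rank(V) < d)
    return(volume_estimate(0, method = "exact",
                           note = "lower-dimensional body"))
  volume_estimate(vol_decompose(V, poly$A, poly$b), method = "exact")
}

affine_rank <- function(V) {
  if (nrow(V) < 2) return(0L)
  qr(t(V[-1, , drop = FALSE]) - V[1, ])$rank
}

# Recursive facet decomposition. V: vertices (rows), {A x <= b} rows
# describing the same polytope (possibly redundant).
vol_decompose <- function(V, A, b) {
  d <- ncol(A)
  if (d == 1) {
    return(max(V[, 1]) - min(V[, 1]))
  }
  nr <- sqrt(rowSums(A^2))
  keep <- nr > 1e-13
  An <- A[keep, , drop = FALSE] / nr[keep]
  bn <- b[keep] / nr[keep]
  # dedupe parallel duplicate rows
  sig <- apply(round(cbind(An, bn), 9), 1, paste, collapse = ",")
  first <- !duplicated(sig)
  An <- An[first, , drop = FALSE]; bn <- bn[first]
  x0 <- colMeans(V)
  vscale <- max(1, max(abs(V)))
  slack <- matrix(bn, nrow(V), length(bn), byrow = TRUE) - V %*% t(An)
  total <- 0
  for (i in seq_along(bn)) {
    act <- which(abs(slack[, i]) <= 1e-7 * vscale)
    if (length(act) < d) next
    Vf <- V[act, , drop = FALSE]
    if (affine_rank(Vf) != d - 1) next
    h <- bn[i] - sum(An[i, ] * x0)
    if (h <= 1e-12 * vscale) next
    j <- which.max(abs(An[i, ]))
    aij <- An[i, j]
    # substitute x_j = (bn_i - sum_{l != j} a_il x_l) / a_ij into other rows
    Asub <- An[-i, -j, drop = FALSE] -
      outer(An[-i, j], An[i, -j]) / aij
    bsub <- bn[-i] - An[-i, j] * bn[i] / aij
    Vsub <- Vf[, -j, drop = FALSE]
    fvol_sub <- vol_decompose(Vsub, Asub, bsub)
    total <- total + h * (fvol_sub / abs(aij)) / d
  }
  total
}

# ---- uniform sampling helpers --------------------------------------------

#' Uniform samples from the capture simplex
#'
#' Exponential-spacings (Dirichlet) sampling of
#' \code{{s >= 0, s'N0 <= Q}}: exact, i.i.d., O(n S).
#'
#' @inheritParams capture_domain
#' @param n number of samples.
#' @return n x S matrix.
#' @export
sample_capture_simplex <- function(net, Q, n) {
  S <- net$S
  E <- matrix(stats::rexp(n * (S + 1)), n, S + 1)
  Y <- Q * E[, seq_len(S), drop = FALSE] / rowSums(E)
  sweep(Y, 2, net$N0, "/")
}

#' Sampling envelopes for rejection estimates
#'
#' An envelope is an exactly-known region with an i.i.d. uniform sampler:
#' either the capture simplex of a network or an axis-aligned box.
#'
#' @inheritParams capture_domain
#' @return list with \code{sample(n)} and \code{volume}.
#' @export
simplex_envelope <- function(net, Q) {
  list(sample = function(n) sample_capture_simplex(net, Q, n),
       volume = simplex_volume(net, Q)$value)
}

#' @rdname simplex_envelope
#' @param lo,hi box corner vectors.
#' @export
box_envelope <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == length(hi), all(hi > lo))
  d <- length(lo)
  list(sample = function(n) {
    U <- matrix(stats::runif(n * d), n, d)
    sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  },
  volume = prod(hi - lo))
}

#' Rejection-sampling volume (validation oracle)
#'
#' Uniform points in an envelope of known volume; the body volume is the
#' hit fraction times the envelope volume, with a binomial standard error.
#' Feasible only in low dimension; used to validate the exact and
#' multiphase estimators.
#'
#' @param body an \code{hpolytope} or \code{interpolyquad} contained in the
#'   envelope.
#' @param envelope from \code{simplex_envelope()} or \code{box_envelope()}.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return a \code{volume_estimate} with method "rejection".
#' @export
rejection_volume <- function(body, envelope, n = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- envelope$sample(n)
  hits <- sum(body_contains(body, X, tol = 1e-10))
  p <- hits / n
  if (hits == 0)
    return(volume_estimate(0, standard_error = envelope$volume * 3 / n,
                           method = "rejection", sample_count = n,
                           note = "zero hits; one-sided bound"))
  volume_estimate(p * envelope$volume,
                  standard_error = envelope$volume * sqrt(p * (1 - p) / n),
                  method = "rejection", sample_count = n)
}

# ---- hit-and-run + multiphase MC -----------------------------------------

#' Hit-and-Run samples from a convex body
#'
#' Uniform (asymptotically) samples from an \code{interpolyquad} by the
#' Hit-and-Run Markov chain: from the current point, draw a uniform random
#' direction, intersect the line with every linear half-space and with the
#' quadratic constraint (roots of a scalar quadratic), and jump to a
#' uniform point on the feasible chord.
#'
#' @param body an \code{interpolyquad}.
#' @param n retained samples.
#' @param thin chord steps between retained samples (default \code{5 * d},
#'   a mixing heuristic).
#' @param start strictly interior starting point (default
#'   \code{interior_point(body)}).
#' @param seed optional RNG seed.
#' @return n x d matrix of points, all inside the body.
#' @export
hit_and_run <- function(body, n, thin = NULL, start = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- body$d
  if (is.null(thin)) thin <- 5L * d
  if (is.null(start)) start <- interior_point(body)
  if (is.null(start)) stop("body appears empty: no interior point")
  if (!body_contains(body, start, tol = 0))
    stop("'start' is not strictly interior")
  poly <- body$polytope
  hq <- !is.null(body$quad)
  hr_sample_cpp(poly$A, poly$b,
                hq,
                if (hq) body$quad$M else matrix(0, d, d),
                if (hq) body$quad$v else numeric(d),
                if (hq) body$quad$c else 0,
                FALSE, numeric(d), 0,
                as.numeric(start), as.integer(n), as.integer(thin))
}

ball_log_volume <- function(d, r) {
  d / 2 * log(pi) + d * log(r) - lgamma(d / 2 + 1)
}

# Bounding radius of the body around x0: per-coordinate LP box over the
# polytope rows, and/or the enclosing ball of the quadratic region.
covering_radius <- function(body, x0) {
  d <- body$d
  bounds <- Inf
  if (!is.null(body$quad)) {
    q <- body$quad
    Msym <- (q$M + t(q$M)) / 2
    ev <- eigen(Msym, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-12 * max(abs(ev), 1)) {
      center <- as.numeric(-solve(Msym, q$v) / 2)
      r2 <- q$c + sum(center * (Msym %*% center))
      if (r2 > 0)
        bounds <- sqrt(sum((x0 - center)^2)) + sqrt(r2 / min(ev))
      else bounds <- 0
    }
  }
  if (nrow(body$polytope$A) >= d + 1) {
    lo <- hi <- rep(NA_real_, d)
    for (j in seq_len(d)) {
      ej <- numeric(d); ej[j] <- 1
      rlo <- solve_lp(ej, body$polytope$A, body$polytope$b, maximize = FALSE)
      rhi <- solve_lp(ej, body$polytope$A, body$polytope$b, maximize = TRUE)
      if (rlo$status == "optimal") lo[j] <- rlo$value
      if (rhi$status == "optimal") hi[j] <- rhi$value
    }
    if (!anyNA(lo) && !anyNA(hi)) {
      corner <- pmax(abs(lo - x0), abs(hi - x0))
      # small inflation: the box extremes come from a regularized LP
      bounds <- min(bounds, 1.02 * sqrt(sum(corner^2)) + 1e-9)
    }
  }
  if (!is.finite(bounds))
    stop("cannot bound the body: unbounded polytope and indefinite quadratic")
  bounds
}

standardize_or_identity <- function(body) {
  out <- tryCatch(standardize(body), error = function(e) NULL)
  if (!is.null(out)) return(out)
  interpolyquad(body$polytope, body$quad, trans = diag(body$d),
                shift = rep(0, body$d), logdet = 0)
}

#' Multiphase Monte Carlo volume
#'
#' Telescoping-ratio volume estimation for an \code{interpolyquad}: after
#' whitening (when the quadratic is positive definite), intersect the body
#' K with balls of radius \code{r_i = r0 * 2^(i/d)} around an interior
#' point, anchored at a ball fully inside K and ending at a ball covering
#' K. Each ratio vol(K_i)/vol(K_{i+1}) is estimated by Hit-and-Run samples
#' of the larger intersection counted against the smaller ball, and the
#' volume is the anchor-ball volume times the product of inverse ratios,
#' with a delta-method standard error.
#'
#' @param body an \code{interpolyquad}.
#' @param samples_per_phase Hit-and-Run samples retained per phase.
#' @param thin chord steps between retained samples (default \code{5 * d}).
#' @param seed optional RNG seed.
#' @param anchor_shrink safety factor (< 1) applied to the inscribed radius
#'   for the anchor ball, keeping the chain strictly interior.
#' @return a \code{volume_estimate} with method "multiphase_mc".
#' @export
multiphase_volume <- function(body, samples_per_phase = 2e4, thin = NULL,
                              seed = NULL, anchor_shrink = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  d <- body$d
  if (is.null(thin)) thin <- 5L * d
  logdet0 <- if (is.null(body$logdet)) 0 else body$logdet
  wb <- standardize_or_identity(body)
  wb$logdet <- wb$logdet + logdet0
  x0 <- interior_point(wb)
  if (is.null(x0))
    return(volume_estimate(0, standard_error = 0, method = "multiphase_mc",
                           sample_count = 0L, note = "empty body"))
  poly <- wb$polytope
  r_in <- Inf
  if (nrow(poly$A) > 0) {
    nr <- sqrt(rowSums(poly$A^2))
    keep <- nr > 0
    r_in <- min((poly$b[keep] - as.numeric(poly$A[keep, , drop = FALSE]
                                           %*% x0)) / nr[keep])
  }
  if (!is.null(wb$quad))
    r_in <- min(r_in, quad_inner_radius(wb$quad, x0))
  if (!is.finite(r_in) || r_in <= 0)
    return(volume_estimate(0, standard_error = 0, method = "multiphase_mc",
                           sample_count = 0L,
                           note = "degenerate body (no inscribed ball)"))
  r0 <- anchor_shrink * r_in
  R <- covering_radius(wb, x0)
  k <- max(1L, ceiling(d * log2(R / r0)))
  radii <- r0 * 2^(seq_len(k) / d)
  radii[k] <- max(radii[k], R)
  hq <- !is.null(wb$quad)
  Mq <- if (hq) wb$quad$M else matrix(0, d, d)
  vq <- if (hq) wb$quad$v else numeric(d)
  cq <- if (hq) wb$quad$c else 0
  logvol <- ball_log_volume(d, r0)
  relvar <- 0
  start <- x0
  for (i in seq_len(k)) {
    X <- hr_sample_cpp(poly$A, poly$b, hq, Mq, vq, cq,
                       TRUE, x0, radii[i],
                       as.numeric(start), as.integer(samples_per_phase),
                       as.integer(thin))
    r_small <- if (i == 1) r0 else radii[i - 1]
    inside <- rowSums(sweep(X, 2, x0)^2) <= r_small^2
    f <- mean(inside)
    if (f == 0)
      stop("multiphase phase ", i, " ratio estimated as 0; ",
           "increase samples_per_phase")
    logvol <- logvol - log(f)
    relvar <- relvar + (1 - f) / (f * samples_per_phase)
    # warm start next phase from a retained point (inside the next ball too)
    start <- X[nrow(X), ]
  }
  value <- exp(logvol - wb$logdet)
  volume_estimate(value, standard_error = value * sqrt(relvar),
                  method = "multiphase_mc",
                  sample_count = as.integer(k * samples_per_phase))
}

# ---- exact 2-D quadrature path -------------------------------------------

# Area of (convex polygon) intersect (disk of radius r centered at the
# origin). Vertices need not be ordered; they are sorted CCW around the
# centroid. Standard edge-wise decomposition into triangles and circular
# sectors.
convex_polygon_disk_area <- function(V, r) {
  if (nrow(V) < 3) return(0)
  ctr <- colMeans(V)
  ord <- order(atan2(V[, 2] - ctr[2], V[, 1] - ctr[1]))
  V <- V[ord, , drop = FALSE]
  n <- nrow(V)
  total <- 0
  for (i in seq_len(n)) {
    p1 <- V[i, ]; p2 <- V[if (i == n) 1 else i + 1, ]
    total <- total + edge_disk_contrib(p1, p2, r)
  }
  abs(total)
}

sector_area <- function(p1, p2, r) {
  ang <- atan2(p1[1] * p2[2] - p1[2] * p2[1], sum(p1 * p2))
  r^2 / 2 * ang
}

edge_disk_contrib <- function(p1, p2, r) {
  in1 <- sum(p1^2) <= r^2
  in2 <- sum(p2^2) <= r^2
  tri <- function(a, b) (a[1] * b[2] - a[2] * b[1]) / 2
  if (in1 && in2) return(tri(p1, p2))
  dp <- p2 - p1
  a <- sum(dp^2)
  b <- 2 * sum(p1 * dp)
  cc <- sum(p1^2) - r^2
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(sector_area(p1, p2, r))
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  q1 <- p1 + t1 * dp
  q2 <- p1 + t2 * dp
  if (in1 && !in2) {
    # exits at t2
    return(tri(p1, q2) + sector_area(q2, p2, r))
  }
  if (!in1 && in2) {
    return(sector_area(p1, q1, r) + tri(q1, p2))
  }
  # both outside: chord crosses iff 0 < t1 < t2 < 1
  if (t1 > 0 && t2 < 1 && t2 > t1) {
    return(sector_area(p1, q1, r) + tri(q1, q2) + sector_area(q2, p2, r))
  }
  sector_area(p1, p2, r)
}

# Exact area of a 2-D interpolyquad via whitening + polygon/disk clipping.
# Returns NA if the body is not 2-dimensional.
ipq_area_2d <- function(body) {
  if (body$d != 2) return(NA_real_)
  if (is.null(body$quad)) {
    return(polytope_volume_exact(body$polytope)$value)
  }
  wb <- standardize_or_identity(body)
  if (is.null(wb$trans)) return(NA_real_)
  r2 <- wb$quad$c
  if (r2 <= 0) return(0)
  V <- polytope_vertices(wb$polytope)
  if (nrow(V) < 3) return(0)
  convex_polygon_disk_area(V, sqrt(r2)) * exp(-wb$logdet)
}
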