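#' Full-community steady state
#'
#' Solves \code{sigma N* = s - d} for the interior equilibrium biomass of
#' the full community. No positivity is imposed: a negative component
#' simply means the full community is infeasible at that capture vector.
#'
#' @param net an \code{energetic_network}.
#' @param s length-S capture-rate vector (power mass^-1), all \code{s_i >= 0}.
#' @return length-S numeric vector \code{N*}.
#' @export
steady_state <- function(net, s) {
  s <- check_capture(net, s)
  kappa <- kappa(net$sigma, exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("'sigma' is numerically singular (condition number ",
         format(kappa, digits = 3), ")")
  as.numeric(solve(net$sigma, s - net$d))
}

check_capture <- function(net, s) {
  s <- as.numeric(s)
  if (length(s) != net$S) stop("'s' must have length ", net$S)
  if (any(!is.finite(s))) stop("'s' must be finite")
  if (any(s < 0)) stop("capture rates must be nonnegative")
  s
}

# Columns of the boundary-equilibrium linear map for support C:
# sigma_i for members, -e_i for non-members, so that
# s - d = B_C %*% n with n > 0 on the partition cell of C.
support_basis <- function(net, members) {
  S <- net$S
  B <- -diag(S)
  if (length(members)) B[, members] <- net$sigma[, members]
  B
}

#' Boundary equilibrium on a candidate community
#'
#' For a candidate community \code{C} (a subset of populations), the
#' boundary equilibrium solves the complementarity condition
#' \code{s - d = sum_{i in C} n_i sigma_i - sum_{i not in C} n_i e_i},
#' where \code{sigma_i} is the i-th column of \code{sigma} and \code{e_i}
#' the i-th unit vector. Members' multipliers \code{n_i} are their
#' equilibrium biomasses; non-members' multipliers are the slack of their
#' invasion condition. The equilibrium is admissible iff all \code{n_i > 0}.
#'
#' @inheritParams steady_state
#' @param members integer vector of member indices (1-based); may be empty.
#' @return list with \code{n} (all S multipliers), \code{N} (biomass:
#'   \code{n_i} for members, 0 elsewhere), \code{members}.
#' @export
boundary_equilibrium <- function(net, s, members) {
  s <- check_capture(net, s)
  members <- check_members(net$S, members)
  B <- support_basis(net, members)
  n <- tryCatch(as.numeric(solve(B, s - net$d)),
                error = function(e)
                  stop("degenerate support {", paste(members, collapse = ","),
                       "}: singular column system"))
  N <- numeric(net$S)
  N[members] <- n[members]
  list(n = n, N = N, members = members)
}

check_members <- function(S, members) {
  if (length(members) == 0) return(integer(0))
  members <- sort(unique(as.integer(members)))
  if (any(members < 1L) || any(members > S))
    stop("community members must be indices in 1..", S)
  members
}

#' Classify a capture vector by its stable support
#'
#' Under dissipativity every capture vector \code{s} has a unique globally
#' stable equilibrium, supported on the unique candidate community whose
#' boundary-equilibrium multipliers are all strictly positive. Supports are
#' enumerated in decreasing cardinality with early exit (at most 2^S
#' linear solves, S <= 12).
#'
#' @inheritParams steady_state
#' @param tol relative tolerance for "strictly positive" multipliers
#'   (relative to the max-norm of the multiplier vector). A multiplier
#'   within \code{tol} of zero raises a boundary-tie error rather than
#'   guessing.
#' @return integer vector of member indices (possibly empty).
#' @export
classify_support <- function(net, s, tol = 1e-9) {
  s <- check_capture(net, s)
  if (net$S > 12) stop("support enumeration limited to S <= 12")
  cands <- communities(net$S)
  cands <- cands[order(-vapply(cands, length, 1L))]
  near_tie <- NULL
  for (members in cands) {
    n <- tryCatch(solve(support_basis(net, members), s - net$d),
                  error = function(e) NULL)
    if (is.null(n)) next
    thr <- tol * max(abs(n), 1e-300)
    if (all(n > thr)) return(members)
    if (all(n > -thr)) near_tie <- list(members = members, n = n)
  }
  if (!is.null(near_tie))
    stop("boundary tie: support {",
         paste(near_tie$members, collapse = ","),
         "} has a multiplier within tolerance of zero (",
         format(min(near_tie$n), digits = 3), ")")
  stop("no support with all-positive multipliers found; ",
       "is the network dissipative?")
}

#' Enumerate candidate communities
#'
#' All \code{2^S} subsets of \code{{1..S}} in a deterministic size-major
#' (then lexicographic) order, the empty community first.
#'
#' @param S number of populations, 1 <= S <= 12.
#' @return list of integer vectors.
#' @examples
#' length(communities(6))  # 64; 63 nonempty
#' @export
communities <- function(S) {
  S <- as.integer(S)
  if (S < 1L || S > 12L) stop("S must be in 1..12 (combinatorial budget)")
  out <- list(integer(0))
  for (D in seq_len(S)) {
    combos <- utils::combn(S, D, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}
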