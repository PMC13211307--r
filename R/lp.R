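# Internal LP wrapper: minimize obj'x subject to A x <= b, x free.
#
# Solved as a ridge-regularized QP through quadprog's dual (Goldfarb-
# Idnani) method: minimize (eps/2)||x||^2 + obj'x. The regularizer makes
# the problem strictly convex (so degenerate and even unbounded LPs are
# well-posed) while perturbing the optimal value by only O(eps ||x*||^2).
# eps is escalated a few times if the solver's Cholesky factor breaks
# down. Infeasibility is reported via status.
solve_lp <- function(obj, A, b, maximize = FALSE) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == nrow(A))
  if (maximize) obj <- -obj
  # normalize constraint rows for conditioning
  nr <- sqrt(rowSums(A^2))
  keep <- nr > 1e-300
  An <- A[keep, , drop = FALSE] / nr[keep]
  bn <- b[keep] / nr[keep]
  cscale <- max(abs(obj), 1)
  for (eps in cscale * c(1e-9, 1e-7, 1e-5)) {
    res <- tryCatch(
      quadprog::solve.QP(Dmat = diag(eps, n), dvec = -obj,
                         Amat = t(-An), bvec = -bn),
      error = function(e) conditionMessage(e))
    if (!is.character(res)) {
      x <- res$solution
      val <- sum(obj * x)
      return(list(x = x, value = if (maximize) -val else val,
                  status = "optimal"))
    }
    if (grepl("inconsistent", res, fixed = TRUE))
      return(list(x = rep(NA_real_, n), value = NA_real_,
                  status = "infeasible"))
  }
  list(x = rep(NA_real_, n), value = NA_real_, status = "failed")
}
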