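#' Logit-space functional data analysis of probability curves
#'
#' Aggregates replicate probability curves: each curve is linearly
#' interpolated in (log Q, p) onto a common logarithmically spaced grid,
#' probabilities are clamped to \code{[epsilon, 1 - epsilon]}, mapped
#' through the logit, and summarized by the pointwise mean and standard
#' deviation (n - 1 denominator) across curves. The central trend and the
#' one-standard-deviation band are mapped back by the inverse logit, which
#' keeps them inside (0, 1) with asymmetric uncertainty near the
#' boundaries.
#'
#' @param curves list of data frames, each with columns \code{Q} and
#'   \code{p} (or a \code{probability_curve} plus \code{value} naming the
#'   probability column).
#' @param value name of the probability column, default \code{"p"};
#'   \code{"p_init"}/\code{"p_mat"} for \code{probability_curve}s.
#' @param n_grid number of common grid points (log-spaced).
#' @param grid optional explicit common Q grid (must be covered by every
#'   curve; extrapolation is refused).
#' @param epsilon clamp width, default 1e-3.
#' @return data frame of class \code{"fda_summary"} with columns \code{Q},
#'   \code{p_bar}, \code{p_lo}, \code{p_hi}, \code{mu_logit},
#'   \code{sd_logit}.
#' @export
fda_aggregate <- function(curves, value = "p", n_grid = 200, grid = NULL,
                          epsilon = 1e-3) {
  if (length(curves) < 2)
    stop("need at least 2 curves for a pointwise standard deviation")
  getQ <- function(cv) cv$Q
  getP <- function(cv) cv[[value]]
  if (is.null(grid)) {
    lo <- max(vapply(curves, function(cv) min(getQ(cv)), 0))
    hi <- min(vapply(curves, function(cv) max(getQ(cv)), 0))
    if (hi <= lo) stop("curves have no common Q range")
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  }
  lam <- matrix(NA_real_, length(curves), length(grid))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    q <- getQ(cv); p <- getP(cv)
    if (is.null(p)) stop("curve ", i, " has no column '", value, "'")
    if (min(grid) < min(q) - 1e-9 * min(q) ||
        max(grid) > max(q) + 1e-9 * max(q))
      stop("curve ", i, " does not cover the common grid; ",
           "extrapolation refused")
    pi_ <- stats::approx(log(q), p, xout = log(grid), rule = 1)$y
    pi_ <- pmin(pmax(pi_, epsilon), 1 - epsilon)
    lam[i, ] <- log(pi_ / (1 - pi_))
  }
  mu <- colMeans(lam)
  sdv <- apply(lam, 2, stats::sd)
  inv <- function(z) 1 / (1 + exp(-z))
  structure(data.frame(Q = grid, p_bar = inv(mu), p_lo = inv(mu - sdv),
                       p_hi = inv(mu + sdv), mu_logit = mu, sd_logit = sdv),
            epsilon = epsilon, n_curves = length(curves),
            class = c("fda_summary", "data.frame"))
}

#' @export
plot.fda_summary <- function(x, ...) {
  graphics::plot(x$Q, x$p_bar, type = "n", log = "x", ylim = c(0, 1),
                 xlab = "total energy supply Q", ylab = "probability", ...)
  graphics::polygon(c(x$Q, rev(x$Q)), c(x$p_lo, rev(x$p_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$Q, x$p_bar, col = "steelblue")
  invisible(x)
}

#' Aggregate diversity curves on the original scale
#'
#' Diversity curves are averaged pointwise (arithmetic mean after
#' interpolation onto the common log-spaced grid); no logit transform.
#'
#' @param curves list of data frames with columns \code{Q} and \code{D}.
#' @param n_grid,grid as in \code{\link{fda_aggregate}}.
#' @return data frame with columns \code{Q}, \code{D_bar}.
#' @export
diversity_aggregate <- function(curves, n_grid = 200, grid = NULL) {
  if (length(curves) < 1) stop("need at least one curve")
  if (is.null(grid)) {
    lo <- max(vapply(curves, function(cv) min(cv$Q), 0))
    hi <- min(vapply(curves, function(cv) max(cv$Q), 0))
    if (hi <= lo) stop("curves have no common Q range")
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  }
  vals <- vapply(curves, function(cv) {
    if (min(grid) < min(cv$Q) - 1e-9 * min(cv$Q) ||
        max(grid) > max(cv$Q) + 1e-9 * max(cv$Q))
      stop("a curve does not cover the common grid; extrapolation refused")
    stats::approx(log(cv$Q), cv$D, xout = log(grid), rule = 1)$y
  }, numeric(length(grid)))
  data.frame(Q = grid, D_bar = rowMeans(as.matrix(vals)))
}

#' Shape scores for probability curves
#'
#' Package-defined summary scores (not taken from any published formula)
#' quantifying how saturating-monotone or unimodal a curve is:
#' \itemize{
#'   \item saturation score: Spearman rank correlation of p with Q times
#'     \code{(1 - normalized terminal slope)}, where the terminal slope is
#'     the average |dp/dlogQ| over the last fifth of the grid divided by
#'     the maximum |dp/dlogQ| anywhere. Near 1 for curves that rise then
#'     flatten; <= 0 for decreasing curves.
#'   \item unimodality score: \code{1 - RSS(best rise-then-fall isotonic
#'     fit) / RSS(best monotone isotonic fit)}, in [0, 1]. Near 1 for
#'     clearly single-peaked non-monotone curves, 0 for monotone ones.
#' }
#' A constant curve returns both scores 0 with a degeneracy flag.
#'
#' @param Q supply grid (increasing), length >= 5.
#' @param p probabilities on the grid.
#' @return list with \code{saturation}, \code{unimodality},
#'   \code{degenerate}.
#' @export
shape_scores <- function(Q, p) {
  stopifnot(length(Q) == length(p), length(Q) >= 5)
  if (stats::sd(p) == 0)
    return(list(saturation = 0, unimodality = 0, degenerate = TRUE))
  rho <- suppressWarnings(
    stats::cor(p, Q, method = "spearman"))
  x <- log(Q)
  slopes <- diff(p) / diff(x)
  tail_idx <- seq(ceiling(0.8 * length(slopes)), length(slopes))
  smax <- max(abs(slopes))
  term <- if (smax == 0) 0 else
    min(1, mean(abs(slopes[tail_idx])) / smax)
  saturation <- rho * (1 - term)

  rss_up <- isotonic_rss(p, decreasing = FALSE)
  rss_dn <- isotonic_rss(p, decreasing = TRUE)
  rss_mono <- min(rss_up, rss_dn)
  n <- length(p)
  rss_uni <- min(vapply(seq_len(n), function(k) {
    left <- if (k > 1) isotonic_rss(p[1:k], FALSE) else 0
    right <- if (k < n) isotonic_rss(p[k:n], TRUE) else 0
    left + right
  }, 0))
  unimodality <- if (rss_mono <= 0) 0 else 1 - rss_uni / rss_mono
  list(saturation = saturation, unimodality = unimodality,
       degenerate = FALSE)
}

isotonic_rss <- function(p, decreasing) {
  if (length(p) < 2) return(0)
  y <- if (decreasing) rev(p) else p
  fit <- stats::isoreg(y)
  sum((fit$yf - y)^2)
}
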