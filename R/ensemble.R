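#' Configuration for the constrained random-network generator
#'
#' Hyperparameters of the random ensemble: network size \code{S}, overall
#' exchange scale \code{s_sigma}, dissipativity floor \code{sigma_0} (the
#' minimum eigenvalue imposed on the symmetric part before scaling),
#' centers \code{N_0} and \code{d_0} of the minimal-biomass and demand
#' draws, connectance, replicate count and seed. Defaults are the study
#' conditions: \code{s_sigma = 1}, \code{sigma_0 = 0.5}, \code{N_0 = 1},
#' \code{d_0 = 1}, full connectance.
#'
#' @param S network size.
#' @param s_sigma positive scale applied to the whole exchange matrix.
#' @param sigma_0 positive dissipativity floor.
#' @param N_0,d_0 positive centers of the N0 and d draws.
#' @param sd_frac standard deviation of the N0 and d draws, as a fraction
#'   of their centers (draws are resampled until positive).
#' @param connectance probability in (0, 1] that an off-diagonal pair is
#'   retained (pairs are masked together).
#' @param replicates number of networks.
#' @param seed integer RNG seed.
#' @return list of class \code{"generator_config"}.
#' @export
generator_config <- function(S, s_sigma = 1.0, sigma_0 = 0.5, N_0 = 1.0,
                             d_0 = 1.0, sd_frac = 0.25, connectance = 1.0,
                             replicates = 1L, seed = 1L) {
  stopifnot(S >= 1, s_sigma > 0, sigma_0 > 0, N_0 > 0, d_0 > 0,
            sd_frac >= 0, connectance > 0, connectance <= 1,
            replicates >= 1)
  structure(list(S = as.integer(S), s_sigma = s_sigma, sigma_0 = sigma_0,
                 N_0 = N_0, d_0 = d_0, sd_frac = sd_frac,
                 connectance = connectance,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "generator_config")
}

rnorm_positive <- function(n, center, sd) {
  if (sd == 0) return(rep(center, n))
  out <- stats::rnorm(n, center, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), center, sd)
  }
  out
}

# Efficiency rule: for opposite-sign pairs, energy transfer efficiency at
# most 1, i.e. |sigma_ij| <= |sigma_ji| whenever sigma_ij < 0 < sigma_ji.
# Violating pairs have their absolute values swapped (signs kept).
apply_efficiency <- function(sigma) {
  S <- nrow(sigma)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      a <- sigma[i, j]; b <- sigma[j, i]
      if (a < 0 && b > 0 && abs(a) > abs(b)) {
        sigma[i, j] <- -abs(b); sigma[j, i] <- abs(a)
      } else if (b < 0 && a > 0 && abs(b) > abs(a)) {
        sigma[j, i] <- -abs(a); sigma[i, j] <- abs(b)
      }
    }
  }
  sigma
}

# Diagonal shift making the minimum eigenvalue of the symmetric part
# exactly sigma_0.
apply_dissipativity_floor <- function(sigma, sigma_0) {
  lmin <- min(eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  sigma + diag(sigma_0 - lmin, nrow(sigma))
}

#' Generate one constrained random network
#'
#' Four-step procedure: (1) sample every \code{sigma_ij} from
#' Normal(0, 1); (2) enforce the transfer-efficiency rule by swapping
#' absolute values of violating opposite-sign pairs; (3) shift the
#' diagonal so the minimum eigenvalue of the symmetric part equals
#' \code{sigma_0}; (4) scale the whole matrix by \code{s_sigma}. Demands
#' and minimal biomasses are normal draws centered at \code{d_0} and
#' \code{N_0} (sd \code{sd_frac} x center), resampled until positive.
#' Off-diagonal pairs are masked (both directions together) with
#' probability \code{1 - connectance} before the efficiency step. The step
#' order is normative: flooring before scaling makes the realized
#' eigenvalue floor \code{sigma_0 * s_sigma}.
#'
#' @param config a \code{generator_config}.
#' @param id optional label for the network.
#' @return an \code{energetic_network}, guaranteed dissipative.
#' @export
generate_network <- function(config, id = NULL) {
  S <- config$S
  sigma <- matrix(stats::rnorm(S * S), S, S)
  if (config$connectance < 1 && S > 1) {
    for (i in seq_len(S - 1)) {
      for (j in (i + 1):S) {
        if (stats::runif(1) > config$connectance) {
          sigma[i, j] <- 0; sigma[j, i] <- 0
        }
      }
    }
  }
  sigma <- apply_efficiency(sigma)
  sigma <- apply_dissipativity_floor(sigma, config$sigma_0)
  sigma <- sigma * config$s_sigma
  d <- rnorm_positive(S, config$d_0, config$sd_frac * config$d_0)
  N0 <- rnorm_positive(S, config$N_0, config$sd_frac * config$N_0)
  energetic_network(sigma, d, N0, id = id)
}

#' Generate a reproducible ensemble of networks
#'
#' Draws one child seed per replicate from the configured seed, so any
#' replicate can be regenerated bit-exactly. The manifest (attribute
#' \code{"manifest"}) records the config and per-replicate seeds.
#'
#' @param config a \code{generator_config}.
#' @return list of \code{energetic_network}s with a manifest attribute.
#' @export
generate_ensemble <- function(config) {
  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max, config$replicates)
  nets <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(child[r])
    nets[[r]] <- generate_network(config, id = paste0("rep", r))
  }
  attr(nets, "manifest") <- list(config = unclass(config),
                                 child_seeds = child)
  nets
}

#' Down-sample a network to fewer populations
#'
#' Keeps the leading principal submatrix of \code{sigma} and the leading
#' entries of \code{d} and \code{N0}. The dissipativity floor is
#' re-applied to the submatrix whenever the sub-network's minimum
#' symmetric-part eigenvalue falls below it, so every analyzed network
#' satisfies the dissipativity precondition.
#'
#' @param net an \code{energetic_network}.
#' @param S_new new (smaller) size.
#' @param sigma_0 dissipativity floor to re-impose; use
#'   \code{sigma_0 * s_sigma} from the generating config.
#' @return an \code{energetic_network} of size \code{S_new}.
#' @export
downsample_network <- function(net, S_new, sigma_0 = 0.5) {
  S_new <- as.integer(S_new)
  stopifnot(S_new >= 1, S_new <= net$S)
  idx <- seq_len(S_new)
  sigma <- net$sigma[idx, idx, drop = FALSE]
  lmin <- min(eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  if (lmin < sigma_0)
    sigma <- sigma + diag(sigma_0 - lmin, S_new)
  energetic_network(sigma, net$d[idx], net$N0[idx], net$mu[idx],
                    id = if (is.na(net$id)) NULL
                         else paste0(net$id, "-S", S_new))
}
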