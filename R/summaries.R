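#' Exceedance probability of a relative risk
#'
#' Fraction of posterior draws strictly greater than the threshold; used to
#' flag areal units with significantly elevated risk (probability at or above
#' 0.90 at threshold 1).
#'
#' @param theta_draws numeric vector of posterior relative-risk draws.
#' @param threshold relative-risk threshold (default 1).
#' @return scalar in `[0, 1]`.
#' @export
exceedance_probability <- function(theta_draws, threshold = 1.0) {
  stopifnot(length(theta_draws) >= 1)
  mean(theta_draws > threshold)
}

# per-draw log relative risks for outlet type k: (draws*chains) x n
log_theta_draws <- function(draws, k) {
  beta <- combine_chains(draws$beta)[, k]
  alpha <- combine_chains(draws$alpha)[, k]
  w <- combine_chains(draws$w)
  u <- combine_chains(draws$u)
  v <- combine_chains(draws$v)
  s <- chain_slice(combine_chains(draws$s), k)
  ndi <- w %*% t(draws$q)           # draws x n
  alpha + beta * ndi + u + v + s
}

# k-th slice of a draws x units x types array, kept as a matrix
chain_slice <- function(a, k) {
  out <- a[, , k, drop = FALSE]
  dim(out) <- dim(a)[1:2]
  out
}

#' Summarize relative risks, shared and outlet-specific components
#'
#' Computes per-draw relative risks `theta_ik = exp(alpha_k + beta_k NDI_i +
#' u_i + v_i + s_ik)` and reports posterior medians, equal-tailed 95%
#' intervals, exceedance probabilities and elevation flags
#' (`exceedance >= prob_threshold`), along with summaries of the total shared
#' component `exp(u_i + v_i)` and the outlet-specific components
#' `exp(s_ik)`.
#'
#' @param draws an `ndi_draws` object from [fit_shared_car].
#' @param rr_threshold relative-risk threshold for exceedance (default 1).
#' @param prob_threshold exceedance probability at or above which a unit is
#'   flagged elevated (default 0.90).
#' @return list of class `ndi_rr` with data frames `rr` (unit x type rows:
#'   `rr_median`, `rr_lo`, `rr_hi`, `exceedance_prob`, `elevated`), `shared`
#'   (per unit) and `specific` (unit x type).
#' @export
summarize_rr <- function(draws, rr_threshold = 1.0, prob_threshold = 0.90) {
  stopifnot(inherits(draws, "ndi_draws"))
  n <- length(draws$unit_ids); K <- dim(draws$beta)[2]
  qtl <- function(m) t(apply(m, 2, quantile, probs = c(0.5, 0.025, 0.975),
                             names = FALSE))
  rr <- do.call(rbind, lapply(seq_len(K), function(k) {
    th <- exp(log_theta_draws(draws, k))
    qs <- qtl(th)
    ex <- colMeans(th > rr_threshold)
    data.frame(block_group_id = draws$unit_ids,
               outlet_type = outlet_types()[k],
               rr_median = qs[, 1], rr_lo = qs[, 2], rr_hi = qs[, 3],
               exceedance_prob = ex, elevated = ex >= prob_threshold,
               row.names = NULL)
  }))
  shared_draws <- exp(combine_chains(draws$u) + combine_chains(draws$v))
  qs <- qtl(shared_draws)
  shared <- data.frame(block_group_id = draws$unit_ids,
                       shared_median = qs[, 1], shared_lo = qs[, 2],
                       shared_hi = qs[, 3], row.names = NULL)
  specific <- do.call(rbind, lapply(seq_len(K), function(k) {
    sd_k <- exp(chain_slice(combine_chains(draws$s), k))
    qs <- qtl(sd_k)
    data.frame(block_group_id = draws$unit_ids,
               outlet_type = outlet_types()[k],
               specific_median = qs[, 1], specific_lo = qs[, 2],
               specific_hi = qs[, 3], row.names = NULL)
  }))
  structure(list(rr = rr, shared = shared, specific = specific,
                 rr_threshold = rr_threshold,
                 prob_threshold = prob_threshold),
            class = "ndi_rr")
}

#' Disadvantage-index effect sizes per outlet type
#'
#' Reports `exp(beta_k)` — the relative risk per one-decile increase of the
#' disadvantage index — as posterior median with equal-tailed 95% interval,
#' plus the posterior probabilities of each pairwise effect ordering.
#'
#' @param draws an `ndi_draws` object.
#' @return list with data frame `effects` (`outlet_type`, `rr_median`,
#'   `rr_lo`, `rr_hi`) and matrix `prob_greater` where entry `[j, k]` is
#'   `Pr(beta_j > beta_k)`.
#' @export
ndi_effect_rr <- function(draws) {
  stopifnot(inherits(draws, "ndi_draws"))
  beta <- combine_chains(draws$beta)
  rr <- exp(beta)
  qs <- t(apply(rr, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  K <- ncol(beta)
  pg <- matrix(NA_real_, K, K, dimnames = list(outlet_types()[1:K],
                                               outlet_types()[1:K]))
  for (j in 1:K) for (k in 1:K) if (j != k)
    pg[j, k] <- mean(beta[, j] > beta[, k])
  list(effects = data.frame(outlet_type = outlet_types()[1:K],
                            rr_median = qs[, 1], rr_lo = qs[, 2],
                            rr_hi = qs[, 3], row.names = NULL),
       prob_greater = pg)
}

#' Summaries of the disadvantage index and its weights
#'
#' Per-unit posterior median and 95% interval of the index `sum_j w_j q_ij`,
#' and per-covariate weight summaries. Reported weight medians are
#' additionally renormalized to sum to 1 (flagged in the output), since
#' medians of simplex draws need not lie on the simplex.
#'
#' @param draws an `ndi_draws` object.
#' @return list with data frames `ndi` (per unit) and `weights` (per
#'   covariate: `weight_median`, `weight_lo`, `weight_hi`,
#'   `weight_median_renorm`) and flag `renormalized = TRUE`.
#' @export
ndi_summary <- function(draws) {
  stopifnot(inherits(draws, "ndi_draws"))
  w <- combine_chains(draws$w)
  ndi_draws_mat <- w %*% t(draws$q)
  qs <- t(apply(ndi_draws_mat, 2, quantile, probs = c(0.5, 0.025, 0.975),
                names = FALSE))
  ndi <- data.frame(block_group_id = draws$unit_ids,
                    ndi_median = qs[, 1], ndi_lo = qs[, 2], ndi_hi = qs[, 3],
                    row.names = NULL)
  wq <- t(apply(w, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  weights <- data.frame(
    covariate = draws$covariates %||% paste0("x", seq_len(ncol(w))),
    weight_median = wq[, 1], weight_lo = wq[, 2], weight_hi = wq[, 3],
    weight_median_renorm = wq[, 1] / sum(wq[, 1]), row.names = NULL)
  list(ndi = ndi, weights = weights, renormalized = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative-risk summaries by population density category
#'
#' Arithmetic mean of posterior-median relative risks and the fraction of
#' units flagged as significantly elevated, per density category (rural,
#' suburban, urban) and outlet type. Empty categories are reported as
#' missing, not zero.
#'
#' @param rr an `ndi_rr` object from [summarize_rr].
#' @param records block-group data frame with `block_group_id`, `population`
#'   and `area` (used to classify density).
#' @return data frame with columns `density`, `outlet_type`, `mean_rr`,
#'   `pct_significant`, `n_units`.
#' @export
density_table <- function(rr, records) {
  stopifnot(inherits(rr, "ndi_rr"))
  density <- population_density_category(records$population, records$area)
  lut <- setNames(as.character(density), records$block_group_id)
  tab <- rr$rr
  tab$density <- factor(lut[tab$block_group_id],
                        levels = c("rural", "suburban", "urban"))
  out <- expand.grid(density = levels(tab$density),
                     outlet_type = outlet_types(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_rr <- NA_real_
  out$pct_significant <- NA_real_
  out$n_units <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- tab$density == out$density[r] & tab$outlet_type == out$outlet_type[r]
    out$n_units[r] <- sum(sel)
    if (any(sel)) {
      out$mean_rr[r] <- mean(tab$rr_median[sel])
      out$pct_significant[r] <- mean(tab$elevated[sel])
    }
  }
  out
}
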