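#' Filter areal units prior to modelling
#'
#' Drops block groups with zero population, then block groups with any
#' missing sociodemographic covariate, recording how many (and which) units
#' each rule removed. Zero-population units have undefined expected counts;
#' units with missing covariates cannot be decile-scored.
#'
#' @param records block-group data frame with columns `block_group_id`,
#'   `population` and the nine covariate columns (see [read_block_groups]).
#' @return list with `records` (kept rows) and `removal_log`, itself a list
#'   with counts `n_zero_population`, `n_missing_covariates` and the
#'   corresponding id vectors.
#' @export
filter_units <- function(records) {
  stopifnot(is.data.frame(records), "population" %in% names(records))
  covs <- intersect(covariate_names(), names(records))
  zero <- records$population <= 0 | is.na(records$population)
  kept <- records[!zero, , drop = FALSE]
  miss <- rowSums(is.na(kept[, covs, drop = FALSE])) > 0
  log <- list(
    n_zero_population = sum(zero),
    n_missing_covariates = sum(miss),
    zero_population_ids = records$block_group_id[zero],
    missing_covariate_ids = kept$block_group_id[miss]
  )
  kept <- kept[!miss, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all units removed by filtering")
  list(records = kept, removal_log = log)
}

#' Racial/ethnic segregation ratio
#'
#' Ratio of a unit's percent population in a group to the state-average
#' percent for that group; 1 means the unit mirrors the state composition.
#'
#' @param pct_group numeric vector of unit-level percentages.
#' @param state_avg_pct positive scalar, the state-average percentage.
#' @return numeric vector of ratios.
#' @export
segregation_ratio <- function(pct_group, state_avg_pct) {
  if (!is.numeric(state_avg_pct) || length(state_avg_pct) != 1L ||
      state_avg_pct <= 0)
    stop("`state_avg_pct` must be a positive scalar")
  pct_group / state_avg_pct
}

#' Invert a covariate so larger values mean more disadvantage
#'
#' Applies `max(x) - x`, used for per-capita income so that the disadvantage
#' index loads positively on low income. The maximum maps to 0 and ranks are
#' exactly reversed.
#'
#' @param x numeric vector without missing values.
#' @return `max(x) - x`.
#' @export
invert_income <- function(x) {
  stopifnot(length(x) > 0, !anyNA(x))
  max(x) - x
}

#' Decile scores of a covariate
#'
#' Scores each value 0-9 by the empirical decile bin it falls in. Breakpoints
#' are type-7 quantiles at probabilities 0.1, ..., 0.9; a value exactly equal
#' to a breakpoint goes to the lower bin. Decile scoring puts all covariates
#' on one scale, limits outlier influence, and makes the index invariant to
#' monotone transforms of its inputs.
#'
#' @param x numeric vector, no missing values.
#' @return integer vector of scores in `0:9`. A constant input yields all
#'   zeros with a warning.
#' @export
decile_scores <- function(x) {
  stopifnot(length(x) > 0)
  if (anyNA(x)) stop("decile_scores: missing values not allowed")
  breaks <- quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7, names = FALSE)
  if (max(x) == min(x)) {
    warning("constant covariate: all decile scores set to 0")
    return(rep.int(0L, length(x)))
  }
  # (b_m, b_{m+1}] bins: ties at a breakpoint fall to the lower score
  findInterval(x, breaks, left.open = TRUE)
}

#' Expected outlet counts under the statewide rate
#'
#' For each outlet type k, the overall rate is `r_k = sum(y_k) / sum(p)` and
#' the expected count in unit i is `E_ik = r_k * p_i`, so each column of `E`
#' sums to the observed total (internal standardization).
#'
#' @param records filtered block-group data frame with `population` and the
#'   count columns `n_tro`, `n_aro`, `n_taro`.
#' @return list of class `ndi_expected` with matrix `E` (units x 3), vector
#'   `rates`, and `degenerate`, a logical vector flagging types with zero
#'   total count.
#' @export
expected_counts <- function(records) {
  p <- records$population
  if (sum(p) <= 0) stop("total population must be positive")
  y <- as.matrix(records[, count_names(), drop = FALSE])
  rates <- colSums(y) / sum(p)
  E <- outer(p, rates)
  dimnames(E) <- list(records$block_group_id, outlet_types())
  degenerate <- rates == 0
  if (any(degenerate))
    warning("zero total count for type(s): ",
            paste(outlet_types()[degenerate], collapse = ", "))
  structure(list(E = E, rates = setNames(rates, outlet_types()),
                 degenerate = degenerate),
            class = "ndi_expected")
}

#' Population density category
#'
#' Classifies units as rural (< 500 persons/sq mi), suburban (>= 500 and
#' < 1000) or urban (>= 1000).
#'
#' @param population numeric vector of unit populations.
#' @param area positive numeric vector of land areas in square miles.
#' @return factor with levels `rural`, `suburban`, `urban`.
#' @export
population_density_category <- function(population, area) {
  stopifnot(all(area > 0))
  density <- population / area
  cut(density, breaks = c(-Inf, 500, 1000, Inf),
      labels = c("rural", "suburban", "urban"), right = FALSE)
}

#' Prepare model inputs from filtered block-group records
#'
#' Runs the preprocessing chain feeding the shared-component model: inverts
#' per-capita income, decile-scores all nine covariates, computes expected
#' counts, and attaches population-density categories.
#'
#' @param records filtered block-group data frame (see [filter_units]).
#' @param adjacency an [ndi_adjacency] covering exactly the kept units.
#' @return list of class `ndi_data` with `y` (units x 3 count matrix), `E`,
#'   `rates`, `q` (units x 9 integer decile matrix), `density`, `records`
#'   and `adjacency`.
#' @export
prepare_ndi_data <- function(records, adjacency) {
  stopifnot(inherits(adjacency, "ndi_adjacency"))
  if (!setequal(records$block_group_id, adjacency$ids) ||
      nrow(records) != length(adjacency$ids))
    stop("adjacency must cover exactly the block groups in `records`")
  records <- records[match(adjacency$ids, records$block_group_id), ,
                     drop = FALSE]
  covs <- covariate_names()
  if (!all(covs %in% names(records)))
    stop("missing covariate column(s): ",
         paste(setdiff(covs, names(records)), collapse = ", "))
  x <- records[, covs, drop = FALSE]
  x$income_percap <- invert_income(x$income_percap)
  q <- vapply(x, decile_scores, integer(nrow(records)))
  rownames(q) <- records$block_group_id
  ec <- expected_counts(records)
  y <- as.matrix(records[, count_names(), drop = FALSE])
  dimnames(y) <- list(records$block_group_id, outlet_types())
  structure(
    list(y = y, E = ec$E, rates = ec$rates, q = q,
         density = population_density_category(records$population,
                                               records$area),
         records = records, adjacency = adjacency),
    class = "ndi_data"
  )
}
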