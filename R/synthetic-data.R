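#' Configuration for the areal synthetic-data generator
#'
#' Defines the generative conditions for a lattice of block groups whose
#' outlet counts follow the shared-component index model with known
#' parameters, so that every downstream stage (preprocessing, fitting,
#' summarization) can be validated against ground truth.
#'
#' Defaults emulate the study setting: nine correlated sociodemographic
#' covariates, outlet-type effects near the reported relative risks per
#' decile of disadvantage, index weights concentrated on three variables,
#' block-group populations in the hundreds-to-thousands, and a baseline
#' outlet rate of about one outlet per thousand residents.
#'
#' @param lattice_rows,lattice_cols lattice dimensions (at least 4 cells).
#' @param n_vars number of covariates (default 9).
#' @param true_weights simplex vector of index weights, length `n_vars`.
#' @param true_betas length-3 disadvantage effects (log relative risk per
#'   decile) for TRO, ARO, TARO.
#' @param true_intercepts length-3 intercepts on the log-risk scale; the
#'   default centers log relative risk near 0 at the mid-range of the index.
#' @param sd_u marginal sd of the unstructured shared effect.
#' @param sd_v marginal sd of the spatially correlated shared (ICAR) effect.
#' @param sd_s length-3 marginal sds of the outlet-specific ICAR effects.
#' @param population_range integer pair; unit populations are drawn uniformly
#'   in this range (lower bound at least 1).
#' @param area_range positive pair, land area range in square miles.
#' @param covariate_correlation common pairwise correlation of the Gaussian
#'   copula generating the covariates, in `[0, 1)`.
#' @param baseline_rate baseline outlets per person used to scale expected
#'   counts during generation.
#' @param seed integer RNG seed.
#' @return object of class `ndi_synth_config`.
#' @export
synthetic_config <- function(lattice_rows = 10, lattice_cols = 10,
                             n_vars = 9,
                             true_weights = c(0.60, 0.23, 0.09,
                                              rep(0.08 / 6, 6)),
                             true_betas = log(c(1.12, 1.15, 1.21)),
                             true_intercepts = -4.5 * true_betas,
                             sd_u = 0.1, sd_v = 0.3,
                             sd_s = c(0.2, 0.2, 0.2),
                             population_range = c(600L, 3000L),
                             area_range = c(0.2, 20),
                             covariate_correlation = 0.4,
                             baseline_rate = 0.001,
                             seed = 1L) {
  cfg <- list(lattice_rows = as.integer(lattice_rows),
              lattice_cols = as.integer(lattice_cols),
              n_vars = as.integer(n_vars),
              true_weights = true_weights, true_betas = true_betas,
              true_intercepts = true_intercepts,
              sd_u = sd_u, sd_v = sd_v, sd_s = sd_s,
              population_range = as.integer(population_range),
              area_range = area_range,
              covariate_correlation = covariate_correlation,
              baseline_rate = baseline_rate, seed = as.integer(seed))
  if (cfg$lattice_rows * cfg$lattice_cols < 4)
    stop("lattice must have at least 4 cells")
  if (length(cfg$true_weights) != cfg$n_vars)
    stop("true_weights must have length n_vars")
  if (abs(sum(cfg$true_weights) - 1) > 1e-12 ||
      any(cfg$true_weights < 0) || any(cfg$true_weights > 1))
    stop("true_weights must be a simplex vector (nonnegative, summing to 1)")
  if (length(cfg$true_betas) != 3 || length(cfg$true_intercepts) != 3)
    stop("true_betas and true_intercepts must have length 3")
  if (cfg$sd_u < 0 || cfg$sd_v < 0 || any(cfg$sd_s < 0) ||
      length(cfg$sd_s) != 3)
    stop("effect scales must be nonnegative (sd_s of length 3)")
  if (cfg$population_range[1] < 1 || diff(cfg$population_range) < 0)
    stop("population_range lower bound must be >= 1")
  if (any(cfg$area_range <= 0)) stop("area_range must be positive")
  if (cfg$covariate_correlation < 0 || cfg$covariate_correlation >= 1)
    stop("covariate_correlation must be in [0, 1)")
  if (cfg$baseline_rate <= 0) stop("baseline_rate must be positive")
  structure(cfg, class = "ndi_synth_config")
}

# exact ICAR draw: sample the non-null eigenvectors of the graph Laplacian
# with variances 1/lambda_m, centre, and rescale to unit empirical sd
icar_draw <- function(adj, scale) {
  n <- length(adj$ids)
  if (scale == 0) return(numeric(n))
  ev <- eigen(adjacency_laplacian(adj), symmetric = TRUE)
  pos <- ev$values > 1e-9 * max(ev$values)
  coef <- rnorm(sum(pos), sd = 1 / sqrt(ev$values[pos]))
  z <- as.vector(ev$vectors[, pos, drop = FALSE] %*% coef)
  z <- z - mean(z)
  if (sd(z) > 0) z <- z / sd(z)
  scale * z
}

# Gaussian copula with equicorrelation rho mapped through heterogeneous
# marginals loosely shaped like the real covariates (segregation ratios,
# percentages, per-capita income); deciles discard the marginals anyway
draw_covariates <- function(n, n_vars, rho) {
  S <- matrix(rho, n_vars, n_vars); diag(S) <- 1
  z <- matrix(rnorm(n * n_vars), n, n_vars) %*% chol(S)
  p <- pnorm(z)
  marginals <- list(
    function(u) qlnorm(u, 0, 0.8),          # seg_black
    function(u) qlnorm(u, 0, 0.9),          # seg_hispanic
    function(u) 100 * qbeta(u, 2, 8),       # pct_income_poverty
    function(u) 100 * qbeta(u, 1.5, 28),    # pct_public_assist
    function(u) 100 * qbeta(u, 2.5, 4.5),   # pct_renter
    function(u) 100 * qbeta(u, 1.2, 8),     # pct_built_pre1940
    function(u) 100 * qbeta(u, 2, 12),      # pct_no_hs
    function(u) 100 * qbeta(u, 2, 10),      # pct_hh_poverty
    function(u) qgamma(u, shape = 6, scale = 4500)  # income_percap
  )
  x <- vapply(seq_len(n_vars), function(j) {
    f <- marginals[[((j - 1) %% length(marginals)) + 1]]
    f(p[, j])
  }, numeric(n))
  colnames(x) <- if (n_vars == 9) covariate_names()
                 else paste0("x", seq_len(n_vars))
  x
}

#' Generate a synthetic areal dataset with known truth
#'
#' Builds a rook-adjacency lattice, draws correlated covariates and converts
#' them to decile scores (inverting per-capita income first, as the pipeline
#' does), draws the unstructured and ICAR random effects exactly (via the
#' Laplacian eigenbasis), computes relative risks from the shared-component
#' index model, and samples Poisson counts around `baseline_rate x
#' population` expectations.
#'
#' @param cfg an [synthetic_config] object.
#' @return list of class `ndi_synth` with `block_groups` (data frame in the
#'   block-group CSV layout), `adjacency`, and `truth` (list: `weights`,
#'   `betas`, `intercepts`, `u`, `v`, `s`, `ndi_true`, `theta`, `E0`).
#' @export
generate_areal_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ndi_synth_config"))
  set.seed(cfg$seed)
  adj <- lattice_adjacency(cfg$lattice_rows, cfg$lattice_cols)
  n <- length(adj$ids)

  population <- sample(cfg$population_range[1]:cfg$population_range[2], n,
                       replace = TRUE)
  area <- runif(n, cfg$area_range[1], cfg$area_range[2])
  x <- draw_covariates(n, cfg$n_vars, cfg$covariate_correlation)

  # decile scores as the model will see them (income inverted first)
  xq <- x
  if ("income_percap" %in% colnames(xq))
    xq[, "income_percap"] <- invert_income(xq[, "income_percap"])
  q <- vapply(seq_len(ncol(xq)), function(j) decile_scores(xq[, j]),
              integer(n))
  ndi_true <- as.vector(q %*% cfg$true_weights)

  u <- if (cfg$sd_u > 0) rnorm(n, sd = cfg$sd_u) else numeric(n)
  v <- icar_draw(adj, cfg$sd_v)
  s <- vapply(1:3, function(k) icar_draw(adj, cfg$sd_s[k]), numeric(n))

  log_theta <- vapply(1:3, function(k)
    cfg$true_intercepts[k] + cfg$true_betas[k] * ndi_true + u + v + s[, k],
    numeric(n))
  theta <- exp(log_theta)
  E0 <- outer(population * cfg$baseline_rate, rep(1, 3))
  y <- matrix(rpois(n * 3, theta * E0), n, 3)

  bg <- data.frame(block_group_id = adj$ids, population = population,
                   area = area, x, check.names = FALSE)
  bg[count_names()] <- as.data.frame(y)

  structure(list(
    block_groups = bg, adjacency = adj,
    truth = list(weights = cfg$true_weights, betas = cfg$true_betas,
                 intercepts = cfg$true_intercepts, u = u, v = v, s = s,
                 ndi_true = ndi_true, theta = theta, E0 = E0)
  ), class = "ndi_synth")
}

#' Configuration for the listing-pair simulator
#'
#' @param n_blockgroups number of 1 sq mi block-group cells listings are
#'   scattered over.
#' @param chain_pool_size number of distinct chain businesses available for
#'   true tobacco-and-alcohol outlets.
#' @param n_known_chains how many chains appear on the known-chain list.
#' @param n_taro_true number of true dual outlets (each produces one TRO and
#'   one ARO listing of the same business).
#' @param n_tro_only,n_aro_only numbers of single-class businesses.
#' @param typo_rate per-character edit probability applied to the ARO copy of
#'   each duplicated listing's name and address.
#' @param coord_jitter_ft sd (feet, per axis) of the coordinate perturbation
#'   applied to the ARO copy.
#' @param seed integer RNG seed.
#' @return object of class `ndi_listing_config`.
#' @export
listing_sim_config <- function(n_blockgroups = 40, chain_pool_size = 30,
                               n_known_chains = chain_pool_size,
                               n_taro_true = 50, n_tro_only = 50,
                               n_aro_only = 50, typo_rate = 0.02,
                               coord_jitter_ft = 100, seed = 1L) {
  cfg <- list(n_blockgroups = as.integer(n_blockgroups),
              chain_pool_size = as.integer(chain_pool_size),
              n_known_chains = as.integer(n_known_chains),
              n_taro_true = as.integer(n_taro_true),
              n_tro_only = as.integer(n_tro_only),
              n_aro_only = as.integer(n_aro_only),
              typo_rate = typo_rate, coord_jitter_ft = coord_jitter_ft,
              seed = as.integer(seed))
  if (cfg$n_blockgroups < 1 || cfg$chain_pool_size < 1)
    stop("n_blockgroups and chain_pool_size must be positive")
  if (cfg$n_taro_true < 0 || cfg$n_tro_only < 0 || cfg$n_aro_only < 0)
    stop("listing counts must be nonnegative")
  if (!is.finite(cfg$typo_rate) || cfg$typo_rate < 0 || cfg$typo_rate > 1)
    stop("typo_rate must be in [0, 1]")
  if (!is.finite(cfg$coord_jitter_ft) || cfg$coord_jitter_ft < 0)
    stop("coord_jitter_ft must be finite and nonnegative")
  if (cfg$n_known_chains > cfg$chain_pool_size)
    stop("n_known_chains cannot exceed chain_pool_size")
  structure(cfg, class = "ndi_listing_config")
}

listing_vocab <- function() {
  list(
    first = c("QUICK", "SPEEDY", "CORNER", "VILLAGE", "SUNRISE", "CAROLINA",
              "BLUE RIDGE", "PIEDMONT", "COASTAL", "RIVERSIDE", "GOLDEN",
              "LUCKY", "FAMILY", "METRO", "UPTOWN"),
    kind = c("MART", "MARKET", "GROCERY", "FOOD STORE", "CONVENIENCE",
             "FUEL STOP", "TRADING CO", "SUPERETTE", "PANTRY", "DEPOT"),
    street = c("MAIN", "OAK", "ELM", "MAPLE", "PINE", "CEDAR", "CHURCH",
               "MILL", "RIVER", "LAKE", "HILLCREST", "DOGWOOD"),
    suffix_variants = list(c("STREET", "ST"), c("AVENUE", "AVE"),
                           c("ROAD", "RD"), c("BOULEVARD", "BLVD"),
                           c("DRIVE", "DR"), c("HIGHWAY", "HWY"),
                           c("LANE", "LN"), c("COURT", "CT"),
                           c("PLACE", "PL"), c("PARKWAY", "PKWY"))
  )
}

# per-character noise: substitution, deletion, or adjacent transposition
apply_typos <- function(x, rate) {
  if (rate <= 0) return(x)
  vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- 1L
    while (i <= length(ch)) {
      if (runif(1) < rate) {
        op <- sample(3L, 1L)
        if (op == 1L) {
          ch[i] <- sample(LETTERS, 1)
        } else if (op == 2L && length(ch) > 1L) {
          ch <- ch[-i]
          i <- i - 1L
        } else if (op == 3L && i < length(ch)) {
          tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
          i <- i + 1L
        }
      }
      i <- i + 1L
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# degrees per foot on the generator's reference sphere
DEG_PER_FT_LAT <- 1 / (20902259 * pi / 180)

#' Generate noisy duplicate business listings with known match truth
#'
#' Lays `n_blockgroups` one-square-mile cells along a strip, scatters
#' single-class businesses and true dual outlets over them, and emits one TRO
#' and one ARO listing per true dual outlet. The ARO copy's name and address
#' receive per-character typos at `typo_rate`, its street suffix may be
#' written in a variant form (STREET vs ST), and its coordinates are jittered
#' with sd `coord_jitter_ft` per axis — emulating two independently curated
#' business databases.
#'
#' @param cfg an [listing_sim_config] object.
#' @return list of class `ndi_listing_sim` with `listings` (data frame in the
#'   listings CSV layout), `truth_pairs` (data frame `tro_id`, `aro_id`), and
#'   `known_chains` (normalized names of the chain subset).
#' @export
generate_listing_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "ndi_listing_config"))
  set.seed(cfg$seed)
  voc <- listing_vocab()
  base_lat <- 35.5; base_lon <- -79.5
  ft_per_mile <- 5280
  dlat_mile <- ft_per_mile * DEG_PER_FT_LAT
  dlon_mile <- dlat_mile / cos(base_lat * pi / 180)
  bg_ids <- sprintf("BG%04d", seq_len(cfg$n_blockgroups))

  make_name <- function(n, tag) {
    if (n == 0) return(character())
    paste(sample(voc$first, n, replace = TRUE),
          sample(voc$kind, n, replace = TRUE), tag, seq_len(n))
  }
  chains <- unique(paste(sample(voc$first, cfg$chain_pool_size, TRUE),
                         sample(voc$kind, cfg$chain_pool_size, TRUE),
                         "INC"))
  chains <- make.unique(chains, sep = " ")
  known_chains <- sort(normalize_name(chains[seq_len(min(cfg$n_known_chains,
                                                         length(chains)))]))

  make_address <- function(n) {
    sfx <- vapply(sample(seq_along(voc$suffix_variants), n, TRUE),
                  function(i) sample(voc$suffix_variants[[i]], 1),
                  character(1))
    list(number = sample(1:9999, n, TRUE),
         street = sample(voc$street, n, TRUE), suffix = sfx)
  }
  place <- function(n) {
    bg <- sample(bg_ids, n, replace = TRUE)
    cell <- match(bg, bg_ids) - 1L
    lon <- base_lon + cell * dlon_mile + runif(n) * dlon_mile
    lat <- base_lat + runif(n) * dlat_mile
    list(bg = bg, lat = lat, lon = lon)
  }

  rows <- list()
  truth <- data.frame(tro_id = character(), aro_id = character())

  if (cfg$n_taro_true > 0) {
    nm <- chains[sample(length(chains), cfg$n_taro_true, replace = TRUE)]
    # some listings carry store identification numbers
    store_no <- ifelse(runif(cfg$n_taro_true) < 0.3,
                       paste0(" #", sample(100:9999, cfg$n_taro_true, TRUE)),
                       "")
    ad <- make_address(cfg$n_taro_true)
    loc <- place(cfg$n_taro_true)
    sfx_alt <- vapply(ad$suffix, function(s) {
      for (vv in voc$suffix_variants) if (s %in% vv) return(sample(vv, 1))
      s
    }, character(1), USE.NAMES = FALSE)
    tro_ids <- sprintf("T%04d", seq_len(cfg$n_taro_true))
    aro_ids <- sprintf("A%04d", seq_len(cfg$n_taro_true))
    jit <- cfg$coord_jitter_ft * DEG_PER_FT_LAT
    rows$taro_t <- data.frame(
      listing_id = tro_ids, name = paste0(nm, store_no),
      address = paste(ad$number, ad$street, ad$suffix),
      latitude = loc$lat, longitude = loc$lon,
      outlet_class = "TRO", block_group_id = loc$bg)
    rows$taro_a <- data.frame(
      listing_id = aro_ids,
      name = apply_typos(nm, cfg$typo_rate),
      address = apply_typos(paste(ad$number, ad$street, sfx_alt),
                            cfg$typo_rate),
      latitude = loc$lat + rnorm(cfg$n_taro_true, sd = jit),
      longitude = loc$lon + rnorm(cfg$n_taro_true, sd = jit) /
        cos(base_lat * pi / 180),
      outlet_class = "ARO", block_group_id = loc$bg)
    truth <- data.frame(tro_id = tro_ids, aro_id = aro_ids)
  }
  if (cfg$n_tro_only > 0) {
    loc <- place(cfg$n_tro_only)
    ad <- make_address(cfg$n_tro_only)
    rows$tro <- data.frame(
      listing_id = sprintf("T9%03d", seq_len(cfg$n_tro_only)),
      name = make_name(cfg$n_tro_only, "TOBACCO"),
      address = paste(ad$number, ad$street, ad$suffix),
      latitude = loc$lat, longitude = loc$lon,
      outlet_class = "TRO", block_group_id = loc$bg)
  }
  if (cfg$n_aro_only > 0) {
    loc <- place(cfg$n_aro_only)
    ad <- make_address(cfg$n_aro_only)
    rows$aro <- data.frame(
      listing_id = sprintf("A9%03d", seq_len(cfg$n_aro_only)),
      name = make_name(cfg$n_aro_only, "BOTTLE SHOP"),
      address = paste(ad$number, ad$street, ad$suffix),
      latitude = loc$lat, longitude = loc$lon,
      outlet_class = "ARO", block_group_id = loc$bg)
  }

  listings <- do.call(rbind, rows)
  if (is.null(listings))
    listings <- data.frame(listing_id = character(), name = character(),
                           address = character(), latitude = numeric(),
                           longitude = numeric(), outlet_class = character(),
                           block_group_id = character())
  rownames(listings) <- NULL
  structure(list(listings = listings, truth_pairs = truth,
                 known_chains = known_chains),
            class = "ndi_listing_sim")
}
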