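#' Read and write block-group tables
#'
#' The block-group CSV has columns `block_group_id`, `population`, `area`
#' (square miles), the nine covariate columns (`seg_black`, `seg_hispanic`,
#' `pct_income_poverty`, `pct_public_assist`, `pct_renter`,
#' `pct_built_pre1940`, `pct_no_hs`, `pct_hh_poverty`, `income_percap`) and
#' the outlet counts `n_tro`, `n_aro`, `n_taro`. Missing covariates are kept
#' as `NA` so [filter_units] can log them.
#'
#' @param path CSV file path.
#' @return data frame of block-group records.
#' @export
read_block_groups <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("block_group_id", "population", "area", covariate_names(),
           count_names())
  if (!all(req %in% names(df)))
    stop("block-group file missing column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (nrow(df) == 0L) return(df[, req])
  df$block_group_id <- as.character(df$block_group_id)
  num <- setdiff(req, "block_group_id")
  bad <- unlist(lapply(num, function(cn) {
    v <- df[[cn]]
    which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
  }))
  if (length(bad))
    stop("malformed numeric value(s) at data line(s): ",
         paste(sort(unique(bad)), collapse = ", "))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (any(df$area <= 0, na.rm = TRUE)) stop("area must be positive")
  if (any(df[count_names()] < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  df[, req]
}

#' @rdname read_block_groups
#' @param records block-group data frame.
#' @export
write_block_groups <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write business-listing tables
#'
#' Listings CSV columns: `listing_id`, `name`, `address`, `latitude`,
#' `longitude`, `outlet_class` (`TRO`/`ARO`), `block_group_id`.
#'
#' @param path CSV file path.
#' @return data frame of listings.
#' @export
read_listings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("listing_id", "name", "address", "latitude", "longitude",
           "outlet_class", "block_group_id")
  if (!all(req %in% names(df)))
    stop("listings file missing column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (nrow(df) == 0L) return(df[, req])
  for (cn in c("latitude", "longitude")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop("malformed ", cn, " at data line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    df[[cn]] <- v
  }
  validate_listings(df)
  df[, req]
}

#' @rdname read_listings
#' @param listings listings data frame.
#' @export
write_listings <- function(listings, path) {
  write.csv(listings, path, row.names = FALSE)
  invisible(path)
}

#' Read and write areal adjacency files
#'
#' One line per unit in the dialect `id: neighbor_id neighbor_id ...`;
#' entries must be symmetric and self-neighbours are rejected.
#'
#' @param path adjacency file path.
#' @return an [ndi_adjacency] object.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L & lengths(parts) != 1L))
    stop("malformed adjacency line(s)")
  ids <- trimws(vapply(parts, `[[`, character(1), 1))
  nbrs <- lapply(parts, function(p) {
    if (length(p) < 2L) return(character())
    strsplit(trimws(p[[2]]), "\\s+")[[1]]
  })
  nbrs <- lapply(nbrs, function(x) x[nzchar(x)])
  names(nbrs) <- ids
  ndi_adjacency(nbrs)
}

#' @rdname read_adjacency
#' @param adj an [ndi_adjacency] object.
#' @export
write_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "ndi_adjacency"))
  lines <- vapply(seq_along(adj$ids), function(i)
    paste0(adj$ids[i], ": ",
           paste(adj$ids[adj$neighbors[[i]]], collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Persist posterior draws as CSV
#'
#' One row per stored iteration per chain; columns are `chain`, `iteration`,
#' the intercepts, effects, weights, precisions, and (optionally) the
#' unit-level random effects.
#'
#' @param draws an `ndi_draws` object.
#' @param path output CSV path.
#' @param include_unit_effects also write the `u`, `v` and `s` columns
#'   (large for big lattices).
#' @return the path, invisibly.
#' @export
write_draws_csv <- function(draws, path, include_unit_effects = FALSE) {
  stopifnot(inherits(draws, "ndi_draws"))
  n_store <- dim(draws$beta)[1]; K <- dim(draws$beta)[2]
  C <- dim(draws$w)[2]
  per_chain <- function(ch) {
    out <- data.frame(chain = ch, iteration = seq_len(n_store))
    for (k in 1:K) out[[paste0("alpha_", k)]] <- draws$alpha[, k, ch]
    for (k in 1:K) out[[paste0("beta_", k)]] <- draws$beta[, k, ch]
    for (j in 1:C) out[[paste0("w_", j)]] <- draws$w[, j, ch]
    out$tau_u <- draws$tau_u[, ch]
    out$tau_v <- draws$tau_v[, ch]
    for (k in 1:K) out[[paste0("tau_s_", k)]] <- draws$tau_s[, k, ch]
    out$sigma_beta <- draws$sigma_beta[, ch]
    if (include_unit_effects) {
      n <- length(draws$unit_ids)
      for (i in seq_len(n)) out[[paste0("u_", i)]] <- draws$u[, i, ch]
      for (i in seq_len(n)) out[[paste0("v_", i)]] <- draws$v[, i, ch]
      for (k in 1:K) for (i in seq_len(n))
        out[[paste0("s_", i, "_", k)]] <- draws$s[, i, k, ch]
    }
    out
  }
  tab <- do.call(rbind, lapply(seq_len(dim(draws$beta)[3]), per_chain))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Rebuild an `ndi_draws` object from a draws CSV
#'
#' Inverse of [write_draws_csv] (written with `include_unit_effects = TRUE`):
#' reconstitutes the posterior draws against the prepared data they were
#' fit to.
#'
#' @param path draws CSV written by [write_draws_csv].
#' @param data the `ndi_data` object (from [prepare_ndi_data]) the model was
#'   fit to.
#' @return an `ndi_draws` object.
#' @export
read_draws_csv <- function(path, data) {
  tab <- read.csv(path)
  chains <- sort(unique(tab$chain))
  n_store <- sum(tab$chain == chains[1])
  n <- nrow(data$y); K <- ncol(data$y); C <- ncol(data$q)
  need <- c(paste0("u_", 1), paste0("v_", 1), paste0("s_", 1, "_", 1))
  if (!all(need %in% names(tab)))
    stop("draws CSV lacks unit-level effects; write with ",
         "include_unit_effects = TRUE to allow summarization")
  grab <- function(cols) {
    a <- array(NA_real_, c(n_store, length(cols), length(chains)))
    for (ci in seq_along(chains)) {
      sub <- tab[tab$chain == chains[ci], cols, drop = FALSE]
      a[, , ci] <- as.matrix(sub)
    }
    a
  }
  draws <- list(
    alpha = grab(paste0("alpha_", 1:K)),
    beta = grab(paste0("beta_", 1:K)),
    w = grab(paste0("w_", 1:C)),
    u = grab(paste0("u_", 1:n)),
    v = grab(paste0("v_", 1:n)),
    s = array(grab(as.vector(outer(1:n, 1:K, function(i, k)
      paste0("s_", i, "_", k)))), c(n_store, n, K, length(chains))),
    tau_u = grab("tau_u")[, 1, , drop = TRUE],
    tau_v = grab("tau_v")[, 1, , drop = TRUE],
    tau_s = grab(paste0("tau_s_", 1:K)),
    sigma_beta = grab("sigma_beta")[, 1, , drop = TRUE]
  )
  if (length(chains) == 1L) {
    draws$tau_u <- matrix(draws$tau_u, ncol = 1)
    draws$tau_v <- matrix(draws$tau_v, ncol = 1)
    draws$sigma_beta <- matrix(draws$sigma_beta, ncol = 1)
  }
  draws$q <- data$q
  draws$E <- data$E
  draws$y <- data$y
  draws$unit_ids <- rownames(data$q)
  draws$covariates <- colnames(data$q)
  draws$config <- NULL
  class(draws) <- "ndi_draws"
  draws
}

#' Run manifest for reproducibility
#'
#' Records seeds, configuration (with an md5 content hash), package version
#' and input-file checksums, so a pipeline output can be re-derived.
#'
#' @param config a configuration object (any list).
#' @param seed the master seed used.
#' @param inputs named character vector of input file paths (checksummed).
#' @param path JSON output path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, inputs = character(), path) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "outletndi",
    version = as.character(utils::packageVersion("outletndi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
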