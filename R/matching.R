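#' Normalize business names and street addresses
#'
#' Standardizes raw listing text before record linkage: upper-casing,
#' stripping punctuation (except `&`, which distinguishes business names),
#' collapsing whitespace, canonicalizing street suffixes in addresses
#' (STREET -> ST, AVENUE -> AVE, ...), and removing trailing store
#' identification numbers from names (`#1234`, `NO 1234`, `STORE 1234`, or a
#' bare trailing digit run).
#'
#' @param x character vector of raw names or addresses.
#' @return character vector of normalized text.
#' @examples
#' normalize_name("Circle K Stores Inc #1234")  # "CIRCLE K STORES INC"
#' normalize_address("12 Main Street")          # "12 MAIN ST"
#' @export
normalize_name <- function(x) {
  out <- normalize_text(x)
  # repeatedly strip trailing store-number tokens
  repeat {
    trimmed <- sub("\\s+(#?[0-9]+|(NO|STORE)\\s+[0-9]+)$", "", out)
    if (identical(trimmed, out)) break
    out <- trimmed
  }
  out
}

#' @rdname normalize_name
#' @export
normalize_address <- function(x) {
  out <- normalize_text(x)
  suffixes <- c(
    STREET = "ST", STR = "ST", AVENUE = "AVE", ROAD = "RD",
    BOULEVARD = "BLVD", DRIVE = "DR", HIGHWAY = "HWY", LANE = "LN",
    COURT = "CT", PLACE = "PL", PARKWAY = "PKWY"
  )
  vapply(strsplit(out, " ", fixed = TRUE), function(tok) {
    hit <- tok %in% names(suffixes)
    tok[hit] <- suffixes[tok[hit]]
    paste(tok, collapse = " ")
  }, character(1))
}

normalize_text <- function(x) {
  out <- toupper(x)
  out <- gsub("[^A-Z0-9& ]+", " ", out)   # punctuation except '&'
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Normalize a table of business listings
#'
#' Applies [normalize_name] and [normalize_address] to a listings data frame,
#' adding `name_norm` and `address_norm` columns.
#'
#' @param listings data frame with columns `listing_id`, `name`, `address`,
#'   `latitude`, `longitude`, `outlet_class` (`"TRO"` or `"ARO"`) and
#'   `block_group_id`.
#' @return the input with `name_norm` and `address_norm` added.
#' @export
normalize_listing <- function(listings) {
  validate_listings(listings)
  listings$name_norm <- normalize_name(listings$name)
  if (any(!nzchar(listings$name_norm)))
    stop("listing name empty after normalization: ",
         paste(listings$listing_id[!nzchar(listings$name_norm)],
               collapse = ", "))
  listings$address_norm <- normalize_address(listings$address)
  listings
}

validate_listings <- function(listings) {
  req <- c("listing_id", "name", "address", "latitude", "longitude",
           "outlet_class", "block_group_id")
  if (!all(req %in% names(listings)))
    stop("listings must have columns: ", paste(req, collapse = ", "))
  if (any(is.na(listings$name) | !nzchar(listings$name)))
    stop("listing names must be non-empty")
  if (any(abs(listings$latitude) > 90) || any(abs(listings$longitude) > 180))
    stop("coordinates out of range")
  if (!all(listings$outlet_class %in% c("TRO", "ARO")))
    stop("outlet_class must be 'TRO' or 'ARO'")
  invisible(listings)
}

#' Optimal string alignment distance
#'
#' Restricted Damerau-Levenshtein edit distance: unit-cost insertions,
#' deletions, substitutions and adjacent transpositions, with no substring
#' edited more than once (so `osa_distance("CA", "ABC")` is 3, not the
#' unrestricted distance 2).
#'
#' @param a,b character vectors (recycled to common length).
#' @return integer vector of distances.
#' @export
osa_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) osa_distance_cpp(a[i], b[i]), integer(1))
}

#' Normalized string similarity
#'
#' `1 - osa_distance(a, b) / max(nchar(a), nchar(b))`, bounded in `[0, 1]`;
#' two empty strings are defined to have similarity 1.
#'
#' @inheritParams osa_distance
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
string_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  mx <- pmax(nchar(a), nchar(b))
  d <- osa_distance(a, b)
  ifelse(mx == 0, 1, 1 - d / mx)
}

#' Great-circle distance in feet
#'
#' Haversine distance on a sphere of radius 20,902,259 ft (6,371.0088 km).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return numeric vector of distances in feet.
#' @export
great_circle_ft <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 20902259)
}

#' Total similarity between a TRO and an ARO listing
#'
#' Weighted linkage score combining name similarity, address similarity and
#' two nested great-circle proximity indicators:
#' `0.25 * namesim + 0.25 * addresssim + 0.20 * I(dist < 520.9 ft) +
#' 0.30 * I(dist < 260.45 ft)`. The distance indicators are strict `<`; a
#' score of at least `0.70` is treated as a match by the matcher.
#'
#' @param tro,aro normalized listing rows (data frames with `name_norm`,
#'   `address_norm`, `latitude`, `longitude`); recycled to a common length.
#' @param weights numeric length-4 vector of component weights (name,
#'   address, outer indicator, inner indicator).
#' @param dist_thresholds_ft numeric length-2 vector: outer and inner
#'   proximity thresholds in feet.
#' @return numeric vector of total similarities in `[0, 1]`.
#' @export
total_similarity <- function(tro, aro,
                             weights = c(0.25, 0.25, 0.20, 0.30),
                             dist_thresholds_ft = c(520.9, 260.45)) {
  stopifnot(length(weights) == 4, length(dist_thresholds_ft) == 2)
  d <- great_circle_ft(tro$latitude, tro$longitude,
                       aro$latitude, aro$longitude)
  weights[1] * string_similarity(tro$name_norm, aro$name_norm) +
    weights[2] * string_similarity(tro$address_norm, aro$address_norm) +
    weights[3] * (d < dist_thresholds_ft[1]) +
    weights[4] * (d < dist_thresholds_ft[2])
}

#' Load a known-chain list
#'
#' Reads one business name per line and normalizes each with
#' [normalize_name], giving the list of commonly appearing businesses known
#' to sell both tobacco and alcohol.
#'
#' @param path file with one raw business name per line.
#' @return character vector of normalized chain names (unique, sorted).
#' @export
read_known_chains <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- x[nzchar(trimws(x))]
  sort(unique(normalize_name(x)))
}

#' Classify one block group's listings into TRO/ARO/TARO counts
#'
#' If both classes are present, all TRO x ARO pairs are scored with
#' [total_similarity] and matched greedily in descending similarity (ties
#' broken by `(tro_id, aro_id)`), one-to-one, declaring matches at
#' `similarity >= threshold`; each matched pair becomes one TARO and is
#' removed from both class counts. If only one class is present, listings
#' whose normalized name is on the known-chain list are counted as TAROs
#' (set-intersection fallback).
#'
#' @param tros,aros normalized listing data frames for a single block group
#'   (either may have zero rows).
#' @param known character vector of normalized known-chain names.
#' @param threshold match threshold on the total similarity score.
#' @return list with `n_tro`, `n_aro`, `n_taro` and a data frame `pairs`
#'   (`tro_id`, `aro_id`, `similarity`).
#' @export
count_outlets_block_group <- function(tros, aros, known = character(),
                                      threshold = 0.70) {
  bg <- unique(c(tros$block_group_id, aros$block_group_id))
  if (length(bg) > 1)
    stop("listings span multiple block groups: ", paste(bg, collapse = ", "))
  empty_pairs <- data.frame(tro_id = character(), aro_id = character(),
                            similarity = numeric())
  nt <- nrow(tros); na <- nrow(aros)
  if (nt == 0L && na == 0L)
    return(list(n_tro = 0L, n_aro = 0L, n_taro = 0L, pairs = empty_pairs))

  if (nt == 0L || na == 0L) {
    # single-class fallback: known chains are assumed to sell both
    one <- if (nt > 0L) tros else aros
    is_known <- one$name_norm %in% known
    n_taro <- sum(is_known)
    return(list(n_tro = if (nt > 0L) nt - n_taro else 0L,
                n_aro = if (na > 0L) na - n_taro else 0L,
                n_taro = n_taro, pairs = empty_pairs))
  }

  grid <- expand.grid(ti = seq_len(nt), ai = seq_len(na))
  sim <- total_similarity(tros[grid$ti, ], aros[grid$ai, ])
  ord <- order(-sim, tros$listing_id[grid$ti], aros$listing_id[grid$ai])
  used_t <- logical(nt); used_a <- logical(na)
  keep <- integer()
  for (r in ord) {
    if (sim[r] < threshold) break
    ti <- grid$ti[r]; ai <- grid$ai[r]
    if (used_t[ti] || used_a[ai]) next
    used_t[ti] <- TRUE; used_a[ai] <- TRUE
    keep <- c(keep, r)
  }
  pairs <- data.frame(tro_id = tros$listing_id[grid$ti[keep]],
                      aro_id = aros$listing_id[grid$ai[keep]],
                      similarity = sim[keep])
  list(n_tro = nt - nrow(pairs), n_aro = na - nrow(pairs),
       n_taro = nrow(pairs), pairs = pairs)
}

#' Run record linkage over all block groups
#'
#' Normalizes the listings, groups them by block group, applies
#' [count_outlets_block_group] to each group independently, and aggregates
#' matched pairs and per-block-group TRO/ARO/TARO counts.
#'
#' @param listings raw listings data frame (see [normalize_listing]).
#' @param known character vector of known-chain names (normalized, e.g. from
#'   [read_known_chains]); raw names are accepted and normalized.
#' @param threshold total-similarity match threshold.
#' @return list of class `ndi_match` with `pairs` (data frame: `tro_id`,
#'   `aro_id`, `similarity`, `block_group_id`) and `counts` (data frame:
#'   `block_group_id`, `n_tro`, `n_aro`, `n_taro`).
#' @export
run_matching <- function(listings, known = character(), threshold = 0.70) {
  empty <- structure(list(
    pairs = data.frame(tro_id = character(), aro_id = character(),
                       similarity = numeric(), block_group_id = character()),
    counts = data.frame(block_group_id = character(), n_tro = integer(),
                        n_aro = integer(), n_taro = integer())),
    class = "ndi_match")
  if (nrow(listings) == 0L) return(empty)
  listings <- normalize_listing(listings)
  known <- sort(unique(normalize_name(known)))
  groups <- split(listings, listings$block_group_id)
  res <- lapply(names(groups), function(bg) {
    g <- groups[[bg]]
    out <- count_outlets_block_group(g[g$outlet_class == "TRO", , drop = FALSE],
                                     g[g$outlet_class == "ARO", , drop = FALSE],
                                     known = known, threshold = threshold)
    if (nrow(out$pairs)) out$pairs$block_group_id <- bg
    out$bg <- bg
    out
  })
  pairs <- do.call(rbind, lapply(res, function(r)
    if (nrow(r$pairs)) r$pairs else NULL))
  counts <- data.frame(
    block_group_id = vapply(res, `[[`, character(1), "bg"),
    n_tro = vapply(res, `[[`, numeric(1), "n_tro"),
    n_aro = vapply(res, `[[`, numeric(1), "n_aro"),
    n_taro = vapply(res, `[[`, numeric(1), "n_taro")
  )
  if (is.null(pairs)) pairs <- empty$pairs
  structure(list(pairs = pairs, counts = counts), class = "ndi_match")
}

#' @export
print.ndi_match <- function(x, ...) {
  cat("ndi_match:", nrow(x$counts), "block groups;",
      sum(x$counts$n_tro), "TRO,", sum(x$counts$n_aro), "ARO,",
      sum(x$counts$n_taro), "TARO\n")
  invisible(x)
}
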