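test_that("name normalization upper-cases, strips store numbers and punctuation", {
  expect_equal(normalize_name("Circle K Stores Inc #1234"),
               "CIRCLE K STORES INC")
  expect_equal(normalize_name("FOOD LION LLC"), "FOOD LION LLC")
  expect_equal(normalize_name("Joe's  Mini-Mart STORE 77"), "JOE S MINI MART")
  expect_equal(normalize_name("Quick Stop NO 9"), "QUICK STOP")
  expect_equal(normalize_name("H&H Grocery 12"), "H&H GROCERY")
})

test_that("address normalization canonicalizes street suffixes", {
  expect_equal(normalize_address("12 Main Street"), "12 MAIN ST")
  expect_equal(normalize_address("3 Oak Avenue"), "3 OAK AVE")
  expect_equal(normalize_address("77 Pine BOULEVARD"), "77 PINE BLVD")
  expect_equal(normalize_address("9 Hwy. 64 Highway"), "9 HWY 64 HWY")
  expect_equal(normalize_address("1 Elm St"), "1 ELM ST")
})

test_that("osa distance matches frozen cases and the recursive oracle", {
  expect_equal(osa_distance("ABC", "ABC"), 0L)
  expect_equal(osa_distance("AB", "BA"), 1L)     # one transposition
  expect_equal(osa_distance("CA", "ABC"), 3L)    # restricted > unrestricted DL
  expect_equal(osa_distance("", "XYZ"), 3L)
  set.seed(41)
  alph <- c("A", "B", "C")
  for (i in 1:60) {
    a <- paste(sample(alph, sample(0:6, 1), TRUE), collapse = "")
    b <- paste(sample(alph, sample(0:6, 1), TRUE), collapse = "")
    expect_equal(osa_distance(a, b), osa_ref(a, b),
                 info = paste(a, "vs", b))
  }
})

test_that("string similarity is normalized and handles empty strings", {
  expect_equal(string_similarity("MART", "MART"), 1.0)
  expect_equal(string_similarity("AB", "BA"), 0.5)
  expect_equal(string_similarity("", "XYZ"), 0.0)
  expect_equal(string_similarity("", ""), 1.0)
})

test_that("great-circle distance uses the stated sphere radius", {
  expect_equal(great_circle_ft(35, -79, 35, -79), 0)
  # 0.001 degrees of latitude at the equator: R * 0.001 * pi/180
  expect_equal(great_circle_ft(0, 0, 0.001, 0), 20902259 * 0.001 * pi / 180,
               tolerance = 1e-6)
  # antipodal points approach pi * R
  expect_equal(great_circle_ft(0, 0, 0, 180), pi * 20902259,
               tolerance = 1e-6)
})

make_pair <- function(dist_ft, name_a = "FOOD LION LLC",
                      addr_a = "12 MAIN ST") {
  dlat <- dist_ft / (20902259 * pi / 180)
  t <- data.frame(name_norm = "FOOD LION LLC", address_norm = "12 MAIN ST",
                  latitude = 35, longitude = -79)
  a <- data.frame(name_norm = name_a, address_norm = addr_a,
                  latitude = 35 + dlat, longitude = -79)
  list(t = t, a = a)
}

test_that("total similarity reproduces the weighted score arithmetic", {
  p <- make_pair(0)
  expect_equal(total_similarity(p$t, p$a), 1.00)
  # identical strings at 300 ft: only the outer (0.20) indicator fires
  p <- make_pair(300)
  expect_equal(total_similarity(p$t, p$a), 0.70)
  # beyond both thresholds with unrelated strings: zero
  p <- make_pair(10000, name_a = "ZZZZZZZZZZZZZ", addr_a = "QQQQQQQQQQQ")
  expect_lt(total_similarity(p$t, p$a), 0.2)
  # boundary conventions are strict '<' on distance: straddle each
  # threshold by a hair (exact equality is not constructible in floats)
  p <- make_pair(520.9 * (1 + 1e-9))
  expect_equal(total_similarity(p$t, p$a), 0.50, tolerance = 1e-6)
  p <- make_pair(520.9 * (1 - 1e-9))
  expect_equal(total_similarity(p$t, p$a), 0.70, tolerance = 1e-6)
  p <- make_pair(260.45 * (1 - 1e-9))
  expect_equal(total_similarity(p$t, p$a), 1.00, tolerance = 1e-6)
  p <- make_pair(260.45 * (1 + 1e-9))
  expect_equal(total_similarity(p$t, p$a), 0.70, tolerance = 1e-6)
})

test_that("total similarity is within [0,1], symmetric in strings, monotone in distance", {
  set.seed(11)
  for (i in 1:20) {
    nm <- c("QUICK MART 1", "QUICK MART 2")
    d1 <- runif(1, 0, 1000); d2 <- d1 + runif(1, 0, 1000)
    p1 <- make_pair(d1, name_a = nm[1])
    p2 <- make_pair(d2, name_a = nm[1])
    s1 <- total_similarity(p1$t, p1$a); s2 <- total_similarity(p2$t, p2$a)
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_gte(s1, s2)  # non-increasing in distance
  }
  expect_equal(string_similarity("ABC", "CAB"), string_similarity("CAB", "ABC"))
})

test_that("single-class block groups fall back to the known-chain list", {
  tros <- normalize_listing(make_listings(
    list("t1", "CIRCLE K STORES INC", "1 Main St", 35, -79, "TRO", "bg1"),
    list("t2", "SMOKES R US", "2 Main St", 35, -79, "TRO", "bg1")))
  res <- count_outlets_block_group(tros, tros[0, ],
                                   known = "CIRCLE K STORES INC")
  expect_equal(c(res$n_tro, res$n_aro, res$n_taro), c(1L, 0L, 1L))
  # symmetric ARO-only case
  aros <- tros; aros$outlet_class <- "ARO"
  res <- count_outlets_block_group(aros[0, ], aros,
                                   known = "CIRCLE K STORES INC")
  expect_equal(c(res$n_tro, res$n_aro, res$n_taro), c(0L, 1L, 1L))
})

test_that("mixed block groups match at the 0.70 threshold, one-to-one", {
  ls <- normalize_listing(make_listings(
    list("t1", "FOOD LION LLC", "12 Main St", 35, -79, "TRO", "bg1"),
    list("a1", "FOOD LION LLC", "12 Main Street", 35, -79, "ARO", "bg1")))
  res <- count_outlets_block_group(ls[1, ], ls[2, ])
  expect_equal(res$n_taro, 1L)
  expect_equal(res$pairs$similarity, 1.0)

  # a pair engineered just below threshold: same address/coords far apart
  far <- make_listings(
    list("t1", "AAAAAAAAAA", "12 Main St", 35, -79, "TRO", "bg1"),
    list("a1", "BBBBBBBBBB", "12 Main St", 36, -79, "ARO", "bg1"))
  res <- count_outlets_block_group(normalize_listing(far[1, ]),
                                   normalize_listing(far[2, ]))
  # namesim 0, addresssim 1, no distance indicator: 0.25 < 0.70
  expect_equal(c(res$n_tro, res$n_aro, res$n_taro), c(1L, 1L, 0L))
  expect_error(count_outlets_block_group(
    normalize_listing(far[1, ]),
    normalize_listing(transform(far[2, ], block_group_id = "bg2"))),
    "multiple block groups")
})

test_that("run_matching conserves listings and is independent across groups", {
  lsim <- generate_listing_pairs(listing_sim_config(
    n_taro_true = 30, n_tro_only = 20, n_aro_only = 20, seed = 5))
  res <- run_matching(lsim$listings, lsim$known_chains)
  ltab <- table(lsim$listings$block_group_id, lsim$listings$outlet_class)
  for (bg in rownames(ltab)) {
    row <- res$counts[res$counts$block_group_id == bg, ]
    n_pairs <- sum(res$pairs$block_group_id == bg)
    n_t0 <- ltab[bg, "TRO"]; n_a0 <- ltab[bg, "ARO"]
    if (n_t0 > 0 && n_a0 > 0) {
      expect_equal(row$n_tro + n_pairs, unname(n_t0))
      expect_equal(row$n_aro + n_pairs, unname(n_a0))
      expect_equal(row$n_taro, n_pairs)
    } else {
      # fallback: taro + remaining equals the single-class total
      expect_equal(row$n_tro + row$n_aro + row$n_taro, unname(n_t0 + n_a0))
    }
  }
  # empty input
  empty <- run_matching(lsim$listings[0, ])
  expect_equal(nrow(empty$counts), 0L)
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("noise-free duplicates are recovered exactly", {
  lsim <- generate_listing_pairs(listing_sim_config(
    n_taro_true = 40, n_tro_only = 10, n_aro_only = 10,
    typo_rate = 0, coord_jitter_ft = 0, seed = 9))
  # exact duplicates score 1 under the similarity
  ls <- normalize_listing(lsim$listings)
  tro <- ls[match(lsim$truth_pairs$tro_id, ls$listing_id), ]
  aro <- ls[match(lsim$truth_pairs$aro_id, ls$listing_id), ]
  expect_true(all(abs(total_similarity(tro, aro) - 1) < 1e-12))
  res <- run_matching(lsim$listings, lsim$known_chains)
  got <- paste(res$pairs$tro_id, res$pairs$aro_id)
  truth <- paste(lsim$truth_pairs$tro_id, lsim$truth_pairs$aro_id)
  expect_setequal(got, truth)
})
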