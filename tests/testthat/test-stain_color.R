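test_that("lalphabeta conversion matches the matrix-chain oracle", {
  # frozen value computed by independent matrix arithmetic for (200,60,120)
  px <- const_tile(200, 60, 120, n = 1)
  lab <- to_lab(px)
  expect_equal(as.numeric(lab),
               c(-0.6553058125249, -0.0345782349064, 0.0698738805094),
               tolerance = 1e-10)
  # achromatic pixels carry near-zero chroma
  for (g in c(32, 128, 240)) {
    lab <- to_lab(const_tile(g, g, g, n = 2))
    expect_lt(max(abs(lab[, , 2:3])), 5e-3)
  }
})

test_that("to_lab / from_lab round-trips within one intensity level", {
  tile <- random_tile(12, seed = 3)
  back <- from_lab(to_lab(tile))
  expect_lt(max(abs(back - tile)), 1)
})

test_that("reinhard transfer follows the scalar per-channel formula", {
  tile <- random_tile(6, seed = 4)
  src <- lab_stats(tile)
  tgt <- growthmap:::new_lab_stats(c(-0.9, 0.02, -0.01), c(0.2, 0.01, 0.02))
  out <- reinhard_transfer(tile, src, tgt)
  # oracle: scalar per-pixel arithmetic in lalphabeta, then inversion
  lab <- to_lab(tile)
  expect_lab <- array(0, dim(lab))
  for (r in seq_len(dim(lab)[1])) {
    for (c in seq_len(dim(lab)[2])) {
      expect_lab[r, c, ] <- oracle_reinhard_pixel(
        lab[r, c, ], src$mean, src$std, tgt$mean, tgt$std)
    }
  }
  expect_equal(out, from_lab(expect_lab), tolerance = 1e-9)
})

test_that("identity transfer and degenerate sources behave as documented", {
  tile <- random_tile(10, seed = 5)
  st <- lab_stats(tile)
  expect_lt(max(abs(reinhard_transfer(tile, st, st) - tile)), 1)

  flat <- const_tile(180, 90, 140, n = 6)
  tgt <- lab_stats(random_tile(10, seed = 6))
  out <- reinhard_transfer(flat, target_stats = tgt)
  # constant tile maps to the target means
  expect_lt(max(abs(to_lab(out)[1, 1, ] - tgt$mean)), 1e-2)
  expect_lt(max(apply(matrix(out, ncol = 3), 2, sd)), 1e-6)
})

test_that("normalize_tile hits the target stats and is idempotent", {
  # comparable-spread source and target (the operation's validity domain;
  # extreme variance amplification would clip out of gamut instead)
  tile <- generate_texture("MP", 64, "site_a", seed = 9)
  tgt <- pooled_pattern(lapply(10:12, function(i) {
    generate_texture("MP", 64, "site_b", seed = i)
  }))
  once <- normalize_tile(tile, tgt)
  twice <- normalize_tile(once, tgt)
  expect_lt(max(abs(twice - once)), 1)
  st <- lab_stats(once)
  expect_lt(max(abs(st$mean - tgt$stats$mean)), 0.02)
})

test_that("pattern derivation recovers planted color clusters", {
  # corpus 1: two well-separated constant colors; k = 2 recovers both
  c1 <- list(const_tile(60, 30, 90, 10), const_tile(230, 200, 215, 10))
  pats <- derive_color_patterns(list(purple_pale = c1), k_total = 2, seed = 1)
  expect_length(pats, 2)
  means <- t(sapply(pats, function(p) p$stats$mean))
  planted <- rbind(as.numeric(to_lab(const_tile(60, 30, 90, 1))),
                   as.numeric(to_lab(const_tile(230, 200, 215, 1))))
  # each planted center matched by exactly one pattern
  d <- as.matrix(dist(rbind(means, planted)))[1:2, 3:4]
  expect_lt(max(apply(d, 2, min)), 0.02)
  expect_lt(max(sapply(pats, function(p) max(p$stats$std))), 0.02)

  # single constant corpus, k = 1: mean equals the color, std 0
  p1 <- derive_color_patterns(list(x = list(const_tile(100, 50, 150, 8))),
                              k_total = 1, seed = 1)
  expect_equal(as.numeric(p1[[1]]$stats$mean),
               as.numeric(to_lab(const_tile(100, 50, 150, 1))),
               tolerance = 1e-6)

  expect_error(derive_color_patterns(list(a = list())), "empty")
})

test_that("four patterns from two corpora are deterministic and tagged", {
  corp <- list(
    site_a = lapply(1:3, function(i) generate_texture("SO", 48, "site_a", i)),
    site_b = lapply(1:3, function(i) generate_texture("SO", 48, "site_b", i))
  )
  p1 <- derive_color_patterns(corp, k_total = 4, seed = 7,
                              pixels_per_corpus = 2000)
  p2 <- derive_color_patterns(corp, k_total = 4, seed = 7,
                              pixels_per_corpus = 2000)
  expect_length(p1, 4)
  expect_identical(lapply(p1, `[[`, "stats"), lapply(p2, `[[`, "stats"))
  expect_equal(table(vapply(p1, `[[`, character(1), "provenance")),
               table(rep(c("site_a", "site_b"), 2)), ignore_attr = TRUE)
  ids <- vapply(p1, `[[`, character(1), "pattern_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("patterns serialize to JSON and back losslessly", {
  pats <- derive_color_patterns(
    list(a = list(generate_texture("AC", 48, "site_a", 1))),
    k_total = 2, seed = 1, pixels_per_corpus = 1000)
  path <- withr::local_tempfile(fileext = ".json")
  write_color_patterns(pats, path)
  back <- read_color_patterns(path)
  for (i in seq_along(pats)) {
    expect_equal(back[[i]]$stats$mean, pats[[i]]$stats$mean)
    expect_equal(back[[i]]$stats$std, pats[[i]]$stats$std)
    expect_identical(back[[i]]$pattern_id, pats[[i]]$pattern_id)
  }
})
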