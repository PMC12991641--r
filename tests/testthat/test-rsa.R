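test_that("RSM entries equal brute-force per-pair Pearson + atanh", {
  set.seed(31)
  a <- matrix(stats::rnorm(12), 3, 4)
  meta <- toy_meta(3, c("cue1", "cue1", "cue2"), c("CS++", "CS++", "CS+-"))
  rsm <- build_rsm(toy_series(a, meta))
  expect_equal(rsm$z, rsm_oracle(a), tolerance = 1e-12)
  expect_true(all(is.na(diag(rsm$z))))
  expect_equal(rsm$z, t(rsm$z))
  # rectangular cross-series case
  b <- matrix(stats::rnorm(8), 2, 4)
  meta_b <- toy_meta(2, "cue1", "CS++", phase = "test_old")
  rsm_x <- build_rsm(toy_series(a, meta), toy_series(b, meta_b))
  expect_equal(rsm_x$z, rsm_oracle(a, b), tolerance = 1e-12)
  expect_false(rsm_x$within)
})

test_that("a near-identical pattern pair gives a large but finite z", {
  x <- stats::rnorm(50)
  y <- x
  y[1] <- y[1] + 1e-4
  a <- rbind(x, y)
  rsm <- build_rsm(toy_series(a, toy_meta(2, "cue1", "CS++")))
  expect_true(is.finite(rsm$z[1, 2]))
  expect_gt(rsm$z[1, 2], 5)
})

test_that("zero-variance patterns are flagged and excluded from masks", {
  a <- rbind(stats::rnorm(6), rep(1, 6), stats::rnorm(6))
  meta <- toy_meta(3, "cue1", "CS++")
  expect_warning(rsm <- build_rsm(toy_series(a, meta)), "zero-variance")
  expect_true(all(is.na(rsm$z[2, ])))
  m <- make_pair_mask(rsm, "same_item", restrict_unreinforced = FALSE)
  expect_false(any(m[2, ]))
  expect_equal(attr(m, "n_pairs"), 1)  # only the (1,3) pair survives
})

test_that("pair masks count the combinatorics of the paradigm", {
  spec <- quick_spec()
  d <- build_phase_design(spec, "acquisition", 41L)
  n <- nrow(d)
  betas <- matrix(stats::rnorm(n * 10), n, 10)
  rsm <- build_rsm(toy_series(betas, as.data.frame(d)))
  # a CS+ cue has 8 unreinforced of 16 presentations: C(8,2) = 28 pairs
  plus_cue <- names(spec$cs_type_map)[spec$cs_type_map == "CS++"][1]
  m <- make_pair_mask(rsm, "same_item", TRUE, cue_id = plus_cue)
  expect_equal(attr(m, "n_pairs"), choose(8, 2))
  # a CS- cue has all 16 unreinforced: C(16,2) = 120 pairs
  minus_cue <- names(spec$cs_type_map)[spec$cs_type_map == "CS--"][1]
  m2 <- make_pair_mask(rsm, "same_item", TRUE, cue_id = minus_cue)
  expect_equal(attr(m2, "n_pairs"), choose(16, 2))
  # same-item and same-type-different-item are disjoint
  m3 <- make_pair_mask(rsm, "same_cstype_different_item", TRUE)
  m4 <- make_pair_mask(rsm, "same_item", TRUE)
  expect_false(any(m3 & m4))
  # cross-phase categories are rejected on square RSMs
  expect_error(make_pair_mask(rsm, "cross_same_item", TRUE), "within-phase")
})

test_that("item stability averages atanh values as hand arithmetic says", {
  # two same-item pairs with r = 0.3 and r = 0.5:
  # (atanh(.3) + atanh(.5)) / 2 = (0.3095 + 0.5493) / 2 = 0.4294
  z <- matrix(NA_real_, 3, 3)
  z[1, 2] <- z[2, 1] <- atanh(0.3)
  z[1, 3] <- z[3, 1] <- atanh(0.5)
  z[2, 3] <- z[3, 2] <- atanh(0.9)  # different-item pair, must be ignored
  meta <- toy_meta(3, c("cue1", "cue1", "cue1"), "CS++")
  rsm <- structure(list(z = z, meta_row = meta, meta_col = meta,
                        within = TRUE, phases = c("acquisition", "acquisition")),
                   class = "rsm")
  rsm$z[2, 3] <- rsm$z[3, 2] <- NA  # keep only the two same-item pairs
  got <- mean(rsm$z[make_pair_mask(rsm, "same_item", FALSE)])
  expect_equal(got, 0.4294, tolerance = 1e-4)
  expect_equal(got, (atanh(0.3) + atanh(0.5)) / 2, tolerance = 1e-12)
})

test_that("every masked metric equals the pair-enumeration oracle", {
  set.seed(55)
  for (rep in 1:5) {
    n <- sample(c(16, 24, 32), 1)
    meta <- data.frame(
      phase = "acquisition", trial_index = seq_len(n) - 1L,
      cue_id = sprintf("cue%d", rep_len(1:8, n)),
      cs_type = NA, context_id = sample(sprintf("ctx%02d", 1:4), n, TRUE),
      reinforced = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8))
    )
    # keep two unreinforced presentations of every cue so no mask is empty
    meta$reinforced[1:16] <- FALSE
    cue_type <- setNames(rep(cs_types(), 2), sprintf("cue%d", 1:8))
    meta$cs_type <- unname(cue_type[meta$cue_id])
    betas <- matrix(stats::rnorm(n * 12), n, 12)
    series <- toy_series(betas, meta)
    rsm <- build_rsm(series)
    z <- rsm_oracle(betas)
    ok <- !meta$reinforced

    st <- item_stability(rsm, TRUE)
    for (k in seq_len(nrow(st$per_cue))) {
      cue <- st$per_cue$cue_id[k]
      want <- metric_oracle(z, meta, meta, function(a, b) {
        a$cue_id == cue && b$cue_id == cue && !a$reinforced && !b$reinforced
      })
      expect_equal(st$per_cue$value[k], want, tolerance = 1e-12)
    }

    gen <- cue_generalization(rsm, TRUE)
    for (k in seq_len(nrow(gen))) {
      cs <- gen$cs_type[k]
      want <- metric_oracle(z, meta, meta, function(a, b) {
        a$cs_type == cs && b$cs_type == cs && a$cue_id != b$cue_id &&
          !a$reinforced && !b$reinforced
      })
      expect_equal(gen$value[k], want, tolerance = 1e-12)
    }

    spec_got <- context_specificity(rsm, TRUE)
    within <- metric_oracle(z, meta, meta, function(a, b) {
      a$context_id == b$context_id && !a$reinforced && !b$reinforced
    })
    between <- metric_oracle(z, meta, meta, function(a, b) {
      a$context_id != b$context_id && !a$reinforced && !b$reinforced
    })
    expect_equal(spec_got, within - between, tolerance = 1e-12)

    # cross-phase reinstatement against the same oracle
    n2 <- n
    meta2 <- meta
    meta2$phase <- "test_old"
    meta2$reinforced <- FALSE
    betas2 <- matrix(stats::rnorm(n2 * 12), n2, 12)
    rsm_x <- build_rsm(series, toy_series(betas2, meta2))
    zx <- rsm_oracle(betas, betas2)
    for (mode in c("item", "generalized")) {
      re <- reinstatement(rsm_x, mode, TRUE)
      for (k in seq_len(nrow(re))) {
        cs <- re$cs_type[k]
        want <- metric_oracle(zx, meta, meta2, function(a, b) {
          same_cue <- a$cue_id == b$cue_id
          pick <- if (mode == "item") same_cue else !same_cue
          a$cs_type == cs && b$cs_type == cs && pick &&
            !a$reinforced && !b$reinforced
        }, within = FALSE)
        expect_equal(re$value[k], want, tolerance = 1e-12)
      }
    }
  }
})

test_that("metrics are invariant to simultaneous trial permutation", {
  set.seed(77)
  n <- 24
  meta <- toy_meta(n, sprintf("cue%d", rep_len(1:8, n)),
                   rep_len(cs_types(), n),
                   context_id = sprintf("ctx%02d", rep_len(1:4, n)))
  betas <- matrix(stats::rnorm(n * 15), n, 15)
  r1 <- build_rsm(toy_series(betas, meta))
  perm <- sample(n)
  r2 <- build_rsm(toy_series(betas[perm, ], meta[perm, ]))
  expect_equal(cue_generalization(r1, FALSE), cue_generalization(r2, FALSE),
               tolerance = 1e-12)
  expect_equal(item_stability(r1, FALSE)$per_cs_type,
               item_stability(r2, FALSE)$per_cs_type, tolerance = 1e-12)
  expect_equal(context_specificity(r1, FALSE), context_specificity(r2, FALSE),
               tolerance = 1e-12)
})

test_that("specificity decomposes exactly into stability minus generalization", {
  set.seed(78)
  n <- 20
  meta <- toy_meta(n, "cue1", "CS--",
                   context_id = sprintf("ctx%02d", rep_len(1:5, n)))
  rsm <- build_rsm(toy_series(matrix(stats::rnorm(n * 9), n, 9), meta))
  expect_identical(
    context_specificity(rsm),
    context_stability(rsm) - context_generalization(rsm)
  )
  # single-context phase errors
  meta1 <- toy_meta(5, "cue1", "CS--", context_id = "ctx01")
  rsm1 <- build_rsm(toy_series(matrix(stats::rnorm(5 * 9), 5, 9), meta1))
  expect_error(context_specificity(rsm1), "2 contexts")
})

test_that("shared context patterns yield near-zero specificity", {
  geom <- tiny_geometry()
  bank <- make_pattern_bank(geom, 21L)
  d <- build_phase_design(quick_spec(), "acquisition", 51L)
  meta <- as.data.frame(d)
  # all context trials drawn from one shared pattern + noise
  shared <- bank$patterns[, "ctx01"]
  betas <- matrix(rep(shared, each = 128), 128) +
    matrix(stats::rnorm(128 * length(shared), 0, 0.5), 128)
  spec_val <- context_specificity(build_rsm(toy_series(betas, meta, "context")))
  expect_lt(abs(spec_val), 0.05)
})

test_that("empty masks raise explicit errors", {
  meta <- toy_meta(4, "cue1", "CS++", reinforced = TRUE)
  rsm <- build_rsm(toy_series(matrix(stats::rnorm(20), 4, 5), meta))
  expect_error(item_stability(rsm, TRUE), "empty pair mask")
})
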