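test_that("f0 screening is a strict-boundary exhaustive partition", {
  tok <- vowel_tokens(rep("s1", 3), rep("IDS", 3), rep("i", 3),
                      median_f0 = c(200, 350, 351),
                      f1 = rep(400, 3), f2 = rep(2000, 3))
  res <- exclude_high_f0(tok)
  expect_equal(res$kept$median_f0, c(200, 350))   # 350 itself is kept
  expect_equal(res$excluded$median_f0, 351)
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(tok))
  expect_equal(nrow(res$log), 1)
  expect_match(res$log$reason, "exceeds 350")

  expect_equal(nrow(exclude_high_f0(tok[1:2, ])$excluded), 0)
  res250 <- exclude_high_f0(tok, threshold = 250)
  expect_equal(res250$kept$median_f0, 200)
  # lowering the threshold never shrinks the excluded set
  expect_true(all(res$excluded$token_id %in% res250$excluded$token_id))
})

test_that("mid-window mean selects samples by timestamp", {
  f1 <- c(100, 100, 100, 400, 400, 400, 400, 400, 100, 100, 100)
  tr <- formant_track(seq(0, 1, length.out = 11), f1, rep(1500, 11))
  est <- mid_window_mean(tr, 0.4)
  expect_equal(est[["f1"]], 400)   # samples at relative times 0.3..0.7
  expect_equal(est[["f2"]], 1500)

  # constant track: invariant for every fraction
  const <- formant_track(c(0, 0.013, 0.05, 0.08), rep(500, 4), rep(1500, 4))
  for (fr in c(0.1, 0.4, 0.77, 1)) {
    expect_equal(mid_window_mean(const, fr), c(f1 = 500, f2 = 1500))
  }

  # single-sample and empty-window fallbacks
  single <- formant_track(0.05, 430, 940)
  expect_equal(mid_window_mean(single), c(f1 = 430, f2 = 940))
  two <- formant_track(c(0, 1), c(300, 600), c(1000, 2000))
  expect_equal(mid_window_mean(two, 0.1), c(f1 = 300, f2 = 1000))

  expect_error(mid_window_mean(formant_track(0.1, 500, 1500)[0, ]), "empty")
  expect_error(formant_track(c(0, 0), c(1, 1), c(1, 1)), "strictly increasing")
})

test_that("mid-windowing reduces coarticulation bias on ramped tracks", {
  withr::local_seed(5)
  cfg <- sim_config()
  better <- 0L
  n <- 300
  for (i in seq_len(n)) {
    steady_f1 <- runif(1, 300, 800); steady_f2 <- runif(1, 800, 2400)
    tr <- phonadapt:::simulate_track(steady_f1, steady_f2, cfg$track)
    mid <- mid_window_mean(tr, 0.4)
    full <- c(f1 = mean(tr$f1), f2 = mean(tr$f2))
    truth <- c(f1 = steady_f1, f2 = steady_f2)
    if (sqrt(sum((mid - truth)^2)) < sqrt(sum((full - truth)^2))) {
      better <- better + 1L
    }
  }
  expect_gte(better / n, 0.95)
})

test_that("vsa reproduces the triangle areas derived from the group means", {
  ids <- data.frame(vowel = c("i", "a", "u"), f1 = c(453, 656, 430),
                    f2 = c(1972, 1383, 934))
  ads <- data.frame(vowel = c("i", "ɑ", "u"), f1 = c(472, 661, 473),
                    f2 = c(1904, 1307, 1032))
  expect_equal(vsa(ids), 112130.5)
  expect_equal(vsa(ads), 82105.5)
  coll <- data.frame(vowel = c("i", "a", "u"), f1 = c(100, 200, 300),
                     f2 = c(100, 200, 300))
  expect_equal(vsa(coll), 0)
  expect_error(vsa(data.frame(vowel = c("i", "a"), f1 = 1:2, f2 = 1:2)),
               "point vowel")
})

test_that("vsa is a proper area: invariances and scaling", {
  withr::local_seed(31)
  for (i in 1:200) {
    m <- data.frame(vowel = c("i", "a", "u"),
                    f1 = runif(3, 200, 900), f2 = runif(3, 700, 2600))
    a <- vsa(m)
    expect_equal(a, oracle_shoelace(m$f1, m$f2), tolerance = 1e-9)
    # translation invariance
    m2 <- m; m2$f1 <- m2$f1 + 57; m2$f2 <- m2$f2 + 1000
    expect_equal(vsa(m2), a, tolerance = 1e-12)
    # row-order permutation invariance
    expect_equal(vsa(m[sample(3), ]), a)
    # quadratic scaling under uniform frequency scaling
    m3 <- m; m3$f1 <- 1.7 * m3$f1; m3$f2 <- 1.7 * m3$f2
    expect_equal(vsa(m3), 1.7^2 * a, tolerance = 1e-9)
  }
})

test_that("hz_to_bark matches the adopted transform and is monotone", {
  expect_equal(hz_to_bark(1960), 12.875)
  expect_equal(hz_to_bark(1000), 8.5274, tolerance = 1e-4)
  f <- sort(runif(200, 20, 16000))
  expect_true(all(diff(hz_to_bark(f)) > 0))
  # low-end correction region still monotone and continuous-ish
  expect_lt(hz_to_bark(100), hz_to_bark(150))
  expect_error(hz_to_bark(0), "positive")
  expect_error(hz_to_bark(-5), "positive")
})

test_that("point-vowel means average per token, Bark conversion first", {
  tok <- vowel_tokens(rep("p1", 4), rep("IDS", 4), c("i", "i", "a", "u"),
                      median_f0 = rep(220, 4),
                      f1 = c(440, 466, 656, 430), f2 = c(1950, 1994, 1383, 934))
  sv <- point_vowel_means(tok, "p1", "IDS", scale = "hz")
  expect_equal(sv$means$f1[sv$means$vowel == "i"], 453)
  expect_equal(sv$means$f2[sv$means$vowel == "i"], 1972)
  expect_equal(sv$means$n_tokens, c(2L, 1L, 1L))
  expect_equal(sv$area, vsa(sv$means))

  svb <- point_vowel_means(tok, "p1", "IDS", scale = "bark")
  expect_equal(svb$means$f2[svb$means$vowel == "i"],
               mean(hz_to_bark(c(1950, 1994))))   # per-token, then average
  expect_equal(svb$scale, "bark")

  expect_error(point_vowel_means(tok[1:3, ], "p1", "IDS"), "u")
})

# identical areas via a register-relabelled copy
ids_to_ads <- function(sv) {
  sv$register <- "ADS"
  sv
}

test_that("vsa differences are signed and guard speaker/scale mismatches", {
  mk <- function(sp, reg, f1s, scale = "hz") {
    tok <- vowel_tokens(rep(sp, 3), rep(reg, 3), c("i", "a", "u"),
                        median_f0 = rep(200, 3), f1 = f1s,
                        f2 = c(1972, 1383, 934))
    point_vowel_means(tok, scale = scale)
  }
  ids <- mk("p1", "IDS", c(453, 656, 430))
  ads <- mk("p1", "ADS", c(472, 661, 473))
  d <- vsa_difference(ids, ads)
  expect_equal(d$difference, d$vsa_ids - d$vsa_ads)

  # hypoarticulation (negative difference) is preserved, not clamped
  d2 <- vsa_difference(mk("p1", "IDS", c(472, 661, 473)),
                       mk("p1", "ADS", c(453, 656, 430)))
  expect_lt(d2$difference, 0)
  expect_equal(vsa_difference(ids, ids_to_ads(ids))$difference, 0)

  expect_error(vsa_difference(ids, mk("p1", "ADS", c(472, 661, 473), "bark")),
               "scale mismatch")
  expect_error(vsa_difference(ids, mk("p2", "ADS", c(472, 661, 473))),
               "speaker mismatch")
})
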