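test_that("centroid expansion scales area quadratically, exactly", {
  ads <- tibble::tibble(vowel = c("i", "ɑ", "u"), f1 = c(472, 661, 473),
                        f2 = c(1904, 1307, 1032))
  for (fac in c(0.8, 1, 1.36, 2)) {
    expect_equal(vsa(expand_triangle(ads, fac)), fac^2 * vsa(ads),
                 tolerance = 1e-12)
  }
  # centroid itself is unchanged
  ex <- expand_triangle(ads, 1.36)
  expect_equal(mean(ex$f1), mean(ads$f1))
  expect_equal(mean(ex$f2), mean(ads$f2))
})

test_that("a noiseless generator round-trips to exact ground truth", {
  cfg <- sim_config(n_dyads = 3, noise_scale = 0, token_form = "point",
                    resid_sd = 0,
                    f0 = list(IDS = list(mean = 240, sd = 0, exceed_rate = 0),
                              ADS = list(mean = 200, sd = 0, exceed_rate = 0)))
  ds <- simulate_study(cfg, seed = 9)
  est <- speaker_vsa_table(ds$tokens)
  m <- merge(est$table, ds$truth, by = "speaker_id")
  expect_equal(m$vsa_ids, m$vsa_ids_true, tolerance = 1e-9)
  expect_equal(m$vsa_ads, m$vsa_ads_true, tolerance = 1e-9)
  expect_equal(m$difference, m$difference_true, tolerance = 1e-9)
  # every dyad shares the same true areas (no between-speaker noise)
  expect_equal(ds$truth$vsa_ads_true, rep(vsa(cfg$ads_means), 3))
  expect_equal(ds$truth$vsa_ids_true / ds$truth$vsa_ads_true, rep(1.36^2, 3))
})

test_that("track tokens with no ramps and no jitter are exact too", {
  cfg <- sim_config(noise_scale = 0,
                    track = list(frame_step = 0.01, duration_range = c(0.1, 0.2),
                                 ramp_fraction = 0, ramp_depth = 0,
                                 neutral = c(f1 = 500, f2 = 1500), noise_sd = 0))
  withr::local_seed(3)
  mu <- phonadapt:::simulate_speaker_means(cfg)
  tok <- simulate_tokens(cfg, "p1", "IDS", speaker_means = mu$IDS)
  sv <- point_vowel_means(exclude_high_f0(tok)$kept)
  expect_equal(sv$area, vsa(mu$IDS), tolerance = 1e-9)
})

test_that("f0 exceedance follows the configured rate", {
  cfg <- sim_config(tokens_per_vowel = list(IDS = c(i = 400, "ɑ" = 400, u = 200),
                                            ADS = c(i = 1, "ɑ" = 1, u = 1)),
                    f0 = list(IDS = list(mean = 240, sd = 40, exceed_rate = 0.2),
                              ADS = list(mean = 200, sd = 30, exceed_rate = 0)))
  tok <- simulate_tokens(cfg, "p1", "IDS", seed = 14)
  frac <- mean(tok$median_f0 > 350)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(frac - 0.2), 3 * se)
  # and the screening stage excludes exactly those tokens
  res <- exclude_high_f0(tok)
  expect_setequal(res$excluded$token_id, tok$token_id[tok$median_f0 > 350])
})

test_that("degenerate targets produce exactly the promised corpora", {
  zeros <- simulate_vocalizations(0, 50, seed = 1)
  expect_true(all(zeros == "ma"))
  expect_true(all(score_corpus(zeros)$total == 0))

  trill_only <- sim_config(feature_weights = c(
    tri = 0, stress = 0, final = 0, cluster = 0, velar = 0, liquid = 0,
    fricative = 0, voiced_fricative = 0, trill = 1, lfrv = 0))
  threes <- simulate_vocalizations(3, 50, trill_only, seed = 2)
  expect_true(all(score_corpus(threes)$total == 3))

  expect_error(simulate_vocalizations(20, 5, seed = 3), "unreachable")
  expect_error(simulate_vocalizations(4, 5, trill_only, seed = 3), "unreachable")
  expect_error(simulate_vocalizations(-1, 5, seed = 3), "non-negative")
})

test_that("analytic expectation matches enumeration through the real scorer", {
  cfg <- sim_config()
  for (target in c(0.4, 1.23, 2.5, 4.69)) {
    p <- calibrate_wcm_probs(target, cfg$feature_weights)
    expect_equal(expected_wcm_se(p), target, tolerance = 1e-8)
    # exact enumeration over all feature patterns, scored by the pipeline
    feats <- names(p)
    grid <- as.matrix(expand.grid(rep(list(0:1), length(feats))))
    colnames(grid) <- feats
    probs <- apply(grid, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
    keep <- probs > 0
    scores <- apply(grid[keep, , drop = FALSE], 1, function(x) {
      s <- phonadapt:::render_vocalization(x)
      score_vocalization(parse_transcription(s))$total
    })
    expect_equal(sum(probs[keep] * scores), target, tolerance = 1e-8)
  }
})

test_that("empirical corpus means converge to the calibrated expectation", {
  target <- 1.23
  vocs <- simulate_vocalizations(target, 10000, seed = 6)
  totals <- score_corpus(vocs)$total
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - target), 3 * se)
})

test_that("every generated dataset survives the full pipeline unharmed", {
  cfg <- sim_config(n_dyads = 6, token_form = "point", n_vocalizations = 15)
  for (seed in c(21, 22)) {
    ds <- simulate_study(cfg, seed = seed)
    expect_equal(nrow(ds$truth), 6)
    expect_equal(nrow(ds$transcriptions), 6 * 15)
    res <- run_study(ds$tokens, ds$transcriptions, study_config())
    expect_equal(res$audit$n_vocalizations_failed, 0)
    expect_equal(res$audit$n_speakers, 6)
    # estimates track truth even at full study-scale token noise
    m <- merge(res$vsa$hz$table, ds$truth, by = "speaker_id")
    expect_gt(cor(m$difference, m$difference_true), 0.7)
  }
  # with token noise dialled down the estimate is nearly the truth
  quiet <- simulate_study(sim_config(n_dyads = 6, token_form = "point",
                                     n_vocalizations = 15, within_scale = 0.2),
                          seed = 23)
  est <- speaker_vsa_table(quiet$tokens)$table
  m <- merge(est, quiet$truth, by = "speaker_id")
  expect_gt(cor(m$difference, m$difference_true), 0.95)
})

test_that("a null slope is recovered as centred on zero", {
  cfg <- sim_config(n_dyads = 25, token_form = "point", beta_true = 0,
                    noise_scale = 0.3, resid_sd = 0.1, n_vocalizations = 10)
  withr::local_seed(55)
  betas <- replicate(25, {
    ds <- simulate_study(cfg)
    smry <- subject_wcm_table(ds$transcriptions)
    est <- speaker_vsa_table(ds$tokens)$table
    joined <- merge(smry, est, by.x = "subject_id", by.y = "speaker_id")
    fit_regression(joined$difference, joined$mean_score)$beta
  })
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas)), 2 * mc_se + 1e-12)
})

test_that("deterministic given a seed", {
  a <- simulate_study(sim_config(n_dyads = 3, token_form = "point"), seed = 101)
  b <- simulate_study(sim_config(n_dyads = 3, token_form = "point"), seed = 101)
  expect_identical(a$tokens, b$tokens)
  expect_identical(a$transcriptions, b$transcriptions)
  expect_identical(a$truth, b$truth)
})
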