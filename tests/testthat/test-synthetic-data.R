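test_that("set and pool expectations follow the mixture closed form", {
  # all weights equal: every set of the preferred order reads S0 * w^6
  w <- matrix(0.5, 6, 19, dimnames = list(sprintf("P%+d", c(-3, -2, -1, 1, 2, 3)),
                                          kme_alphabet()))
  m <- latent_reader_model(position_weights = w, S0 = 2000)
  expect_equal(expected_set_signal(m, 3, -2, "A"), 2000 * 0.5^6)
  expect_equal(expected_pool_signal(m, 3), 2000 * 0.5^6)

  # one-hot weights: pool/S0 = ((1 + 18 eps) / 19)^6, far below the best set
  sm <- specific_model(epsilon = 0.01, noise_sd = 0)
  ratio <- expected_pool_signal(sm, 3) / sm$S0
  expect_equal(ratio, ((1 + 18 * 0.01) / 19)^6)
  best <- expected_set_signal(sm, 3, -3, "K")
  expect_gt(best / expected_pool_signal(sm, 3), 10)

  # a zero order weight silences that pool
  m0 <- latent_reader_model(order_weights = c(0, 0.05, 0.25, 1))
  expect_equal(expected_pool_signal(m0, 0), 0)
})

test_that("the mean of the 19 set expectations at any position equals the pool", {
  set.seed(13)
  w <- matrix(runif(6 * 19, 0.05, 1), 6, 19,
              dimnames = list(sprintf("P%+d", c(-3, -2, -1, 1, 2, 3)),
                              kme_alphabet()))
  m <- latent_reader_model(position_weights = w)
  for (order in 0:3) {
    pool <- expected_pool_signal(m, order)
    for (p in kme_positions()) {
      sets <- vapply(kme_alphabet(), function(a)
        expected_set_signal(m, order, p, a), numeric(1))
      expect_equal(mean(sets), pool, tolerance = 1e-12)
    }
  }
})

test_that("set expectations agree with Monte-Carlo averages over sampled peptides", {
  # independent oracle: draw peptides from the set's degenerate composition
  # and average the product binding model directly
  sm <- specific_model(epsilon = 0.2, noise_sd = 0)
  w <- sm$position_weights
  set.seed(77)
  for (case in list(c(-2, "A"), c(2, "K"), c(-3, "W"))) {
    p <- as.integer(case[1]); a <- case[2]
    n <- 20000
    prod_w <- rep(sm$S0 * sm$order_weights[4], n)
    for (q in kme_positions()) {
      res <- if (q == p) rep(a, n) else sample(kme_alphabet(), n, TRUE)
      prod_w <- prod_w * w[sprintf("P%+d", q), res]
    }
    mc <- mean(prod_w)
    # the product across 5 free positions has relative SD ~ 2.8, so the MC
    # mean has relative SE ~ 2.8 / sqrt(n); allow ~5 SE
    expect_equal(mc, expected_set_signal(sm, 3, p, a),
                 tolerance = 14 / sqrt(n))
  }
})

test_that("plate simulation is exact at zero noise and bit-reproducible", {
  m <- specific_model(noise_sd = 0)
  plate <- simulate_plate(m, n_replicates = 2, seed = 4)
  sets <- plate[!plate$pool & plate$methyl_order == 3, ]
  mu <- mapply(function(p, a) expected_set_signal(m, 3, p, a),
               sets$fixed_position, sets$fixed_residue)
  expect_equal(sets$signal, mu + m$gst_background, tolerance = 1e-12)
  expect_equal(unique(plate$gst_signal), m$gst_background)

  m2 <- specific_model(noise_sd = 50)
  p1 <- simulate_plate(m2, n_replicates = 4, seed = 99)
  p2 <- simulate_plate(m2, n_replicates = 4, seed = 99)
  expect_identical(p1, p2)
  p3 <- simulate_plate(m2, n_replicates = 4, seed = 100)
  expect_false(identical(p1$signal, p3$signal))
})

test_that("simulated plates cover the full library with matched GST wells", {
  m <- latent_reader_model()
  plate <- simulate_plate(m, n_replicates = 3, seed = 1)
  expect_equal(nrow(plate), (4 * 114 + 4) * 3)
  for (order in 0:3) {
    sets <- plate[!plate$pool & plate$methyl_order == order, ]
    expect_equal(length(unique(paste(sets$fixed_position,
                                     sets$fixed_residue))), 114)
  }
  expect_true(all(is.finite(plate$gst_signal)))
  expect_true(all(plate$signal >= 0))
})

test_that("proteome generation plants motifs at recorded interior positions", {
  pr <- generate_proteome(50, planted_motifs = c("KAKKTGK", "GGGKGGG"),
                          seed = 12)
  expect_equal(nrow(pr$manifest), 2)
  for (i in 1:2) {
    s <- pr$records[[pr$manifest$protein_id[i]]]
    k <- pr$manifest$k_position[i]
    expect_equal(substr(s, k - 3, k + 3), pr$manifest$window[i])
    expect_true(k >= 4 && k <= nchar(s) - 3)
  }
  expect_identical(generate_proteome(50, seed = 12)$records,
                   generate_proteome(50, seed = 12)$records)
  expect_equal(nrow(generate_proteome(5, seed = 1)$manifest), 0)
})

test_that("FP titration simulation inverts its own conversion and hits half-saturation", {
  tit <- simulate_fp_titration(kd = 2, hill = 1, amax = 0.1, baseline = 0.01,
                               concentrations = c(0.1, 0.5, 2, 8, 32, 128),
                               noise_sd = 0)
  # at x = kd the curve sits exactly halfway between baseline and amax
  expect_equal(tit$anisotropy[tit$concentration_uM == 2],
               0.01 + (0.1 - 0.01) / 2)
  # mP column is the exact inverse image of the anisotropy column
  expect_equal(polarization_to_anisotropy(tit$mP, mP = TRUE), tit$anisotropy)
})

test_that("YAML model configuration round-trips into a latent model", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preferred_order: 2", "epsilon: 0.3", "S0: 5000",
               "noise_sd: 25", "reader_id: cfg_reader", "seed: 7",
               "n_replicates: 2",
               "hot_residues: [A, A, A, T, T, T]"), cfg)
  got <- read_model_config(cfg)
  expect_equal(got$model$preferred_order, 2L)
  expect_equal(got$model$S0, 5000)
  expect_equal(got$model$position_weights["P-3", "A"], 1)
  expect_equal(got$model$position_weights["P-3", "G"], 0.3)
  expect_equal(got$seed, 7L)
  expect_equal(got$n_replicates, 2L)
})

test_that("planted optimal motifs are recovered end to end on a quiet plate", {
  m <- specific_model(noise_sd = 20)
  plate <- simulate_plate(m, n_replicates = 4, seed = 31, methyl_orders = 3L)
  prof <- build_profile(plate, methyl_order = 3)
  expect_equal(predict_optimal_sequence(prof)$window, "KAKKTGK")

  pr <- generate_proteome(60, planted_motifs = "KAKKTGK", seed = 32)
  res <- score_proteome(prof, pr$records)
  hit <- res[res$protein_id == pr$manifest$protein_id &
               res$k_position == pr$manifest$k_position, ]
  expect_equal(hit$rank, 1L)
  expect_equal(hit$norm_score, 1.0)
})
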