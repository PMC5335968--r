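test_that("db4 decomposition annihilates polynomials and halves lengths", {
  bands <- dwt_db4(rep(1, 512), 5)
  expect_named(bands, c("d1", "d2", "d3", "d4", "d5", "a5"))
  for (d in bands[1:5]) expect_lt(max(abs(d)), 1e-8)
  expect_equal(length(bands$d1), 259)  # (512 + 7) / 2, rounded down
  set.seed(8)
  x <- rnorm(1024)
  en <- sum(vapply(dwt_db4(x, 5), function(b) sum(b^2), numeric(1)))
  # symmetric extension adds boundary energy but stays the same order
  expect_gt(en, 0.9 * sum(x^2))
})

test_that("stage-1 features behave on degenerate and clean windows", {
  cfg <- pp_config()
  zero <- rep(0, 1000)
  f0 <- extract_stage1_features(zero, zero, zero, cfg)
  expect_length(f0, 24)
  expect_equal(unname(f0["energy_time"]), 0)
  expect_true(all(f0[grep("wv_energy", names(f0))] == 0))
  expect_equal(unname(f0["cc_spec_raw"]), 0)  # zero variance maps to 0

  tone <- make_tone(1.7, n = 1000)
  ft <- extract_stage1_features(tone, tone, zero, cfg)
  expect_equal(unname(ft["n_sig_peaks"]), 1)
  expect_equal(unname(ft["cc_spec_raw"]), 1)
  expect_gt(ft["energy_time"], 0)

  # purity: identical windows give bitwise-identical features
  expect_identical(ft, extract_stage1_features(tone, tone, zero, cfg))
})

test_that("Strong/NotStrong labels follow the truth-distance rule", {
  cfg <- pp_config()
  fs <- cfg$fs; N <- cfg$N
  truth <- 100
  on_bin <- make_tone(truth / 60, n = 1000)
  expect_equal(label_stage1(on_bin, truth, cfg), "NotStrong")

  off <- make_tone((truth + 10) / 60, n = 1000)
  expect_equal(label_stage1(off, truth, cfg), "Strong")

  cfg_inf <- pp_config(tol_bpm = Inf)
  expect_equal(label_stage1(off, truth, cfg_inf), "NotStrong")
})

test_that("the gate classifier separates separable clouds and is seeded", {
  cfg <- pp_config()
  clouds <- make_clouds(100, centers = c(0, 3), dim = 24, seed = 9)
  labels <- c("NotStrong", "Strong")[clouds$labels]
  fit <- train_stage1(clouds$features, labels, cfg, seed = 5)
  expect_gte(fit$cv$accuracy, 0.95)
  expect_true(all(c("sensitivity", "specificity") %in% names(fit$cv)))

  set.seed(10)
  null_fit <- train_stage1(clouds$features, sample(labels), cfg, seed = 5)
  expect_lt(abs(null_fit$cv$accuracy - 0.5), 0.1)

  fit2 <- train_stage1(clouds$features, labels, cfg, seed = 5)
  expect_identical(fit$cv, fit2$cv)

  dec <- decide_ma(fit, unlist(clouds$features[1, ]))
  expect_equal(dec, "NotStrong")
  dec2 <- decide_ma(fit, unlist(clouds$features[150, ]))
  expect_equal(dec2, "Strong")
  expect_error(decide_ma(list(), unlist(clouds$features[1, ])),
               "state error")
})

test_that("single-class or tiny training sets are refused", {
  clouds <- make_clouds(10, centers = c(0, 3), dim = 4, seed = 11)
  expect_error(train_stage1(clouds$features,
                            rep("Strong", 20), pp_config()),
               "training error")
})
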