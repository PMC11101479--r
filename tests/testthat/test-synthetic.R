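test_that("generation is deterministic under a fixed seed, down to the CSV
           bytes", {
  cfg <- synthetic_config(seed = 7)
  a <- generate_neural_population(cfg)
  b <- generate_neural_population(cfg)
  expect_identical(a, b)
  ca <- generate_csf_dataset(cfg)
  cb <- generate_csf_dataset(cfg)
  expect_identical(ca, cb)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_neural_csv(a, f1)
  write_neural_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  different <- generate_neural_population(synthetic_config(seed = 8))
  expect_false(identical(a$rate_dom, different$rate_dom))
})

test_that("default configuration reproduces the study-scale counts", {
  cfg <- synthetic_config(seed = 1)
  neu <- generate_neural_population(cfg)
  expect_equal(nrow(neu), 10 + 55 + 48)
  counts <- table(neu$truth_label)
  expect_equal(as.integer(counts[c("gate_facilitatory", "true_facilitatory",
                                   "suppressive_between",
                                   "suppressive_other")]),
               c(10L, 55L, 35L, 13L))
  csf <- generate_csf_dataset(cfg)
  expect_equal(nrow(csf), 9 * 6 + 25 * 6 + 45 * 5)
  expect_equal(sum(!csf$truth_enhancer) / 6, 5)  # five non-enhancing subjects
})

test_that("noiseless generation satisfies the generating equations exactly", {
  cfg <- synthetic_config(seed = 2, noise_cv = 0)
  neu <- generate_neural_population(cfg)
  gate <- neu[neu$truth_label == "gate_facilitatory", ]
  expect_true(all(abs(gate$rate_binoc -
                      2.2 * gate$rate_dom^0.84) < 1e-12 * gate$rate_binoc))
  true <- neu[neu$truth_label == "true_facilitatory", ]
  expect_true(all(abs(true$rate_binoc -
                      2.14 * true$rate_dom^0.89) < 1e-12 * true$rate_binoc))
  btw <- neu[neu$truth_label == "suppressive_between", ]
  pred <- schrodinger_combine(btw$rate_dom, btw$rate_nondom)$predicted
  expect_true(all(abs(btw$rate_binoc - pred) < 1e-12 * btw$rate_binoc))
  csf <- generate_csf_dataset(cfg)
  enh <- best_worst_split(csf[csf$truth_enhancer, ])
  expect_true(all(abs(enh$sens_binoc - 1.63 * enh$sens_best^0.93) <
                  1e-12 * enh$sens_binoc))
})

test_that("an identity CSF generator returns binocular equal to the better
           eye", {
  cfg <- synthetic_config(seed = 5, noise_cv = 0, csf_params = c(a = 1, n = 1),
                          n_nonenhancers = 0L)
  csf <- best_worst_split(generate_csf_dataset(cfg))
  expect_equal(csf$sens_binoc, csf$sens_best, tolerance = 1e-12)
})

test_that("firing-rate variance tracks firing-rate magnitude under both
           variance models", {
  poi <- generate_neural_population(synthetic_config(seed = 3))
  expect_equal(poi$var_dom, pmax(poi$rate_dom, 1e-2))
  ccv <- generate_neural_population(
    synthetic_config(seed = 3, variance_model = "constant_cv"))
  expect_equal(ccv$var_dom, pmax((0.15 * ccv$rate_dom)^2, 1e-2))
  expect_gt(cor(poi$var_nondom, poi$rate_nondom), 0.99)
})

test_that("pooled best-eye sensitivities span at least 1.5 decades", {
  csf <- best_worst_split(generate_csf_dataset(synthetic_config(seed = 4)))
  expect_gt(log10(max(csf$sens_best) / min(csf$sens_best)), 1.5)
})

test_that("the enhancement screen rejects exactly the generated
           non-enhancers at the default noise level", {
  csf <- generate_csf_dataset(synthetic_config(seed = 6))
  screen <- subject_enhancement_screen(csf)
  truth <- dplyr::distinct(csf[, c("study", "subject", "truth_enhancer")])
  joined <- dplyr::inner_join(screen, truth, by = c("study", "subject"))
  expect_equal(joined$include, joined$truth_enhancer)
})

test_that("classification recovers generator subtypes, with disagreements
           confined to noise-width boundary cases", {
  agree <- numeric(10)
  for (s in 1:10) {
    neu <- classify_neurons(generate_neural_population(
      synthetic_config(seed = s)))
    hit <- as.character(neu$class) == neu$truth_label
    agree[s] <- mean(hit)
    # suppressive subtypes are defined by where the rate fell: always exact
    sup <- neu$truth_label %in% c("suppressive_between", "suppressive_other")
    expect_true(all(hit[sup]))
    # disagreements are facilitatory neurons whose noisy binocular rate fell
    # at or below the facilitation boundary: they land in the adjacent
    # classes, never in strong suppression
    bad <- neu[!hit, ]
    if (nrow(bad) > 0) {
      expect_true(all(bad$rate_binoc <= bad$rate_dom * 1.05))
      expect_true(all(as.character(bad$class) %in%
                        c("suppressive_between", "non_interacting")))
    }
  }
  expect_gt(mean(agree), 0.90)
})

test_that("generator statistical closure: seed-averaged recovery of the
           generating exponents is unbiased", {
  n_hat <- vapply(1:50, function(s) {
    neu <- generate_neural_population(synthetic_config(seed = s))
    true <- neu[neu$truth_label == "true_facilitatory", ]
    fit_power_law(true$rate_dom, true$rate_binoc)$n
  }, numeric(1))
  expect_lt(abs(mean(n_hat) - 0.89), 0.02)
  m_hat <- vapply(1:50, function(s) {
    csf <- generate_csf_dataset(
      synthetic_config(seed = s, generator_csf = "minkowski"))
    enh <- best_worst_split(csf[csf$truth_enhancer, ])
    fit_minkowski_global(enh$sens_best, enh$sens_worst, enh$sens_binoc)$m
  }, numeric(1))
  expect_lt(abs(mean(m_hat) - 2.65), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_between = 40, n_suppressive = 30),
               "n_between")
  expect_error(synthetic_config(noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_config(generator_neural = "nope"))
  expect_error(synthetic_config(n_nonenhancers = 50), "exceeds")
})
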