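test_that("cohort spec validation names the violated field", {
  expect_error(cohort_spec(n_sf = -1), "n_sf")
  expect_error(cohort_spec(n_sf = 0, n_nsf = 1), "at least 2")
  expect_error(cohort_spec(effect_size = -0.1), "effect_size")
  expect_error(cohort_spec(sampling_rate = 50), "sampling_rate")
  expect_error(cohort_spec(channels = c("Fp1", "Fp1")), "channels")
})

test_that("identical spec and seed give bit-identical cohorts", {
  s <- tiny_spec(n_sf = 3, n_nsf = 2, seed = 7)
  expect_identical(generate_cohort(s), generate_cohort(s))
  # a different seed changes the signals
  s2 <- tiny_spec(n_sf = 3, n_nsf = 2, seed = 8)
  expect_false(identical(generate_cohort(s)[[1]]$recording,
                         generate_cohort(s2)[[1]]$recording))
})

test_that("cohort shape matches the spec (class sizes, channels, samples)", {
  coh <- generate_cohort(tiny_spec(n_sf = 4, n_nsf = 2, seed = 9))
  expect_length(coh, 6)
  labs <- vapply(coh, `[[`, "", "label")
  expect_equal(sum(labs == "SF"), 4)
  expect_equal(sum(labs == "NSF"), 2)
  rec <- coh[[1]]$recording
  expect_equal(nrow(rec$data), 19)
  expect_equal(ncol(rec$data), 2 * 15 * 256)
  expect_identical(rec$channel_labels, default_channels())
  # reference cohort shape at the default class sizes
  clin <- generate_clinical(52, 22, seed = 1)
  expect_equal(nrow(clin), 74)
  expect_equal(sum(clin$label == "SF"), 52)
})

test_that("clinical marginals converge to the reference tables", {
  clin <- generate_clinical(5000, 2100, seed = 41)
  counts <- clinical_reference_counts()
  for (f in c("sex", "perinatal_injury", "circadian_rhythm", "mri")) {
    ref <- counts[[f]]
    for (cl in c("SF", "NSF")) {
      obs <- table(factor(clin[[f]][clin$label == cl],
                          levels = colnames(ref)))
      gof <- chisq.test(obs, p = ref[cl, ] / sum(ref[cl, ]))
      expect_gt(gof$p.value, 0.01)
    }
  }
  # quantitative calibration: follow-up is normal with the stated moments
  fu <- clin$follow_up[clin$label == "SF"]
  expect_equal(mean(fu), 32.58, tolerance = 0.02)
  expect_equal(sd(fu), 9.83, tolerance = 0.05)
  # skewed variables match the stated medians
  expect_equal(median(clin$age[clin$label == "NSF"]), 16.5, tolerance = 0.05)
})

test_that("effect_size = 0 removes every class difference", {
  clin <- generate_clinical(3000, 3000, effect_size = 0, seed = 43)
  for (f in c("perinatal_injury", "seizure_freq_before_oxc")) {
    sf <- clin[[f]][clin$label == "SF"]
    nsf <- clin[[f]][clin$label == "NSF"]
    if (is.numeric(sf)) {
      expect_lt(abs(median(sf) - median(nsf)), 0.3)
    } else {
      expect_lt(abs(mean(sf == "Y") - mean(nsf == "Y")), 0.04)
    }
  }
  plan <- oxceeg:::.cohort_plan(cohort_spec(n_sf = 200, n_nsf = 200,
                                            effect_size = 0, seed = 3,
                                            n_epochs_per_subject = 1))
  nf <- plan$noise_fraction
  labs <- plan$labels
  expect_lt(abs(mean(nf[labs == "SF"]) - mean(nf[labs == "NSF"])), 0.02)
})

test_that("the planted complexity effect is monotone in effect_size", {
  gaps <- vapply(c(0, 0.3, 0.6), function(e) {
    per_seed <- vapply(1:10, function(s) {
      fm <- cohort_feature_matrix(tiny_spec(n_sf = 3, n_nsf = 3,
                                            effect_size = e, seed = s),
                                  estimator = "lzc",
                                  epoch_seed = 50L + s)
      cx <- fm$values[, 1:76]
      mean(cx[fm$labels == "NSF", ]) - mean(cx[fm$labels == "SF", ])
    }, 0)
    mean(per_seed)
  }, 0)
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), 0.02)   # no spurious gap under the null
  expect_gt(gaps[3], 0.05)        # strong planted effect is visible
})

test_that("NSF recordings carry more broadband noise than SF at strong effect", {
  spec <- tiny_spec(n_sf = 3, n_nsf = 3, effect_size = 0.6, seed = 19)
  fm <- cohort_feature_matrix(spec, estimator = "lzc", epoch_seed = 7L)
  cx <- fm$values[, 1:76]
  expect_gt(mean(cx[fm$labels == "NSF", ]), mean(cx[fm$labels == "SF", ]))
})
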