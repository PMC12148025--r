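test_that("relative brightness is 1 for the reference and tracks photon rate", {
  set.seed(9)
  cm <- c(rnorm(10, 1000, 20), rnorm(10, 3000, 60))
  fp <- rep(c("ref", "bright"), each = 10)
  rb <- relative_brightness(cm, fp, "ref")
  expect_equal(rb$relative_brightness[rb$fp == "ref"], 1)
  expect_equal(rb$relative_brightness[rb$fp == "bright"],
               mean(cm[11:20]) / mean(cm[1:10]))
  # two FPs with identical simulated parameters: ratio ~ 1
  cm2 <- c(rnorm(200, 1000, 20), rnorm(200, 1000, 20))
  rb2 <- relative_brightness(cm2, rep(c("a", "b"), each = 200), "a")
  expect_lt(abs(rb2$relative_brightness[rb2$fp == "b"] - 1), 0.02)
  expect_error(relative_brightness(cm, fp, "absent"), "not present")
})

test_that("emission yield reproduces published arithmetic", {
  ref <- fp_reference()
  hl <- setNames(ref$half_life_s, ref$fp)
  rb <- setNames(ref$relative_brightness, ref$fp)
  # reference green FP: brightness 1, half-life 23 s
  expect_equal(emission_yield(rb[["EGFP"]], hl[["EGFP"]]), 23)
  # a 3x brighter FP with a 60 s half-life: yield 180, ~7.8x the reference
  y <- emission_yield(rb[["mStayGold"]], hl[["mStayGold"]])
  expect_equal(y, 180)
  expect_equal(y / 23, 7.826, tolerance = 0.001)
  # bright-but-bleachy red FP: yield ratio vs its reference is below 1
  ratio <- emission_yield(rb[["mScarlet-I"]], hl[["mScarlet-I"]]) /
    emission_yield(rb[["mCherry"]], hl[["mCherry"]])
  expect_equal(ratio, 1.6 * 5.4 / 21, tolerance = 1e-12)
  expect_lt(ratio, 1)
  # unit invariance: folds are unitless
  expect_equal(emission_yield(2, 30), emission_yield(2, 30) * 1)
  expect_error(emission_yield(1, 0))
  expect_error(emission_yield(Inf, 10))
})

test_that("Tukey-Kramer reduces to the pooled t-test for two groups", {
  set.seed(123)
  for (rep in 1:5) {
    x <- rnorm(12, 10, 2)
    y <- rnorm(8, 11, 2)    # unequal n: Kramer form
    res <- anova_tukey(c(x, y), rep(c("a", "b"), c(12, 8)))
    p_t <- t.test(x, y, var.equal = TRUE)$p.value
    expect_lt(abs(res$pairwise["a", "b"] - p_t), 1e-6)
    expect_equal(res$pairwise["a", "b"], res$pairwise["b", "a"])
  }
})

test_that("clearly separated groups are all significant with distinct letters", {
  set.seed(5)
  vals <- c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01), rnorm(10, 20, 0.01))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- anova_tukey(vals, g)
  expect_lt(res$anova_p, 1e-10)
  off_diag <- res$pairwise[upper.tri(res$pairwise)]
  expect_true(all(off_diag < 0.05))
  expect_equal(unname(res$letters), c("a", "b", "c"))
})

test_that("indistinguishable groups share a letter", {
  set.seed(6)
  vals <- rnorm(30, 5, 1)
  res <- anova_tukey(vals, rep(c("a", "b", "c"), each = 10))
  expect_equal(unname(res$letters), c("a", "a", "a"))
  expect_error(anova_tukey(vals[1:10], rep("a", 10)), "2 groups")
  expect_error(anova_tukey(vals[1:4], c("a", "a", "b", "b")), "3 observations")
})

test_that("Fibonacci spacing scales linearly and shrinks with point count", {
  s35 <- fibonacci_spacing(60, 35)
  expect_equal(fibonacci_spacing(60, 70), 2 * s35, tolerance = 1e-12)
  expect_equal(fibonacci_spacing(60, 0), 0)
  n_seq <- c(10, 20, 60, 120, 500)
  sp <- vapply(n_seq, fibonacci_spacing, numeric(1), sphere_diameter = 35)
  expect_true(all(diff(sp) < 0))
  # large-n limit approaches the sqrt(area / n) packing scale
  n <- 1000
  expect_lt(abs(fibonacci_spacing(n, 2) / sqrt(4 * pi / n) - 1), 0.2)
  expect_error(fibonacci_spacing(1, 35), "2 points")
})

test_that("spectral throughput handles inside, outside and partial bands", {
  tri_em <- data.frame(wavelength_nm = c(500, 510, 520, 530, 540),
                       amplitude = c(0, 0.5, 1, 0.5, 0))
  ex <- data.frame(wavelength_nm = c(470, 488, 500), amplitude = c(2, 4, 1))
  # emission entirely inside the pass-band
  r <- spectral_throughput(488, c(480, 560), ex, tri_em)
  expect_equal(r$emission_capture, 1, tolerance = 1e-12)
  expect_equal(r$excitation_efficiency, 1)   # peak-normalized at the line
  # disjoint band
  expect_equal(spectral_throughput(488, c(600, 700), ex,
                                   tri_em)$emission_capture, 0)
  # rectangular spectrum, exactly half in band
  rect <- data.frame(wavelength_nm = c(500, 520), amplitude = c(1, 1))
  expect_equal(spectral_throughput(488, c(510, 560), ex,
                                   rect)$emission_capture, 0.5,
               tolerance = 1e-12)
  # long-pass edge at the emission peak captures half the area
  expect_equal(spectral_throughput(488, c(520, Inf), ex,
                                   tri_em)$emission_capture, 0.5,
               tolerance = 1e-12)
  expect_equal(spectral_throughput(488, c(530, Inf), ex,
                                   tri_em)$emission_capture, 0.125,
               tolerance = 1e-12)
  expect_error(spectral_throughput(450, c(480, 560), ex, tri_em),
               "outside")
})

test_that("fp_comparison joins brightness and half-life into yields", {
  bright <- data.frame(fp = c("ref", "x"), n_cells = c(5L, 5L),
                       mean_cage_intensity_counts = c(1000, 2500),
                       relative_brightness = c(1, 2.5))
  hls <- data.frame(fp = c("ref", "x"), mean_half_life_s = c(23, 46))
  cmp <- fp_comparison(bright, hls, channel = "green_sim")
  expect_equal(cmp$emission_yield_fold_s[cmp$fp == "ref"], 23)
  expect_equal(cmp$emission_yield_fold_s[cmp$fp == "x"], 115)
  expect_equal(unique(cmp$channel), "green_sim")
})
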