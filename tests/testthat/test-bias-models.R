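test_that("family homozygosity matches direct arithmetic", {
  expect_equal(family_homozygosity(c(2, 2)), 1 / 3)
  expect_equal(family_homozygosity(c(5, 0)), 1)
  expect_true(is.na(family_homozygosity(c(1, 0))))
  expect_true(is.na(family_homozygosity(c(0, 0))))
  expect_equal(family_homozygosity(c(3, 1)), (4 * (9 + 1) / 16 - 1) / 3)
})

test_that("the expected-ENC curve evaluates the closed form", {
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0.3), 2 + 0.3 + 29 / (0.09 + 0.49))
  expect_error(enc_expected(-0.1), class = "mitocub_domain_error")
  expect_error(enc_expected(1.5), class = "mitocub_domain_error")
  # curve shape on a dense grid: a single interior maximum just right of
  # gc3s = 0.5 (the linear GC3s term nudges it off the symmetric point)
  grid <- seq(0, 1, by = 0.001)
  vals <- enc_expected(grid)
  peak <- grid[which.max(vals)]
  expect_gt(peak, 0.49)
  expect_lt(peak, 0.53)
  expect_gte(max(vals), 60.5)
  expect_lt(max(vals), 60.6)
  expect_true(all(diff(vals[grid <= 0.49]) > 0))
  expect_true(all(diff(vals[grid >= 0.53]) < 0))
})

test_that("Nc hits its defining limits", {
  # one codon per observed family -> Nc = number of observed families
  one <- make_counts(c(AAA = 5, TTT = 4, GGA = 6, CGA = 3, TTA = 8))
  expect_equal(enc_observed(one, warn_low = FALSE), 5)
  # uniform usage at large n -> Nc near the sense-codon count
  code <- genetic_code(5)
  sense <- code$codons$codon[code$codons$aa != "*"]
  uni <- make_counts(stats::setNames(rep(10000 %/% 62, 62), sense))
  expect_lt(abs(enc_observed(uni) - 62), 0.5)
  code1 <- genetic_code(1)
  sense1 <- code1$codons$codon[code1$codons$aa != "*"]
  uni1 <- make_counts(stats::setNames(rep(164L, 61), sense1), code_id = 1)
  expect_lt(abs(enc_observed(uni1, code_id = 1) - 61), 0.5)
})

test_that("Nc agrees with an independent brute-force implementation", {
  set.seed(202)
  for (code_id in c(1, 5)) {
    for (i in 1:200) {
      counts <- random_counts(code_id, lambda = runif(1, 0.3, 8))
      if (sum(counts$count) < 2) next
      got <- tryCatch(suppressWarnings(enc_observed(counts, code_id = code_id)),
                      error = function(e) NA_real_)
      if (is.na(got)) next  # degenerate table: estimator undefined by design
      want <- enc_brute(stats::setNames(counts$count, counts$codon), code_id)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("Nc converges under count scaling and errors without data", {
  # the homozygosity estimator has an O(1/n) sample-size term, so Nc is not
  # exactly scale-free at finite n; doubling differences must shrink toward
  # a limit as counts scale up
  set.seed(33)
  counts <- random_counts(5, lambda = 20)   # total ~ 1200
  at_scale <- function(k) {
    scaled <- counts
    scaled$count <- k * scaled$count
    enc_observed(scaled)
  }
  d1 <- abs(at_scale(2L) - at_scale(1L))
  d2 <- abs(at_scale(4L) - at_scale(2L))
  d3 <- abs(at_scale(64L) - at_scale(32L))
  expect_lt(d1, 0.05 * at_scale(1L))
  expect_lt(d2, d1)
  expect_lt(d3, 0.05)
  expect_error(suppressWarnings(enc_observed(make_counts(c()))),
               class = "mitocub_insufficient_data")
  expect_warning(enc_observed(make_counts(c(AAA = 2, AAG = 3))), "noisy")
})

test_that("ENC-plot points separate biased from unbiased genes", {
  set.seed(55)
  biased <- dplyr::bind_rows(lapply(1:3, function(i)
    generate_cds(400, bias_concentration = 0.05, gene = paste0("nad", i))))
  unbiased <- dplyr::bind_rows(lapply(1:3, function(i)
    generate_cds(400, bias_concentration = Inf, gene = paste0("cox", i))))
  tab <- enc_table(dplyr::bind_rows(biased, unbiased))
  expect_s3_class(tab, "enc_table")
  expect_equal(nrow(tab), 6)
  res_biased <- tab$residual[grepl("nad", tab$gene)]
  res_unbiased <- tab$residual[grepl("cox", tab$gene)]
  expect_gt(min(res_biased), max(res_unbiased))
  # unbiased genes sit near the expected curve
  expect_true(all(abs(res_unbiased) < 8))
  # single-gene input gives a single point
  expect_equal(nrow(enc_table(biased[1, ])), 1)
})

test_that("the neutrality regression recovers exact and degenerate geometries", {
  exact <- tibble::tibble(gc3 = c(0.2, 0.4, 0.6), gc12 = c(0.2, 0.4, 0.6))
  f <- neutrality_fit(exact)
  expect_equal(f$slope, 1)
  expect_equal(f$r, 1)
  flat <- tibble::tibble(gc3 = c(0.1, 0.2, 0.3), gc12 = c(0.3, 0.3, 0.3))
  f0 <- neutrality_fit(flat)
  expect_equal(f0$slope, 0)
  expect_equal(f0$intercept, 0.3)
  expect_error(neutrality_fit(exact[1:2, ]), class = "mitocub_degenerate_fit")
  nov <- tibble::tibble(gc3 = rep(0.3, 4), gc12 = runif(4))
  expect_error(neutrality_fit(nov), class = "mitocub_degenerate_fit")
})

test_that("neutrality fit p-value is the classical t-test on r and methods are tidy", {
  set.seed(12)
  pts <- tibble::tibble(gc3 = runif(13, 0.1, 0.5))
  pts$gc12 <- 0.5 * pts$gc3 + rnorm(13, sd = 0.02)
  f <- neutrality_fit(pts)
  ct <- cor.test(pts$gc3, pts$gc12)
  expect_equal(f$p_value, ct$p.value)
  expect_equal(f$r, unname(ct$estimate))
  td <- tidy(f)
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_equal(gl$n, 13)
  expect_equal(gl$r.squared, f$r^2)
  expect_equal(summary(f$model)$r.squared, f$r^2)
})

test_that("slope recovery is unbiased across simulated regimes", {
  set.seed(99)
  for (beta in c(0, 0.5, 1)) {
    slopes <- replicate(120, {
      gc3 <- runif(13, 0.05, 0.5)
      gc12 <- beta * gc3 + rnorm(13, sd = 0.02)
      neutrality_fit(tibble::tibble(gc3 = gc3, gc12 = gc12))$slope
    })
    expect_lt(abs(mean(slopes) - beta), 0.05)
  }
})
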