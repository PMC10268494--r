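mk_breath <- function(ch4, subject = "S1", period = "before",
                      semester = "SIM", co2 = 3.5, h2 = 10) {
  data.frame(subject = subject, period = period, semester = semester,
             h2_ppm = h2, ch4_ppm = ch4, co2_pct = co2,
             stringsAsFactors = FALSE)
}

test_that("breath normalization rescales to nominal CO2", {
  b <- mk_breath(ch4 = c(8, 8, 0), co2 = c(3.5, 7, 5))
  n <- normalize_breath(b)
  expect_equal(n$ch4_norm, c(8, 4, 0))
  expect_equal(n$h2_norm, 10 * 3.5 / c(3.5, 7, 5))
  # scale consistency: doubling CO2 halves normalized values
  b2 <- b; b2$co2_pct <- b$co2_pct * 2
  expect_equal(normalize_breath(b2)$ch4_norm, n$ch4_norm / 2)
  b$co2_pct[1] <- 0
  expect_error(normalize_breath(b), "CO2")
})

test_that("Tukey fences exclude the planted outlier and spare benign data", {
  res <- tukey_exclude(c(1, 2, 3, 4, 5, 100))
  expect_equal(res$excluded, c(rep(FALSE, 5), TRUE))
  expect_equal(res$kept, 1:5)

  const <- tukey_exclude(rep(7, 10))
  expect_false(any(const$excluded))

  unif <- tukey_exclude(seq(0, 1, length.out = 50))
  expect_false(any(unif$excluded))

  expect_error(tukey_exclude(numeric(0)), "no values")
})

test_that("Tukey fences agree with brute force on 1000 random samples", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    x <- if (runif(1) < 0.5) rnorm(n, 10, 5) else rlnorm(n, 2, 1)
    if (runif(1) < 0.3) x[1] <- x[1] + 100  # plant an outlier sometimes
    k <- sample(c(1.5, 3), 1)
    expect_identical(tukey_exclude(x, k = k)$excluded,
                     oracle_tukey_mask(x, k = k))
  }
})

test_that("methanogen classification uses a strict threshold and baselines", {
  b <- normalize_breath(mk_breath(ch4 = c(2, 5, 3)))
  st <- classify_methanogenic(b)
  expect_equal(st$status, "MG")

  b2 <- normalize_breath(mk_breath(ch4 = c(4, 4, 4)))
  expect_equal(classify_methanogenic(b2)$status, "non-MG")

  # 5 ppm raw in an elevated-baseline semester corrects to 4 -> non-MG
  b3 <- normalize_breath(mk_breath(ch4 = c(5, 5), semester = "W16"))
  expect_equal(classify_methanogenic(b3)$status, "MG")
  expect_equal(classify_methanogenic(b3,
                                     baseline_semesters = "W16")$status,
               "non-MG")

  # periods are classified separately
  b4 <- normalize_breath(rbind(mk_breath(ch4 = c(1, 2), period = "before"),
                               mk_breath(ch4 = c(9, 1), period = "during")))
  st4 <- classify_methanogenic(b4)
  expect_equal(st4$status[st4$period == "before"], "non-MG")
  expect_equal(st4$status[st4$period == "during"], "MG")

  expect_error(classify_methanogenic(b4[0, ]), "no breath samples")
})

test_that("raising a CH4 reading never flips MG to non-MG", {
  set.seed(11)
  for (i in 1:50) {
    ch4 <- runif(5, 0, 8)
    b <- normalize_breath(mk_breath(ch4 = ch4))
    before <- classify_methanogenic(b)$status
    j <- sample(5, 1)
    b$ch4_norm[j] <- b$ch4_norm[j] + runif(1, 0, 10)
    after <- classify_methanogenic(b)$status
    expect_false(before == "MG" && after == "non-MG")
  }
})

test_that("subject period means average retained samples only", {
  s <- data.frame(subject = rep(c("A", "B"), each = 3),
                  period = "before",
                  v = c(10, 12, 100, 9, 10, 11))
  m_raw <- subject_period_means(s, "v", k = Inf)
  expect_equal(m_raw$mean[m_raw$subject == "A"], mean(c(10, 12, 100)))
  m <- subject_period_means(s, "v", k = 3)
  expect_equal(m$mean[m$subject == "A"], 11)
  expect_equal(m$n_excluded[m$subject == "A"], 1)
  expect_equal(m$mean[m$subject == "B"], 10)

  one <- data.frame(subject = "A", period = "during", v = 4.2)
  expect_warning(m1 <- subject_period_means(one, "v"), "fewer than 4")
  expect_equal(m1$mean, 4.2)
  two <- data.frame(subject = "A", period = "during", v = c(2, 4))
  expect_warning(m2 <- subject_period_means(two, "v"), "fewer than 4")
  expect_equal(m2$mean, 3)
})

test_that("MG group comparison matches brute-force t and detects group shifts", {
  set.seed(3)
  n <- 20
  means <- data.frame(subject = sprintf("S%02d", 1:(2 * n)),
                      period = "during",
                      mean = c(rnorm(n, 5, 1), rnorm(n, 10, 1)))
  status <- data.frame(subject = means$subject, period = "during",
                       status = rep(c("MG", "non-MG"), each = n))
  res <- compare_mg_groups(means, status, "during")
  oracle <- oracle_t2(means$mean[1:n], means$mean[(n + 1):(2 * n)])
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)

  same <- means; same$mean <- rep(c(1, 2), n)
  expect_equal(compare_mg_groups(same, status, "during")$p,
               oracle_t2(same$mean[1:n], same$mean[(n + 1):(2 * n)])$p)

  # explicit exclusion removes a flagged subject from the test
  res_ex <- compare_mg_groups(means, status, "during",
                              exclude_subjects = "S01")
  expect_equal(res_ex$n_mg, n - 1)

  tiny <- means[c(1, n + 1, n + 2), ]
  expect_error(compare_mg_groups(tiny, status, "during"), ">= 2 subjects")
})

test_that("before/during contrast supports paired and unpaired forms", {
  means <- data.frame(subject = rep(sprintf("S%02d", 1:6), 2),
                      period = rep(c("before", "during"), each = 6),
                      mean = c(1:6, 2:7))
  pa <- before_during_contrast(means, paired = TRUE)
  expect_equal(pa$mean_during - pa$mean_before, 1)
  expect_lt(pa$p, 1e-6)  # constant +1 shift, paired
  un <- before_during_contrast(means, paired = FALSE)
  expect_gt(un$p, pa$p)
})

test_that("pipeline recovers a programmed during-only methanogen effect", {
  sim <- gen_cohort(cohort_sim_params(seed = 202))
  res <- cohort_mg_comparison(sim$breath, sim$fecal)
  stat <- classify_methanogenic(normalize_breath(sim$breath))
  truth <- sim$subjects
  # classification recovers the generator's truth in both periods
  for (per in c("before", "during")) {
    st <- stat[stat$period == per, ]
    expect_equal(st$status[match(truth$subject, st$subject)],
                 ifelse(truth$methanogenic, "MG", "non-MG"))
  }
  during <- res[res$period == "during", ]
  before <- res[res$period == "before", ]
  expect_true(all(during$p < 0.05))
  expect_true(all(during$mean_mg < during$mean_non_mg))
  expect_true(all(before$p > 0.05))
})
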