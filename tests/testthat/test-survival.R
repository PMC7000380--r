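test_that("Kaplan-Meier matches the hand-computed product limit", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- kaplan_meier(rec)
  # S(1) = 2/3 (one death of three at risk); censor at 2; S(3) = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  all_cens <- kaplan_meier(tibble::tibble(time = c(5, 8, 2), event = 0))
  expect_true(all(all_cens$survival == 1))

  expect_error(kaplan_meier(tibble::tibble(time = c(0, 1), event = c(1, 1))),
               "non-positive")
})

test_that("Kaplan-Meier equals an independent long-hand computation", {
  set.seed(12)
  rec <- tibble::tibble(time = sample(1:50, 10), event = rbinom(10, 1, 0.7))
  km <- kaplan_meier(rec)
  # long-hand product-limit over distinct times
  ord <- order(rec$time)
  t_sorted <- rec$time[ord]; e_sorted <- rec$event[ord]
  s <- 1
  for (tt in unique(t_sorted)) {
    at_risk <- sum(t_sorted >= tt)
    deaths <- sum(t_sorted == tt & e_sorted == 1)
    s_new <- s * (1 - deaths / at_risk)
    if (deaths > 0) {
      expect_equal(km$survival[km$time == tt], s_new, tolerance = 1e-12)
    }
    s <- s_new
  }
  # invariance under record permutation; survival is non-increasing
  km2 <- kaplan_meier(rec[sample(10), ])
  expect_equal(km, km2)
  expect_true(all(diff(km$survival) <= 1e-12))
})

test_that("log-rank reproduces the frozen worked example and edge cases", {
  rec <- tibble::tibble(time = 1:6, event = 1,
                        group = rep(c("A", "B"), each = 3))
  res <- logrank_test(rec)
  # long-hand O/E/V at the six death times gives chi2 = 1.85^2 / 0.6775
  expect_equal(res$chi2, 1.85^2 / 0.6775, tolerance = 1e-4)
  expect_equal(res$chi2, 5.0517, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0246, tolerance = 1e-3)

  # identical groups -> chi2 = 0, p = 1
  same <- tibble::tibble(time = rep(c(3, 5, 9), 2), event = rep(c(1, 0, 1), 2),
                         group = rep(c("A", "B"), each = 3))
  res2 <- logrank_test(same)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)

  # zero events overall -> p = 1 by convention
  none <- tibble::tibble(time = c(4, 5, 6, 7), event = 0,
                         group = rep(c("A", "B"), 2))
  expect_equal(logrank_test(none)$p_value, 1)

  # symmetry in group labels
  flipped <- rec
  flipped$group <- ifelse(rec$group == "A", "B", "A")
  expect_equal(logrank_test(flipped)$chi2, res$chi2)

  expect_error(logrank_test(tibble::tibble(time = 1:3, event = 1,
                                           group = "A")), ">= 2 groups")
})

test_that("log-rank p-values are approximately uniform under the null", {
  ps <- numeric(200)
  for (s in 1:200) {
    sv <- simulate_survival(rep(1:3, each = 40), hazards = rep(0.004, 3),
                            censor_rate = 0.2, seed = s + 7000)
    ps[s] <- logrank_test(tibble::tibble(time = sv$pfi_time,
                                         event = sv$pfi_event,
                                         group = rep(1:3, each = 40)))$p_value
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # type-I error within 3 MC SEs of 0.05
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("event-stratified survival flags planted protective events", {
  # planted protective event: carriers have one third of the hazard
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    occ <- rbinom(n, 1L, 0.5)
    bm <- rbind(GA = occ, GB = occ)
    colnames(bm) <- sprintf("s%03d", 1:n)
    storage.mode(bm) <- "integer"
    sv <- simulate_survival(ifelse(occ == 1, 1, 2),
                            hazards = c(0.001, 0.003),
                            censor_rate = 0.3, seed = s + 300)
    cl <- toy_clinical(colnames(bm), is_tumor = rep(TRUE, n),
                       time = sv$pfi_time, event = sv$pfi_event)
    res <- event_stratified_survival(c("GA", "GB"), "CO", bm, cl)
    if (res$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # an all-carrier stratum is an error naming the stratum
  bm1 <- rbind(GA = rep(1L, 4), GB = rep(1L, 4))
  colnames(bm1) <- sprintf("s%d", 1:4)
  cl1 <- toy_clinical(colnames(bm1), is_tumor = rep(TRUE, 4),
                      time = c(10, 20, 30, 40), event = rep(1L, 4))
  expect_error(event_stratified_survival(c("GA", "GB"), "CO", bm1, cl1),
               "without")
})

test_that("null event stratification rejects at the nominal rate", {
  rej <- 0; n_rep <- 100
  for (s in 1:n_rep) {
    set.seed(s + 50)
    n <- 300
    occ <- rbinom(n, 1L, 0.5)
    bm <- rbind(GA = occ, GB = occ)
    colnames(bm) <- sprintf("s%03d", 1:n)
    storage.mode(bm) <- "integer"
    sv <- simulate_survival(rep(1, n), hazards = 0.002,
                            censor_rate = 0.3, seed = s + 600)
    cl <- toy_clinical(colnames(bm), is_tumor = rep(TRUE, n),
                       time = sv$pfi_time, event = sv$pfi_event)
    res <- event_stratified_survival(c("GA", "GB"), "CO", bm, cl)
    if (res$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Kruskal-Wallis matches the rank formula with and without ties", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$H, 27 / 7, tolerance = 1e-9)

  expect_equal(kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))$H, 0)
  expect_equal(kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))$p_value, 1)

  # tie-corrected formula, computed independently
  v <- c(1, 2, 2, 3, 3, 3, 4, 5); g <- rep(c("a", "b"), 4)
  res2 <- kruskal_wallis(v, g)
  r <- rank(v); n <- length(v)
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  expect_equal(res2$H, h_raw / corr, tolerance = 1e-9)
})

test_that("chi-square association matches the expected-count formula", {
  res <- chi_square_assoc(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)

  same_rows <- matrix(c(5, 10, 5, 10), 2, byrow = TRUE)
  res2 <- chi_square_assoc(same_rows)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)

  # 3x4 random table against the formula oracle
  set.seed(8)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  res3 <- chi_square_assoc(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res3$chi2, sum((tab - exp_counts)^2 / exp_counts),
               tolerance = 1e-9)
  expect_equal(res3$df, 6)

  expect_error(chi_square_assoc(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("clinical associations dispatch continuous vs categorical tests", {
  set.seed(9)
  n <- 90
  labels <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           cluster = rep(1:3, each = 30))
  clin <- tibble::tibble(
    sample_id = labels$sample_id, cancer_type = "CA", is_tumor = TRUE,
    pfi_time = 100, pfi_event = 1L,
    age = 50 + 5 * labels$cluster + rnorm(n, 0, 3),
    gender = ifelse(runif(n) < c(0.2, 0.5, 0.8)[labels$cluster],
                    "female", "male")
  )
  out <- clinical_associations(labels, clin, features = c("age", "gender"))
  expect_equal(out$test[out$feature == "age"], "kruskal_wallis")
  expect_equal(out$test[out$feature == "gender"], "chi_square")
  expect_lt(out$p_value[out$feature == "age"], 0.001)
  expect_lt(out$p_value[out$feature == "gender"], 0.01)
})
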