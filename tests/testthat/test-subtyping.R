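test_that("event-sample matrix stacks per-sample occurrences", {
  bm <- matrix(c(1L, 1L, 0L,
                 1L, 0L, 1L,
                 0L, 1L, 1L), 3, 3, byrow = TRUE,
               dimnames = list(c("GA", "GB", "GC"), c("s1", "s2", "s3")))
  fr <- tibble::tibble(gene_a = c("GA", "GB"), gene_b = c("GB", "GC"),
                       type = c("CO", "ME"))
  esm <- event_sample_matrix(fr, bm)
  expect_equal(rownames(esm), c("GA|GB|CO", "GB|GC|ME"))
  expect_equal(unname(esm["GA|GB|CO", ]), c(1L, 0L, 0L))
  expect_equal(unname(esm["GB|GC|ME", ]), c(1L, 1L, 0L))
})

test_that("consensus clustering separates planted blocks and is deterministic", {
  sim <- simulate_event_matrix(n_samples = 60, n_events = 20, k = 2,
                               signature_prob = 0.9, background_prob = 0.1,
                               seed = 8)
  cr <- consensus_cluster(sim$esm, k_range = 2:4, n_reps = 30, seed = 15)
  cons2 <- cr$consensus[["2"]]
  same <- outer(sim$labels, sim$labels, "==")
  within <- cons2[same & upper.tri(cons2)]
  between <- cons2[!same & upper.tri(cons2)]
  expect_gte(mean(within), 0.95)
  expect_lte(mean(between), 0.05)
  # labels recover the blocks exactly (up to relabeling)
  lab <- cr$labels[["2"]]
  tab <- table(lab[names(sim$labels)], sim$labels)
  expect_equal(sum(apply(tab, 1, max)), length(sim$labels))
  # determinism
  cr2 <- consensus_cluster(sim$esm, k_range = 2:4, n_reps = 30, seed = 15)
  expect_identical(cr$labels, cr2$labels)
  expect_identical(cr$consensus, cr2$consensus)
  expect_identical(cr$chosen_k, cr2$chosen_k)
})

test_that("identical samples give an all-one consensus at every k", {
  esm <- matrix(rep(c(1L, 0L, 1L), each = 12), nrow = 3, byrow = TRUE,
                dimnames = list(sprintf("E%d", 1:3), sprintf("s%02d", 1:12)))
  cr <- consensus_cluster(esm, k_range = 2:3, n_reps = 10, seed = 1)
  for (k in c("2", "3")) {
    expect_true(all(cr$consensus[[k]] == 1))
  }
})

test_that("k selection: planted k recovered, structureless falls to minimum", {
  sim <- simulate_event_matrix(n_samples = 90, n_events = 30, k = 3,
                               signature_prob = 0.9, background_prob = 0.1,
                               seed = 21)
  cr <- consensus_cluster(sim$esm, k_range = 2:6, n_reps = 40, seed = 22)
  expect_equal(choose_k(cr, "silhouette"), 3)
  expect_equal(choose_k(cr, "cdf_elbow"), 3)

  # silhouette of a perfect two-block consensus is 1 at k = 2
  cons <- cr$consensus[["2"]]
  ideal <- matrix(0, 40, 40); ideal[1:20, 1:20] <- 1
  ideal[21:40, 21:40] <- 1; diag(ideal) <- 1
  sil <- cluster::silhouette(rep(1:2, each = 20), as.dist(1 - ideal))
  expect_equal(mean(sil[, "sil_width"]), 1)

  # i.i.d. noise: silhouette prefers the k-range minimum
  set.seed(5)
  noise <- matrix(rbinom(30 * 60, 1L, 0.5), 30, 60,
                  dimnames = list(sprintf("E%02d", 1:30),
                                  sprintf("s%02d", 1:60)))
  crn <- consensus_cluster(noise, k_range = 2:5, n_reps = 30, seed = 6)
  expect_equal(choose_k(crn, "silhouette"), 2)

  # fully tied consensus (identical samples): elbow falls to the minimum
  esm_id <- matrix(rep(c(1L, 0L, 1L), each = 12), nrow = 3, byrow = TRUE,
                   dimnames = list(sprintf("E%d", 1:3),
                                   sprintf("t%02d", 1:12)))
  cr_id <- consensus_cluster(esm_id, k_range = 2:4, n_reps = 10, seed = 7)
  expect_equal(choose_k(cr_id, "cdf_elbow"), 2)
})

test_that("cluster enrichment ranks exclusive events first", {
  set.seed(2)
  n <- 40
  labels <- setNames(rep(1:2, each = 20), sprintf("s%02d", 1:n))
  esm <- rbind(
    excl = c(rep(1L, 20), rep(0L, 20)),       # cluster-1 exclusive
    ubiq = rep(1L, 40),                       # occurs everywhere
    rand = rbinom(n, 1L, 0.5)
  )
  colnames(esm) <- names(labels)
  enr <- cluster_event_enrichment(esm, labels, top_n = 3)
  c1 <- enr[enr$cluster == 1, ]
  expect_equal(c1$event_id[1], "excl")
  # hypergeometric closed form: all 20 occurrences inside a 20-sample cluster
  expect_equal(c1$p_hyper[1], 1 / choose(40, 20), tolerance = 1e-12)
  # an event occurring in every sample carries no enrichment signal
  expect_equal(enr$p_hyper[enr$event_id == "ubiq" & enr$cluster == 1], 1,
               tolerance = 1e-9)
  # top_n larger than the event count returns everything
  enr_all <- cluster_event_enrichment(esm, labels, top_n = 50)
  expect_equal(nrow(enr_all), 6)
})

test_that("subtype recovery meets the ARI benchmark across seeds", {
  skip_if_not_installed("mclust")
  aris <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_event_matrix(n_samples = 200, n_events = 60, k = 3,
                                 signature_prob = 0.85,
                                 background_prob = 0.1, seed = s)
    cr <- consensus_cluster(sim$esm, k_range = 2:6, n_reps = 50,
                            seed = s + 40)
    expect_equal(cr$chosen_k$silhouette, 3)
    lab <- cr$labels[["3"]]
    aris[s] <- mclust::adjustedRandIndex(lab[names(sim$labels)], sim$labels)
  }
  expect_true(all(aris >= 0.9))
})

test_that("tidy and glance views expose labels and selection diagnostics", {
  sim <- simulate_event_matrix(n_samples = 40, n_events = 12, k = 2,
                               signature_prob = 0.9, background_prob = 0.1,
                               seed = 3)
  cr <- consensus_cluster(sim$esm, k_range = 2:3, n_reps = 20, seed = 4)
  td <- tidy(cr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_true(all(td$cluster %in% 1:2))
  gl <- glance(cr)
  expect_equal(gl$k, 2:3)
  expect_equal(sum(gl$chosen_by_silhouette), 1)
})
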