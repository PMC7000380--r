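test_that("event occurrence implements the CO and ME decision rules", {
  bm <- matrix(c(1L, 1L,   # s1: both
                 1L, 0L,   # s2: only GA
                 0L, 1L,   # s3: only GB
                 0L, 0L),  # s4: neither
               nrow = 2, dimnames = list(c("GA", "GB"),
                                         sprintf("s%d", 1:4)))
  co <- event_occurrence(bm, c("GA", "GB"), "CO")
  me <- event_occurrence(bm, c("GA", "GB"), "ME")
  expect_equal(unname(co), c(1L, 0L, 0L, 0L))
  expect_equal(unname(me), c(0L, 1L, 1L, 0L))
  # logical invariants: CO implies both 1; ME implies gene sum exactly 1
  expect_true(all(colSums(bm)[co == 1] == 2))
  expect_true(all(colSums(bm)[me == 1] == 1))
  expect_error(event_occurrence(bm, c("GA", "GX"), "CO"), "GX")
  zero <- matrix(0L, 2, 4, dimnames = dimnames(bm))
  expect_equal(unname(event_occurrence(zero, c("GA", "GB"), "CO")),
               rep(0L, 4))
})

test_that("Fisher differential occurrence matches the frozen extreme table", {
  occ <- setNames(c(rep(1L, 10), rep(0L, 10)), sprintf("s%02d", 1:20))
  cl <- toy_clinical(names(occ), is_tumor = c(rep(TRUE, 10), rep(FALSE, 10)))
  rec <- fisher_differential(occ, cl)
  expect_equal(unlist(rec[c("a", "b", "c", "d")]),
               c(a = 10, b = 0, c = 0, d = 10))
  expect_equal(rec$p_fisher, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(rec$differential)

  # identical proportions -> p = 1
  occ2 <- setNames(rep(c(1L, 0L), 10), names(occ))
  rec2 <- fisher_differential(occ2, cl)
  expect_equal(rec2$p_fisher, 1)

  # zero normals -> non-assessable with warning
  cl3 <- toy_clinical(names(occ), is_tumor = rep(TRUE, 20))
  expect_warning(rec3 <- fisher_differential(occ, cl3), "no normal sample")
  expect_true(is.na(rec3$p_fisher))
})

test_that("Fisher p equals exhaustive hypergeometric enumeration (property)", {
  # two-sided exact p: sum of hypergeometric probabilities of tables with
  # the same margins that are as or less probable than the observed one
  fisher_enum <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    obs <- dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(77)
  for (rep in 1:50) {
    n_tot <- sample(4:40, 1)
    n_tum <- sample(2:(n_tot - 2), 1)
    a <- sample(0:n_tum, 1); b <- n_tum - a
    cc <- sample(0:(n_tot - n_tum), 1); d <- n_tot - n_tum - cc
    occ <- c(rep(1L, a), rep(0L, b), rep(1L, cc), rep(0L, d))
    names(occ) <- sprintf("s%02d", seq_along(occ))
    cl <- toy_clinical(names(occ),
                       is_tumor = c(rep(TRUE, n_tum),
                                    rep(FALSE, n_tot - n_tum)))
    rec <- fisher_differential(occ, cl)
    expect_equal(rec$p_fisher, fisher_enum(a, b, cc, d), tolerance = 1e-7)
  }
})

test_that("frequent-event selection applies the >= 3 cancers rule", {
  ev <- tibble::tibble(
    gene_a = rep(c("GA", "GC", "GE", "GG"), times = c(3, 2, 4, 1)),
    gene_b = rep(c("GB", "GD", "GF", "GH"), times = c(3, 2, 4, 1)),
    type = rep(c("CO", "ME", "CO", "CO"), times = c(3, 2, 4, 1)),
    cancer = c("BRCA", "KIRC", "LUSC",
               "BRCA", "KIRC",
               "BRCA", "KIRC", "LUSC", "PAAD",
               "BRCA"),
    differential = TRUE
  )
  out <- select_frequent(ev, min_cancers = 3)
  expect_equal(out$gene_a, c("GE", "GA"))      # 4 cancers sorts before 3
  expect_equal(out$n_cancers_differential, c(4L, 3L))
  expect_equal(out$cancers[2], "BRCA,KIRC,LUSC")

  # threshold 1 keeps every differential event
  expect_equal(nrow(select_frequent(ev, min_cancers = 1)), 4)
  # monotone decreasing in min_cancers and always a subset
  n_prev <- Inf
  for (mc in 1:5) {
    out_mc <- suppressWarnings(select_frequent(ev, min_cancers = mc))
    expect_lte(nrow(out_mc), n_prev)
    n_prev <- nrow(out_mc)
  }
  expect_warning(select_frequent(ev, min_cancers = 5), "no event")
})

test_that("differential_events assembles per-cancer records", {
  spec <- cohort_spec(n_genes = 20, n_planted_co = 2, n_planted_me = 0,
                      n_signature_per_subtype = 0, n_subtypes = 1,
                      hazards = 0.002, n_tumor = 80, n_normal = 30, seed = 2)
  events <- list(); bms <- list(); clin <- list()
  for (cancer in c("CA", "CB")) {
    tum <- simulate_binary(spec, seed = if (cancer == "CA") 4 else 5,
                           sample_prefix = paste0(cancer, "_T"))
    nor <- simulate_binary(spec, n_samples = 30, tumor = FALSE,
                           seed = if (cancer == "CA") 6 else 7,
                           sample_prefix = paste0(cancer, "_N"),
                           gene_rate = tum$gene_rate)
    bms[[cancer]] <- cbind(tum$matrix, nor$matrix)
    events[[cancer]] <- suppressWarnings(test_all_pairs(filter_genes(tum$matrix)))
    clin[[cancer]] <- toy_clinical(colnames(bms[[cancer]]),
                                   is_tumor = rep(c(TRUE, FALSE), c(80, 30)),
                                   cancer = cancer)
  }
  de <- differential_events(events, bms, dplyr::bind_rows(clin))
  expect_true(all(c("a", "b", "c", "d", "p_fisher", "differential")
                  %in% colnames(de)))
  expect_true(all(de$a + de$b == 80))
  expect_true(all(de$c + de$d == 30))
  # planted CO pairs occur in tumors far above normals -> differential
  planted <- dplyr::semi_join(de, spec |> planted_pairs(),
                              by = c("gene_a", "gene_b"))
  expect_true(all(planted$differential))
})
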