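test_that("exact Poisson-binomial tails match frozen enumeration values", {
  # P(X <= 0) for two Bernoulli(0.25): 0.75^2, enumerated over 4 outcomes
  expect_equal(poisson_binomial_tail(c(0.25, 0.25), 0, "le"), 0.5625)
  # whole support
  expect_equal(poisson_binomial_tail(runif(7), 0, "ge"), 1)
  # i.i.d. case reduces to the binomial closed form
  expect_equal(poisson_binomial_tail(rep(0.3, 10), 4, "ge"),
               pbinom(3, 10, 0.3, lower.tail = FALSE))
  expect_equal(poisson_binomial_tail(rep(0.3, 10), 4, "le"),
               pbinom(4, 10, 0.3))
  expect_error(poisson_binomial_tail(c(0.5, 0.5), 3), "out of range")
  expect_error(poisson_binomial_tail(c(0.5, 1.5), 1), "in \\[0, 1\\]")
})

test_that("Poisson-binomial tails agree with 2^n enumeration (property)", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    probs <- runif(n)
    x <- sample(0:n, 1)
    expect_equal(poisson_binomial_tail(probs, x, "ge"),
                 pb_tail_enum(probs, x, "ge"), tolerance = 1e-12)
    expect_equal(poisson_binomial_tail(probs, x, "le"),
                 pb_tail_enum(probs, x, "le"), tolerance = 1e-12)
  }
})

test_that("background fit reproduces margins and the symmetric 2x2 case", {
  bm <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  fit <- estimate_background(bm)
  expect_equal(unname(fit$prob), matrix(0.5, 2, 2), tolerance = 1e-6)

  m <- toy_binary(15, 30, seed = 3)
  fit2 <- estimate_background(m)
  expect_true(max(abs(rowSums(fit2$prob) - rowSums(m))) <= 1e-6)
  expect_true(max(abs(colSums(fit2$prob) - colSums(m))) <= 1e-6)
  expect_true(all(fit2$prob > 0 & fit2$prob < 1))

  expect_error(estimate_background(matrix(0L, 3, 3,
    dimnames = list(letters[1:3], letters[4:6]))), "degenerate")
})

test_that("background fit matches an independent maximum-likelihood solver", {
  skip_if_not_installed("pracma")
  set.seed(11)
  m <- matrix(rbinom(20 * 30, 1, 0.35), 20, 30,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30)))
  m <- filter_genes(m, 0.01, 0.99)
  fit <- estimate_background(m)
  # independent route: the margin equations are the score equations of the
  # Bernoulli likelihood with additive logit effects; solve by BFGS on the
  # negative log-likelihood with analytic gradient (gauge: drop one sample
  # effect via centring is unnecessary -- probabilities are gauge-invariant)
  g <- nrow(m); n <- ncol(m)
  nll <- function(par) {
    u <- par[1:g]; v <- par[(g + 1):(g + n)]
    eta <- outer(u, v, "+")
    sum(log1p(exp(eta))) - sum(eta * m)
  }
  grad <- function(par) {
    u <- par[1:g]; v <- par[(g + 1):(g + n)]
    P <- plogis(outer(u, v, "+"))
    c(rowSums(P) - rowSums(m), colSums(P) - colSums(m))
  }
  opt <- optim(rep(0, g + n), nll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  P_mle <- plogis(outer(opt$par[1:g], opt$par[(g + 1):(g + n)], "+"))
  expect_lt(max(abs(fit$prob - P_mle)), 1e-4)
})

test_that("pair test reduces to binomial tails under a uniform background", {
  # 4 samples, both genes background probability 0.5 -> joint 0.25, x = 2
  bm <- matrix(c(1L, 1L, 1L, 0L,
                 1L, 1L, 0L, 1L), 2, 4, byrow = TRUE,
               dimnames = list(c("GA", "GB"), sprintf("s%d", 1:4)))
  model <- list(prob = matrix(0.5, 2, 4,
                              dimnames = dimnames(bm)))
  res <- test_pair(model, bm, "GA", "GB")
  expect_equal(res$overlap, 2L)
  expect_equal(res$p_co, 0.26171875)   # P(Bin(4, 0.25) >= 2)
  expect_equal(res$p_me, pbinom(2, 4, 0.25))
  expect_error(test_pair(model, bm, "GA", "GX"), "absent")
})

test_that("pair tails match exhaustive enumeration on a 12-sample matrix", {
  set.seed(21)
  n <- 12
  bm <- matrix(rbinom(2 * n, 1L, 0.5), 2, n,
               dimnames = list(c("GA", "GB"), sprintf("s%d", 1:n)))
  P <- matrix(runif(2 * n, 0.2, 0.8), 2, n, dimnames = dimnames(bm))
  res <- test_pair(list(prob = P), bm, "GA", "GB")
  joint <- P[1, ] * P[2, ]
  expect_equal(res$p_co, pb_tail_enum(joint, res$overlap, "ge"),
               tolerance = 1e-12)
  expect_equal(res$p_me, pb_tail_enum(joint, res$overlap, "le"),
               tolerance = 1e-12)
  # shared point mass: p_co + p_me >= 1
  expect_gte(res$p_co + res$p_me, 1)
})

test_that("extreme overlap gives the product tail and p_me = 1", {
  n <- 6
  bm <- matrix(1L, 2, n, dimnames = list(c("GA", "GB"), sprintf("s%d", 1:n)))
  P <- matrix(runif(2 * n, 0.3, 0.7), 2, n, dimnames = dimnames(bm))
  res <- test_pair(list(prob = P), bm, "GA", "GB")
  expect_equal(res$p_co, prod(P[1, ] * P[2, ]), tolerance = 1e-12)
  expect_equal(res$p_me, 1)
})

test_that("BH adjustment matches the hand-computed closed form", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(p.adjust(p, "BH"), rep(0.05, 5))
})

test_that("test_all_pairs calls planted CO pairs and is order-invariant", {
  spec <- cohort_spec(n_genes = 50, n_planted_co = 1, n_planted_me = 0,
                      n_signature_per_subtype = 0, n_subtypes = 1,
                      hazards = 0.002, n_tumor = 200, seed = 5)
  sim <- simulate_binary(spec, seed = 5)
  bm <- filter_genes(sim$matrix)
  res <- test_all_pairs(bm)
  planted <- sim$truth
  hit <- res[res$gene_a == planted$gene_a & res$gene_b == planted$gene_b, ]
  expect_equal(hit$call, "CO")
  expect_lte(hit$q_co, 0.05)

  # invariance to gene and sample ordering
  set.seed(9)
  perm_g <- sample(nrow(bm)); perm_s <- sample(ncol(bm))
  res2 <- test_all_pairs(bm[perm_g, perm_s])
  expect_equal(res2$p_co, res$p_co, tolerance = 1e-9)
  expect_equal(res2$call, res$call)
})

test_that("a single independent pair on null data is not called", {
  set.seed(31)
  bm <- matrix(rbinom(200, 1L, 0.4), 2, 100,
               dimnames = list(c("GA", "GB"), sprintf("s%03d", 1:100)))
  res <- suppressWarnings(test_all_pairs(bm))
  expect_equal(res$call, "none")
})
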