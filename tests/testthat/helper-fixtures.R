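# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive Poisson-binomial tail by enumeration over all 2^n outcomes.
# Independent of the package's dynamic-programming implementation.
pb_tail_enum <- function(probs, x, side = c("ge", "le")) {
  side <- match.arg(side)
  n <- length(probs)
  outcomes <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  k <- rowSums(outcomes)
  keep <- if (side == "ge") k >= x else k <= x
  lp <- outcomes %*% log(pmax(probs, .Machine$double.xmin)) +
    (1 - outcomes) %*% log(pmax(1 - probs, .Machine$double.xmin))
  sum(exp(lp[keep]))
}

# small deterministic binary matrix with margins away from the boundaries
toy_binary <- function(g = 10, n = 20, seed = 42, p = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(g * n, 1L, p), g, n,
              dimnames = list(sprintf("g%02d", seq_len(g)),
                              sprintf("s%02d", seq_len(n))))
  # nudge any boundary margin into the open interval
  for (i in seq_len(g)) {
    if (sum(m[i, ]) == 0) m[i, sample(n, 2)] <- 1L
    if (sum(m[i, ]) == n) m[i, sample(n, 2)] <- 0L
  }
  for (j in seq_len(n)) {
    if (sum(m[, j]) == 0) m[sample(g, 2), j] <- 1L
    if (sum(m[, j]) == g) m[sample(g, 2), j] <- 0L
  }
  storage.mode(m) <- "integer"
  m
}

# minimal clinical table for a set of samples
toy_clinical <- function(sample_ids, is_tumor, cancer = "CA",
                         time = NULL, event = NULL) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids, cancer_type = cancer, is_tumor = is_tumor,
    pfi_time = if (is.null(time)) rep(100, n) else time,
    pfi_event = if (is.null(event)) rep(1L, n) else event
  )
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
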