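#' Specification of a synthetic methylation cohort
#'
#' Collects every generator parameter in one validated list.  Defaults
#' emulate the structure of a multi-cancer 450K promoter-methylation study
#' at desk scale: bimodal probe betas straddling the 0.3 calls threshold,
#' heterogeneous per-sample methylation loads and per-gene rates, planted
#' co-occurring pairs (shared latent driver with leak), planted mutually
#' exclusive pairs (exclusive latent assignment), tumor-restricted planted
#' structure (normals carry background only), subtype-specific event
#' signatures, exponential progression-free-interval times with
#' subtype-specific hazards, and clinical covariates correlated with
#' subtype.
#'
#' @param cancers Cancer-type codes (default three types).
#' @param n_tumor,n_normal Samples per cancer.
#' @param n_genes Number of genes.
#' @param probes_per_gene Promoter probes emitted per gene.
#' @param n_planted_co,n_planted_me Planted CO / ME pairs (occupying the
#'   first genes).
#' @param driver_prob,leak_prob CO mechanism: both genes = driver OR leak,
#'   driver ~ Bernoulli(`driver_prob`), leak ~ Bernoulli(`leak_prob`).
#' @param assign_prob ME mechanism: with this probability the pair shows the
#'   exactly-one pattern, otherwise both genes follow background.
#' @param sample_load_shape,sample_load_scale Per-sample baseline alteration
#'   rate `load = scale * Beta(shape1, shape2)`.
#' @param gene_rate_range Per-gene rate multiplier, uniform over this range.
#' @param beta_unmeth,beta_meth Beta-distribution parameters of the probe
#'   emission for unmethylated (mean 0.1) and methylated (mean 0.6) states.
#' @param n_subtypes,signature_prob,background_prob,n_signature_per_subtype
#'   Subtype structure: each subtype owns `n_signature_per_subtype`
#'   signature CO pairs whose driver fires with `signature_prob` in samples
#'   of that subtype and `background_prob` elsewhere.
#' @param hazards Per-subtype exponential PFI hazards (events/day).
#' @param censor_rate Target fraction of censored tumor records.
#' @param anticorr_fraction Fraction of genes whose expression is
#'   anti-correlated with promoter methylation.
#' @param seed Master seed; all stage-level randomness is derived from it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(cancers = c("CA", "CB", "CC"),
                        n_tumor = 100, n_normal = 30,
                        n_genes = 80, probes_per_gene = 3,
                        n_planted_co = 3, n_planted_me = 3,
                        driver_prob = 0.5, leak_prob = 0.1,
                        assign_prob = 0.8,
                        sample_load_shape = c(2, 5), sample_load_scale = 0.8,
                        gene_rate_range = c(0.5, 1.5),
                        beta_unmeth = c(2, 18), beta_meth = c(12, 8),
                        n_subtypes = 3, signature_prob = 0.85,
                        background_prob = 0.1, n_signature_per_subtype = 4,
                        hazards = c(0.004, 0.002, 0.0013),
                        censor_rate = 0.3,
                        anticorr_fraction = 0.8,
                        seed = 1) {
  spec <- as.list(environment())
  probs <- c(driver_prob, leak_prob, assign_prob, signature_prob,
             background_prob, censor_rate, anticorr_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(hazards <= 0)) stop("hazards must be > 0")
  if (length(hazards) < n_subtypes) stop("need one hazard per subtype")
  n_reserved <- 2 * (n_planted_co + n_planted_me) +
    n_subtypes * (n_signature_per_subtype + 1)
  if (n_reserved > n_genes) {
    stop("n_genes too small for the planted pairs and subtype signatures")
  }
  structure(spec, class = "cohort_spec")
}

# gene / sample / probe identifier helpers
.gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Planted-pair layout of a cohort spec
#'
#' CO and ME pairs occupy disjoint gene pairs at the start of the gene list.
#' Each subtype's signature is a connected chain over
#' `n_signature_per_subtype + 1` consecutive genes (so signature events form
#' a connected subnetwork, as coordinated epigenetic modules do).
#'
#' @param spec A `cohort_spec`.
#' @return Tibble: `gene_a`, `gene_b`, `type` (`CO`/`ME`/`SIG`), `subtype`
#'   (`NA` except for signature pairs).
#' @export
planted_pairs <- function(spec) {
  genes <- .gene_ids(spec$n_genes)
  i <- 0
  take <- function(n = 2) { i <<- i + n; genes[(i - n + 1):i] }
  rows <- list(tibble(gene_a = character(), gene_b = character(),
                      type = character(), subtype = integer()))
  for (k in seq_len(spec$n_planted_co)) {
    p <- take()
    rows[[length(rows) + 1]] <- tibble(gene_a = p[1], gene_b = p[2],
                                       type = "CO", subtype = NA_integer_)
  }
  for (k in seq_len(spec$n_planted_me)) {
    p <- take()
    rows[[length(rows) + 1]] <- tibble(gene_a = p[1], gene_b = p[2],
                                       type = "ME", subtype = NA_integer_)
  }
  for (st in seq_len(spec$n_subtypes)) {
    if (spec$n_signature_per_subtype == 0) next
    chain <- take(spec$n_signature_per_subtype + 1)
    for (k in seq_len(spec$n_signature_per_subtype)) {
      rows[[length(rows) + 1]] <- tibble(gene_a = chain[k],
                                         gene_b = chain[k + 1],
                                         type = "SIG", subtype = st)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a binary alteration matrix with planted structure
#'
#' Null genes are methylated independently with probability
#' `clamp(load_s * rate_g)`.  Planted CO pairs share a latent driver with
#' leak; planted ME pairs show the exactly-one pattern with probability
#' `assign_prob` and background otherwise.  Subtype signature pairs act like
#' CO pairs whose driver probability is `signature_prob` in samples of their
#' subtype and `background_prob` elsewhere.  Normals (`tumor = FALSE`) carry
#' background only.
#'
#' @param spec A `cohort_spec`.
#' @param n_samples Number of samples (default `spec$n_tumor`).
#' @param seed Seed for this matrix.
#' @param tumor If `FALSE`, planted mechanisms are disabled.
#' @param subtype_labels Optional integer subtype per sample (drawn uniformly
#'   when `NULL` and `tumor = TRUE`).
#' @param sample_prefix Prefix for generated sample identifiers.
#' @param gene_rate Optional fixed per-gene rate multipliers (drawn from
#'   `spec$gene_rate_range` when `NULL`).
#' @return List: `matrix` (genes x samples 0/1), `truth` (planted-pair
#'   tibble), `subtype` (named labels or `NULL`), `load`, `gene_rate`.
#' @export
simulate_binary <- function(spec, n_samples = spec$n_tumor,
                            seed = spec$seed, tumor = TRUE,
                            subtype_labels = NULL,
                            sample_prefix = "S", gene_rate = NULL) {
  set.seed(seed)
  genes <- .gene_ids(spec$n_genes)
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  load <- spec$sample_load_scale *
    rbeta(n_samples, spec$sample_load_shape[1], spec$sample_load_shape[2])
  if (is.null(gene_rate)) {
    gene_rate <- runif(spec$n_genes, spec$gene_rate_range[1],
                       spec$gene_rate_range[2])
  }
  p0 <- outer(gene_rate, load)            # genes x samples background prob
  p0 <- pmin(pmax(p0, 0.005), 0.995)
  dimnames(p0) <- list(genes, samples)
  bm <- matrix(rbinom(length(p0), 1L, p0), nrow = spec$n_genes,
               dimnames = list(genes, samples))
  truth <- planted_pairs(spec)
  if (tumor) {
    if (is.null(subtype_labels) && spec$n_subtypes > 1 &&
        spec$n_signature_per_subtype > 0) {
      subtype_labels <- sample.int(spec$n_subtypes, n_samples, replace = TRUE)
    }
    for (k in which(truth$type != "SIG")) {
      ga <- truth$gene_a[k]; gb <- truth$gene_b[k]
      if (truth$type[k] == "CO") {
        d <- rbinom(n_samples, 1L, spec$driver_prob)
        bm[ga, ] <- pmax(d, rbinom(n_samples, 1L, spec$leak_prob))
        bm[gb, ] <- pmax(d, rbinom(n_samples, 1L, spec$leak_prob))
      } else {                             # ME: exclusive latent assignment
        excl <- rbinom(n_samples, 1L, spec$assign_prob) == 1L
        z <- rbinom(n_samples, 1L, 0.5)
        a_bg <- rbinom(n_samples, 1L, p0[ga, ])
        b_bg <- rbinom(n_samples, 1L, p0[gb, ])
        bm[ga, ] <- ifelse(excl, z, a_bg)
        bm[gb, ] <- ifelse(excl, 1L - z, b_bg)
      }
    }
    # SIG chains: one subtype-modulated driver per subtype drives every gene
    # of that subtype's signature chain (with per-gene leak)
    sig <- truth[truth$type == "SIG", , drop = FALSE]
    for (st in unique(sig$subtype)) {
      chain_genes <- unique(unlist(sig[sig$subtype == st,
                                       c("gene_a", "gene_b")]))
      dp <- ifelse(subtype_labels == st, spec$signature_prob,
                   spec$background_prob)
      d <- rbinom(n_samples, 1L, dp)
      for (g in chain_genes) {
        bm[g, ] <- pmax(d, rbinom(n_samples, 1L, spec$leak_prob))
      }
    }
  }
  storage.mode(bm) <- "integer"
  if (!is.null(subtype_labels)) names(subtype_labels) <- samples
  list(matrix = bm, truth = truth,
       subtype = if (tumor) subtype_labels else NULL,
       load = setNames(load, samples),
       gene_rate = setNames(gene_rate, genes))
}

#' Generate the probe manifest of a cohort spec
#'
#' Each gene's probes sit in one promoter region class, cycling through the
#' class vocabulary across genes; every tenth gene gets an extra gene-body
#' probe (class `Other`) that promoter aggregation must ignore.
#'
#' @param spec A `cohort_spec`.
#' @return Manifest tibble: `probe_id`, `gene_id`, `region_class`.
#' @export
make_manifest <- function(spec) {
  classes <- c("TSS1500", "TSS200", "FirstExon", "UTR5")
  genes <- .gene_ids(spec$n_genes)
  rows <- list()
  probe <- 0
  for (i in seq_along(genes)) {
    cls <- classes[((i - 1) %% length(classes)) + 1]
    for (j in seq_len(spec$probes_per_gene)) {
      probe <- probe + 1
      rows[[probe]] <- tibble(probe_id = sprintf("cg%06d", probe),
                              gene_id = genes[i], region_class = cls)
    }
    if (i %% 10 == 0) {
      probe <- probe + 1
      rows[[probe]] <- tibble(probe_id = sprintf("cg%06d", probe),
                              gene_id = genes[i], region_class = "Other")
    }
  }
  dplyr::bind_rows(rows)
}

#' Emit probe-level beta values from binary gene states
#'
#' Probes of a methylated gene-sample cell draw from
#' `Beta(spec$beta_meth)` (mean 0.6), unmethylated cells from
#' `Beta(spec$beta_unmeth)` (mean 0.1), so promoter aggregation followed by
#' binarization at 0.3 recovers the input state for the vast majority of
#' cells.
#'
#' @param bm Binary gene-by-sample matrix.
#' @param spec A `cohort_spec`.
#' @param manifest Manifest from [make_manifest()].
#' @param seed Seed.
#' @return Probe-by-sample beta matrix.
#' @export
simulate_beta_from_binary <- function(bm, spec, manifest, seed = spec$seed) {
  set.seed(seed)
  man <- manifest[manifest$gene_id %in% rownames(bm), , drop = FALSE]
  n_s <- ncol(bm)
  beta <- matrix(NA_real_, nrow = nrow(man), ncol = n_s,
                 dimnames = list(man$probe_id, colnames(bm)))
  for (k in seq_len(nrow(man))) {
    state <- bm[man$gene_id[k], ]
    b <- numeric(n_s)
    meth <- state == 1
    b[meth] <- rbeta(sum(meth), spec$beta_meth[1], spec$beta_meth[2])
    b[!meth] <- rbeta(sum(!meth), spec$beta_unmeth[1], spec$beta_unmeth[2])
    beta[k, ] <- b
  }
  beta
}

#' Simulate an event-by-sample matrix with planted subtypes
#'
#' Events are split into `k` equal signature blocks; an event occurs in a
#' sample with probability `signature_prob` when the event belongs to the
#' sample's subtype block and `background_prob` otherwise.
#'
#' @param n_samples,n_events Matrix dimensions.
#' @param k Number of subtypes.
#' @param signature_prob,background_prob Occurrence probabilities.
#' @param seed Seed.
#' @return List: `esm` (events x samples 0/1 matrix), `labels` (named
#'   integer subtype per sample).
#' @export
simulate_event_matrix <- function(n_samples = 200, n_events = 60, k = 3,
                                  signature_prob = 0.85,
                                  background_prob = 0.1, seed = 1) {
  set.seed(seed)
  labels <- sample(rep(seq_len(k), length.out = n_samples))
  block <- rep(seq_len(k), length.out = n_events)
  P <- matrix(background_prob, n_events, n_samples)
  for (st in seq_len(k)) {
    P[block == st, labels == st] <- signature_prob
  }
  esm <- matrix(rbinom(length(P), 1L, P), n_events, n_samples,
                dimnames = list(sprintf("E%03d", seq_len(n_events)),
                                sprintf("S%04d", seq_len(n_samples))))
  storage.mode(esm) <- "integer"
  list(esm = esm, labels = setNames(labels, colnames(esm)))
}

#' Simulate a gene network with a planted high-signal module
#'
#' Builds an Erdős–Rényi-style random network over `n_nodes` genes, plants a
#' connected module (random spanning tree plus extra edges) of
#' `module_size` genes, and emits node statistics: background genes get
#' standard-normal methylation and expression t statistics, module genes get
#' statistics inflated by `t_inflation` (hypermethylated, down-regulated).
#'
#' @param n_nodes Network size (default 100).
#' @param module_size Planted module size (default 8).
#' @param mean_degree Average background degree (default 4).
#' @param t_inflation Mean shift of the module genes' |t| (default 5).
#' @param seed Seed.
#' @return List: `net` (a `come_network`), `stats` (node-statistics tibble),
#'   `module_genes` (planted members).
#' @export
simulate_module_network <- function(n_nodes = 100, module_size = 8,
                                    mean_degree = 4, t_inflation = 5,
                                    seed = 1) {
  stopifnot(module_size >= 2, module_size <= n_nodes)
  set.seed(seed)
  genes <- .gene_ids(n_nodes)
  p_edge <- mean_degree / (n_nodes - 1)
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p_edge
  edges <- tibble(gene_a = genes[idx[keep, 1]], gene_b = genes[idx[keep, 2]])
  mod <- sort(sample(genes, module_size))
  # random spanning tree over the module guarantees connectivity
  perm <- sample(mod)
  tree <- tibble(gene_a = perm[-length(perm)][sample.int(module_size - 1)],
                 gene_b = perm[-1])
  for (k in seq_len(module_size - 1)) {
    tree$gene_a[k] <- sample(perm[seq_len(k)], 1)
    tree$gene_b[k] <- perm[k + 1]
  }
  extra_n <- module_size                 # densify the module a little
  extra <- tibble(gene_a = sample(mod, extra_n, replace = TRUE),
                  gene_b = sample(mod, extra_n, replace = TRUE))
  extra <- extra[extra$gene_a != extra$gene_b, , drop = FALSE]
  all_edges <- dplyr::bind_rows(edges, tree, extra)
  all_edges <- all_edges[all_edges$gene_a != all_edges$gene_b, , drop = FALSE]
  all_edges$type <- "CO"
  net <- build_network(all_edges)
  t_meth <- rnorm(n_nodes); t_expr <- rnorm(n_nodes)
  in_mod <- genes %in% mod
  t_meth[in_mod] <- abs(rnorm(module_size, t_inflation, 1))
  t_expr[in_mod] <- -abs(rnorm(module_size, t_inflation, 1))
  stats <- node_statistics(tibble(gene_id = genes, t = t_meth),
                           tibble(gene_id = genes, t = t_expr))
  list(net = net, stats = stats, module_genes = mod)
}

#' Simulate exponential survival with subtype-specific hazards
#'
#' Event times are exponential with the subtype's hazard; censoring times
#' are independent exponentials with rate chosen so that roughly
#' `censor_rate` of records are censored.
#'
#' @param subtype Integer subtype per sample.
#' @param hazards Per-subtype hazards (events/day).
#' @param censor_rate Target censoring fraction.
#' @param seed Seed.
#' @return Tibble: `pfi_time` (days, > 0), `pfi_event` (0/1).
#' @export
simulate_survival <- function(subtype, hazards, censor_rate = 0.3, seed = 1) {
  set.seed(seed)
  n <- length(subtype)
  t_event <- rexp(n, rate = hazards[subtype])
  c_rate <- mean(hazards[subtype]) * censor_rate / max(1 - censor_rate, 1e-6)
  t_cens <- if (c_rate > 0) rexp(n, rate = c_rate) else rep(Inf, n)
  tibble(pfi_time = pmax(pmin(t_event, t_cens), 0.5),
         pfi_event = as.integer(t_event <= t_cens))
}

#' Simulate a complete multi-cancer cohort bundle
#'
#' Produces every input the pipeline consumes — probe betas, expression,
#' manifest, clinical table, gene annotation — together with the ground
#' truth (planted pairs, subtype labels, per-cancer binary matrices).
#' Tumor samples carry planted CO/ME pairs and subtype signatures; normal
#' samples carry background only, creating tumor-versus-normal differential
#' occurrence.  Expression is anti-correlated with promoter methylation for
#' `spec$anticorr_fraction` of genes.  Clinical covariates (age, gender,
#' stage, histological type, grade) shift with subtype.
#'
#' @param spec A `cohort_spec`.
#' @return List: `beta`, `expr`, `manifest`, `clinical`, `annotation`,
#'   `truth` (list with `pairs`, `subtype`, `binary_by_cancer`,
#'   `anticorr_genes`).
#' @export
simulate_cohort <- function(spec) {
  genes <- .gene_ids(spec$n_genes)
  manifest <- make_manifest(spec)
  pairs <- planted_pairs(spec)
  sig_genes <- unique(unlist(pairs[pairs$type == "SIG",
                                   c("gene_a", "gene_b")]))
  set.seed(derive_seed(spec$seed, 1))
  gene_rate <- runif(spec$n_genes, spec$gene_rate_range[1],
                     spec$gene_rate_range[2])
  # signature-module genes emulate promoter-hypermethylation-driven
  # repression: background-typical rates and anti-correlated expression
  gene_rate[genes %in% sig_genes] <-
    runif(length(sig_genes), spec$gene_rate_range[1],
          mean(spec$gene_rate_range))
  anticorr <- sort(union(
    sample(genes, round(spec$anticorr_fraction * spec$n_genes)), sig_genes))
  beta_list <- list(); clin_list <- list(); bm_list <- list()
  subtype_all <- integer(0)
  for (ci in seq_along(spec$cancers)) {
    cancer <- spec$cancers[ci]
    tum <- simulate_binary(spec, n_samples = spec$n_tumor,
                           seed = derive_seed(spec$seed, 10 + ci),
                           tumor = TRUE,
                           sample_prefix = paste0(cancer, "_T"),
                           gene_rate = gene_rate)
    nor <- simulate_binary(spec, n_samples = spec$n_normal,
                           seed = derive_seed(spec$seed, 40 + ci),
                           tumor = FALSE,
                           sample_prefix = paste0(cancer, "_N"),
                           gene_rate = gene_rate)
    bm <- cbind(tum$matrix, nor$matrix)
    bm_list[[cancer]] <- bm
    beta_list[[cancer]] <- simulate_beta_from_binary(
      bm, spec, manifest, seed = derive_seed(spec$seed, 70 + ci))
    st <- tum$subtype %||%
      setNames(rep(1L, spec$n_tumor), colnames(tum$matrix))
    subtype_all <- c(subtype_all, st)
    surv <- simulate_survival(st, spec$hazards, spec$censor_rate,
                              seed = derive_seed(spec$seed, 100 + ci))
    set.seed(derive_seed(spec$seed, 130 + ci))
    n_t <- spec$n_tumor; n_n <- spec$n_normal
    age_t <- round(52 + 4 * st + rnorm(n_t, 0, 8))
    gender_t <- ifelse(runif(n_t) < 0.25 + 0.15 * st, "female", "male")
    stage_t <- vapply(st, function(s) {
      sample(c("I", "II", "III", "IV"), 1,
             prob = c(4 - 0.8 * s, 3, 2 + 0.4 * s, 1 + 0.6 * s))
    }, character(1))
    hist_t <- vapply(st, function(s) {
      sample(paste0("type", c("A", "B", "C")), 1,
             prob = c(3 - 0.6 * s, 2, 1 + 0.8 * s))
    }, character(1))
    grade_t <- vapply(st, function(s) {
      sample(c("G1", "G2", "G3", "G4"), 1,
             prob = c(3.5 - 0.7 * s, 3, 1.5 + 0.5 * s, 0.5 + 0.5 * s))
    }, character(1))
    clin_list[[cancer]] <- dplyr::bind_rows(
      tibble(sample_id = colnames(tum$matrix), cancer_type = cancer,
             is_tumor = TRUE, pfi_time = surv$pfi_time,
             pfi_event = surv$pfi_event, age = age_t, gender = gender_t,
             histological_type = hist_t, grade = grade_t, stage = stage_t,
             subtype = unname(st)),
      tibble(sample_id = colnames(nor$matrix), cancer_type = cancer,
             is_tumor = FALSE, pfi_time = 3000, pfi_event = 0L,
             age = round(52 + rnorm(n_n, 0, 8)),
             gender = ifelse(runif(n_n) < 0.5, "female", "male"),
             histological_type = NA_character_, grade = NA_character_,
             stage = NA_character_, subtype = NA_integer_)
    )
  }
  beta <- do.call(cbind, beta_list)
  clinical <- dplyr::bind_rows(clin_list)
  gm <- aggregate_promoter(beta, manifest)
  set.seed(derive_seed(spec$seed, 200))
  expr <- matrix(rnorm(length(genes) * ncol(gm), 8, 1), nrow = length(genes),
                 dimnames = list(genes, colnames(gm)))
  ac <- rownames(gm) %in% anticorr
  expr[rownames(gm)[ac], ] <- 8 - 4 * gm[ac, , drop = FALSE] +
    matrix(rnorm(sum(ac) * ncol(gm), 0, 0.5), nrow = sum(ac))
  planted_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  set.seed(derive_seed(spec$seed, 300))
  annotation <- tibble(
    gene_id = genes,
    is_cancer_gene = ifelse(genes %in% planted_genes,
                            runif(length(genes)) < 0.6,
                            runif(length(genes)) < 0.08),
    is_tsg = ifelse(genes %in% planted_genes,
                    runif(length(genes)) < 0.3,
                    runif(length(genes)) < 0.05)
  )
  list(beta = beta, expr = expr, manifest = manifest, clinical = clinical,
       annotation = annotation,
       truth = list(pairs = pairs, subtype = subtype_all,
                    binary_by_cancer = bm_list, anticorr_genes = anticorr,
                    gene_rate = setNames(gene_rate, genes)))
}
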