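#' Read a probe/gene-by-sample matrix from TSV
#'
#' Reads the single tabular dialect used throughout the package: tab-separated
#' UTF-8 text, a header row of sample identifiers, and row identifiers in the
#' first column. `"NA"` and empty cells denote missing values.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"beta"` (values constrained to \[0, 1\]),
#'   `"expression"` (any real values) or `"binary"` (values in \{0, 1\}).
#' @return A numeric (or integer, for `kind = "binary"`) matrix with row and
#'   column names; file order preserved.
#' @details Readers reject invariant-violating input instead of coercing:
#'   duplicated row or column identifiers, beta values outside \[0, 1\] and
#'   binary values other than 0/1/NA are hard errors that name the offending
#'   coordinates.
#' @export
read_matrix <- function(path, kind = c("beta", "expression", "binary")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a row-id column plus >= 1 sample column: ", path)
  row_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  .check_unique(row_ids, "row id")
  .check_unique(sample_ids, "sample id")
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- list(row_ids, sample_ids)
  if (kind == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("beta value out of [0,1] at row '%s', column '%s': %g",
                   row_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                   values[bad[1, 1], bad[1, 2]]))
    }
  } else if (kind == "binary") {
    bad <- which(!is.na(values) & !(values %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("binary value not in {0,1,NA} at row '%s', column '%s': %g",
                   row_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                   values[bad[1, 1], bad[1, 2]]))
    }
    storage.mode(values) <- "integer"
  }
  values
}

.check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write a matrix to TSV
#'
#' Values are written with 10 significant digits so that a write/read
#' round-trip reproduces them; missing values are written as `NA`.
#'
#' @param mat A matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (row-identifier) column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) "NA" else sprintf("%.10g", v)
    }, character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a probe manifest
#'
#' A manifest maps 450K-style probes to genes and promoter region classes.
#' The closed region-class vocabulary is `TSS1500`, `TSS200`, `FirstExon`,
#' `UTR5` and `Other`; unknown strings are mapped to `Other` with a warning.
#'
#' @param path TSV with columns `probe_id`, `gene_id`, `region_class`.
#' @return A tibble with those three columns, `region_class` normalised to
#'   the closed vocabulary.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  required <- c("probe_id", "gene_id", "region_class")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- as_tibble(df[required])
  out$probe_id <- as.character(out$probe_id)
  out$gene_id <- as.character(out$gene_id)
  out$region_class <- normalize_region_class(out$region_class)
  dup <- duplicated(out[c("probe_id", "gene_id")])
  if (any(dup)) out <- out[!dup, , drop = FALSE]
  out
}

#' @rdname read_manifest
#' @param region_class Character vector of region-class strings.
#' @export
normalize_region_class <- function(region_class) {
  vocab <- c("TSS1500", "TSS200", "FirstExon", "UTR5", "Other")
  # tolerate Illumina's spellings for the same classes
  aliases <- c("1stExon" = "FirstExon", "5'UTR" = "UTR5", "5UTR" = "UTR5")
  rc <- as.character(region_class)
  known <- names(aliases)
  rc[rc %in% known] <- aliases[rc[rc %in% known]]
  unknown <- !(rc %in% vocab)
  if (any(unknown)) {
    warning(sprintf("%d probe(s) with unknown region class mapped to 'Other' (e.g. '%s')",
                    sum(unknown), rc[which(unknown)[1]]))
    rc[unknown] <- "Other"
  }
  rc
}

#' Read a clinical table
#'
#' @param path TSV with columns `sample_id`, `cancer_type`, `is_tumor`,
#'   `pfi_time`, `pfi_event` and optionally `age`, `gender`,
#'   `histological_type`, `grade`, `stage`.
#' @return A tibble; `is_tumor` logical, `pfi_event` integer 0/1.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  required <- c("sample_id", "cancer_type", "is_tumor", "pfi_time", "pfi_event")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  .check_unique(out$sample_id, "sample id")
  out$is_tumor <- as.logical(out$is_tumor)
  if (any(!is.na(out$pfi_time) & out$pfi_time < 0)) stop("pfi_time must be >= 0")
  if (any(!is.na(out$pfi_event) & !(out$pfi_event %in% c(0, 1)))) {
    stop("pfi_event must be 0/1")
  }
  out$pfi_event <- as.integer(out$pfi_event)
  out
}

#' Read a cancer-gene / tumor-suppressor annotation table
#'
#' @param path TSV with columns `gene_id`, `is_cancer_gene`, `is_tsg`.
#' @return A tibble with logical flag columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  required <- c("gene_id", "is_cancer_gene", "is_tsg")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop("gene annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- as_tibble(df[required])
  out$gene_id <- as.character(out$gene_id)
  out$is_cancer_gene <- as.logical(out$is_cancer_gene)
  out$is_tsg <- as.logical(out$is_tsg)
  out
}

# Deterministic TSV writer for result tibbles: fixed column order given by
# the caller, floats at 10 significant digits, Unix newlines.
.write_result_tsv <- function(df, path, num_cols) {
  out <- as.data.frame(df)
  for (cc in intersect(num_cols, colnames(out))) {
    out[[cc]] <- vapply(out[[cc]], function(v) {
      if (is.na(v)) "NA" else sprintf("%.10g", v)
    }, character(1))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write / read an event table
#'
#' Event tables carry one row per CO/ME event with the canonical
#' (lexicographically ordered) gene pair, the test statistics and the
#' supporting cancers.  Rows are ordered by ascending q-value, then by
#' `gene_a` and `gene_b`, so re-writing identical input is byte-identical.
#'
#' @param events A tibble with columns `gene_a`, `gene_b`, `type`, `overlap`,
#'   `expected`, `p_value`, `q_value` and optionally `cancers` (character,
#'   comma-joined) .
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_event_table <- function(events, path) {
  stopifnot(all(c("gene_a", "gene_b", "type", "overlap", "expected",
                  "p_value", "q_value") %in% colnames(events)))
  ev <- as_tibble(events)
  key <- canonical_pair(ev$gene_a, ev$gene_b)
  ev$gene_a <- key$gene_a
  ev$gene_b <- key$gene_b
  if (!("cancers" %in% colnames(ev))) ev$cancers <- ""
  ev$cancers <- vapply(strsplit(ifelse(is.na(ev$cancers), "", ev$cancers), ","),
                       function(x) paste(sort(x), collapse = ","), character(1))
  ev <- ev[order(ev$q_value, ev$gene_a, ev$gene_b), , drop = FALSE]
  cols <- c("gene_a", "gene_b", "type", "overlap", "expected",
            "p_value", "q_value", "cancers")
  .write_result_tsv(ev[cols], path, num_cols = c("expected", "p_value", "q_value"))
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  if ("cancers" %in% colnames(df)) {
    df$cancers <- ifelse(is.na(df$cancers), "", as.character(df$cancers))
  }
  as_tibble(df)
}

#' Write a network edge list
#'
#' @param network A `come_network` object (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  ed <- network$edges
  ed <- ed[order(ed$gene_a, ed$gene_b, ed$type), , drop = FALSE]
  ed$cancers <- vapply(ed$cancers, function(x) paste(sort(x), collapse = ","),
                       character(1))
  .write_result_tsv(ed[c("gene_a", "gene_b", "type", "cancers")], path,
                    num_cols = character(0))
}

#' Read / write a run configuration
#'
#' Run configurations hold every pipeline threshold (beta threshold, q-value
#' cutoff, minimum supporting cancers, clustering parameters, seeds) in one
#' YAML or JSON document.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    cfg <- yaml::read_yaml(path)
  }
  cfg
}
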