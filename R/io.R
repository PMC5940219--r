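#' Read a sample-by-gene expression matrix from TSV
#'
#' Reads a tab-separated expression table (RPKM-like, non-negative) into a
#' numeric matrix with samples in rows and genes in columns.  Gzipped files
#' are read transparently.
#'
#' @param path Path to a TSV file with a header row and row identifiers in
#'   the first column.
#' @param samples_in Either `"rows"` (default; first column holds sample
#'   ids, remaining columns are genes) or `"cols"` (first column holds gene
#'   ids; the matrix is transposed on read).
#' @return Numeric matrix, samples x genes, with `rownames`/`colnames`.
#' @export
read_expression <- function(path, samples_in = c("rows", "cols")) {
  samples_in <- match.arg(samples_in)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1]))
    stop("duplicated ", if (samples_in == "rows") "gene" else "sample",
         " ids in ", path, ": ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  df <- read_tsv_checked(path)
  m <- tsv_to_matrix(df, path)
  if (samples_in == "cols") m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicated sample ids in ", path, ": ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicated gene ids in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  m
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

# First column = row ids; everything else must parse as finite numbers.
# Errors name the offending (row id, column) coordinate.
tsv_to_matrix <- function(df, path) {
  if (ncol(df) < 2) stop("expected id column plus data columns in ", path)
  ids <- as.character(df[[1]])
  dat <- df[, -1, drop = FALSE]
  for (j in seq_along(dat)) {
    col <- dat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) == 0) bad <- which(is.na(num))
      stop("non-numeric value in ", path, " at row '", ids[bad[1]],
           "', column '", colnames(dat)[j], "'")
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      stop("missing value in ", path, " at row '", ids[bad],
           "', column '", colnames(dat)[j], "'")
    }
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (row) to share the mean order-statistic profile.
#' Ties within a sample receive the mean of the reference quantiles they
#' span.
#'
#' @param m Numeric matrix, samples x genes.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  out <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  dimnames(out) <- dimnames(m)
  out
}

#' Preprocess raw expression values for association mapping
#'
#' Applies `log2(x + pseudocount)` to non-negative RPKM-like values,
#' quantile-normalizes across samples, and finally restricts to a gene
#' subset (e.g. a curated cancer-gene panel).  Subsetting happens after
#' normalization so the normalization target reflects the full transcriptome.
#'
#' @param em Numeric matrix, samples x genes, values >= 0 (or already
#'   log-scale with `log2 = FALSE`).
#' @param gene_subset Optional character vector of gene ids to retain.
#' @param log2 Apply the log2 transform (default `TRUE`).
#' @param pseudocount Offset added before the log (default 1).
#' @return Preprocessed samples x genes matrix.
#' @export
preprocess_expression <- function(em, gene_subset = NULL, log2 = TRUE,
                                  pseudocount = 1) {
  stopifnot(is.matrix(em), is.numeric(em))
  if (log2) {
    if (any(em < 0)) stop("expression values must be non-negative before log2")
    em <- log2(em + pseudocount)
  }
  em <- quantile_normalize(em)
  if (!is.null(gene_subset)) {
    keep <- intersect(colnames(em), gene_subset)
    if (length(keep) == 0)
      stop("gene_subset has no overlap with measured genes")
    em <- em[, keep, drop = FALSE]
  }
  em
}

#' Read a MAF-like somatic mutation table from TSV
#'
#' Required columns: `sample_id`, `gene`, `protein_change`, `variant_class`.
#' Extra columns are ignored.
#'
#' @param path TSV path (gzip accepted).
#' @return `data.frame` of mutation records.
#' @export
read_mutations <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sample_id", "gene", "protein_change", "variant_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("mutation table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df[need]
}

#' Build the binary sample-by-allele mutation design matrix
#'
#' Collapses mutation records to one column per distinct mutant allele
#' (`"GENE:proteinchange"`), drops alleles observed in fewer than
#' `min_recurrence` samples of the cohort, and deduplicates repeated
#' (sample, allele) records.
#'
#' @param records `data.frame` with columns `sample_id`, `gene`,
#'   `protein_change`, `variant_class`.
#' @param min_recurrence Minimum cohort count for an allele to be retained
#'   (default 2, i.e. recurrent mutations only).
#' @param samples Optional character vector giving the full sample universe
#'   (e.g. all samples with expression data); samples without any mutation
#'   record then still get an all-zero row.  Defaults to the samples seen
#'   in `records`.
#' @return Binary matrix, samples x alleles, rows and columns in
#'   lexicographic order; allele metadata (gene, protein change, variant
#'   class, cohort count) in `attr(, "allele_meta")`.
#' @export
build_mutation_matrix <- function(records, min_recurrence = 2,
                                  samples = NULL) {
  need <- c("sample_id", "gene", "protein_change", "variant_class")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("records lack required column(s): ", paste(miss, collapse = ", "))
  rec <- records
  for (cc in need) rec[[cc]] <- as.character(rec[[cc]])
  bad <- is.na(rec$gene) | rec$gene == "" |
    is.na(rec$protein_change) | rec$protein_change == ""
  if (any(bad))
    stop(sum(bad), " record(s) missing gene or protein_change")
  rec$allele <- paste0(rec$gene, ":", rec$protein_change)
  rec <- rec[!duplicated(rec[c("sample_id", "allele")]), , drop = FALSE]
  counts <- table(rec$allele)
  keep <- names(counts)[counts >= min_recurrence]
  if (length(keep) == 0)
    stop("no allele reaches min_recurrence = ", min_recurrence)
  rec <- rec[rec$allele %in% keep, , drop = FALSE]
  if (is.null(samples)) {
    samples <- sort(unique(as.character(records$sample_id)))
  } else {
    samples <- sort(unique(as.character(samples)))
    unknown <- setdiff(rec$sample_id, samples)
    if (length(unknown))
      stop("mutation records reference sample(s) outside the given ",
           "universe: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  alleles <- sort(keep)
  X <- matrix(0L, length(samples), length(alleles),
              dimnames = list(samples, alleles))
  X[cbind(match(rec$sample_id, samples), match(rec$allele, alleles))] <- 1L
  meta <- rec[!duplicated(rec$allele),
              c("allele", "gene", "protein_change", "variant_class")]
  meta <- meta[match(alleles, meta$allele), , drop = FALSE]
  meta$count <- as.integer(colSums(X))
  rownames(meta) <- NULL
  attr(X, "allele_meta") <- meta
  X
}

#' Build the standardized functional-impact-score feature table
#'
#' Imputes missing scores with the per-feature mean (e.g. indels lacking a
#' SIFT score), orients every feature so that larger values mean greater
#' predicted impact (SIFT-like features are flipped as `1 - x`, which is
#' equivalent to negation after standardization), and standardizes each
#' feature column to mean 0 and unit population variance.
#'
#' @param raw Numeric matrix or data.frame, alleles x features; `NA` marks
#'   missing scores.  Row names are allele ids.
#' @param higher_is_impact Named logical vector, one entry per feature:
#'   `TRUE` if a larger raw value predicts greater impact (GERP-like),
#'   `FALSE` if smaller raw values are more damaging (SIFT-like).  Features
#'   not named default to `TRUE`, except features whose name contains
#'   `"SIFT"` (case-insensitive), which default to `FALSE`.
#' @return Matrix, alleles x features, standardized; the imputation mask is
#'   kept in `attr(, "missing_mask")` and the applied orientation in
#'   `attr(, "orientation")`.
#' @export
build_feature_table <- function(raw, higher_is_impact = NULL) {
  F <- as.matrix(raw)
  storage.mode(F) <- "double"
  if (is.null(colnames(F)))
    colnames(F) <- paste0("feature", seq_len(ncol(F)))
  orient <- setNames(!grepl("sift", colnames(F), ignore.case = TRUE),
                     colnames(F))
  if (!is.null(higher_is_impact)) {
    if (is.null(names(higher_is_impact)))
      stop("higher_is_impact must be a named logical vector")
    orient[names(higher_is_impact)] <- higher_is_impact
  }
  mask <- is.na(F)
  for (j in seq_len(ncol(F))) {
    v <- F[, j]
    if (all(is.na(v)))
      stop("feature '", colnames(F)[j], "' has no observed values")
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    if (!orient[j]) v <- 1 - v
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    F[, j] <- if (s > 0) (v - mu) / s else 0
  }
  attr(F, "missing_mask") <- mask
  attr(F, "orientation") <- orient
  F
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols.
#'
#' @param path GMT path (gzip accepted).
#' @param uppercase Uppercase gene symbols on read (default `TRUE`).
#' @return Named list of character vectors; set descriptions in
#'   `attr(, "description")`.
#' @export
read_gene_sets <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  descr <- character()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    p <- p[nzchar(p)]
    if (length(p) < 3)
      stop("GMT parse error at line ", i, " of ", path,
           ": expected name, description and at least one gene")
    nm <- p[1]
    if (nm %in% names(sets))
      stop("duplicate gene-set name '", nm, "' in ", path)
    genes <- p[-(1:2)]
    if (uppercase) genes <- toupper(genes)
    sets[[nm]] <- genes
    descr[nm] <- p[2]
  }
  attr(sets, "description") <- descr
  sets
}

#' Read a clinical survival table from TSV
#'
#' Required columns: `sample_id`, `time` (overall survival, months, >= 0)
#' and `event` (1 = death observed, 0 = censored).
#'
#' @param path TSV path (gzip accepted).
#' @return `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival times must be non-negative and non-missing")
  if (!all(df$event %in% c(0, 1)))
    stop("event indicator must be 0/1")
  df
}

#' Read per-allele functional impact scores from TSV
#'
#' First column holds allele ids (`"GENE:proteinchange"`); remaining columns
#' are score features (e.g. `GERP`, `SIFT`).  Empty cells / `NA` mark
#' missing scores and are permitted (they are imputed later by
#' [build_feature_table()]).
#'
#' @param path TSV path (gzip accepted).
#' @return Numeric matrix, alleles x features, possibly with `NA`s.
#' @export
read_feature_scores <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("expected allele id column plus score columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated allele ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Align expression, mutation and clinical tables on shared samples
#'
#' Restricts all inputs to the intersection of their sample ids, in
#' lexicographic order, so downstream results do not depend on input row
#' order.  Dropped samples are reported via `message()`.
#'
#' @param em Expression matrix (samples x genes).
#' @param mm Mutation matrix (samples x alleles).
#' @param clinical Optional clinical `data.frame` with a `sample_id` column.
#' @return List with elements `expression`, `mutations` and (if supplied)
#'   `clinical`, all row-aligned.
#' @export
align_samples <- function(em, mm, clinical = NULL) {
  common <- intersect(rownames(em), rownames(mm))
  if (!is.null(clinical)) common <- intersect(common, clinical$sample_id)
  if (length(common) == 0) stop("no samples shared across inputs")
  common <- sort(common)
  dropped <- setdiff(union(rownames(em), rownames(mm)), common)
  if (length(dropped))
    message("align_samples: dropped ", length(dropped),
            " sample(s) absent from some input")
  out <- list(expression = em[common, , drop = FALSE],
              mutations = mm[common, , drop = FALSE])
  meta <- attr(mm, "allele_meta")
  if (!is.null(meta)) {
    meta$count <- as.integer(colSums(out$mutations))
    attr(out$mutations, "allele_meta") <- meta
  }
  if (!is.null(clinical))
    out$clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  out
}
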