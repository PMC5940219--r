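#' Configuration for the synthetic driver-mutation data generator
#'
#' Defaults describe a desk-scale tumor cohort with planted sparse
#' mutation-to-expression effects: 200 samples, 200 genes, 50 recurrent
#' mutant alleles of which 5 are drivers each regulating 30 genes with
#' effect size 1 (in expression-SD units of the standardized design)
#' against unit Gaussian noise.
#'
#' @param n_samples,n_genes,n_alleles,n_drivers Cohort and model sizes.
#' @param genes_per_driver Number of genes each driver regulates.
#' @param effect_size Magnitude of nonzero association coefficients; signs
#'   are random (drivers may activate or repress expression).
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param allele_freq_range Range of per-allele carrier frequencies
#'   (uniform draw; identical for drivers and passengers, so frequency
#'   carries no driver signal).
#' @param n_features Number of functional impact score features (2 =
#'   GERP-like conservation + SIFT-like tolerance).
#' @param feature_informativeness Mean shift (in SD units) of driver
#'   alleles' latent impact; 0 makes the scores uninformative.
#' @param missing_feature_rate Fraction of alleles with a missing SIFT-like
#'   score (emulating indels that annotators skip).
#' @param baseline_hazard Exponential death hazard per month for a sample
#'   at the median prognostic score.
#' @param log_hr_per_sd Log hazard ratio per standard deviation of the true
#'   integrative prognostic score.
#' @param censoring_rate Expected fraction of censored samples.
#' @param seed Integer seed.
#' @return List of class `"exdriver_simconfig"`.
#' @export
simulation_config <- function(n_samples = 200, n_genes = 200,
                              n_alleles = 50, n_drivers = 5,
                              genes_per_driver = 30, effect_size = 1,
                              noise_sd = 1,
                              allele_freq_range = c(0.03, 0.2),
                              n_features = 2, feature_informativeness = 1,
                              missing_feature_rate = 0.1,
                              baseline_hazard = log(2) / 60,
                              log_hr_per_sd = 0.8, censoring_rate = 0.3,
                              seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_alleles = n_alleles, n_drivers = n_drivers,
              genes_per_driver = genes_per_driver,
              effect_size = effect_size, noise_sd = noise_sd,
              allele_freq_range = allele_freq_range,
              n_features = n_features,
              feature_informativeness = feature_informativeness,
              missing_feature_rate = missing_feature_rate,
              baseline_hazard = baseline_hazard,
              log_hr_per_sd = log_hr_per_sd,
              censoring_rate = censoring_rate, seed = seed)
  stopifnot(cfg$n_drivers <= cfg$n_alleles,
            cfg$genes_per_driver <= cfg$n_genes,
            cfg$n_samples > 0, cfg$n_genes > 0, cfg$n_alleles > 0,
            all(cfg$allele_freq_range > 0), all(cfg$allele_freq_range < 1))
  structure(cfg, class = "exdriver_simconfig")
}

#' Simulate a cohort with planted mutation-to-expression effects
#'
#' Generates all five pipeline inputs with known ground truth:
#' * mutations: binary sample x allele matrix, per-allele Bernoulli
#'   frequencies, resampled until every allele has at least 2 carriers
#'   (honoring the recurrence filter);
#' * expression: `Y = X_std \%*\% true_beta + N(0, noise_sd^2)` where
#'   `X_std` is the (population-)standardized design and `true_beta` has
#'   `genes_per_driver` entries of `+/- effect_size` per driver column and
#'   all-zero passenger columns;
#' * impact scores: GERP-like (higher = impact) and SIFT-like (lower =
#'   damaging) features driven by a latent impact variable shifted by
#'   `feature_informativeness` for drivers, with some SIFT scores missing;
#' * clinical: exponential survival with log-hazard proportional to the
#'   true integrative prognostic score and independent exponential
#'   censoring calibrated to `censoring_rate`;
#' * gene sets: one set per driver containing its regulated genes, plus
#'   random decoy sets.
#'
#' @param cfg From [simulation_config()].
#' @return Object of class `"exdriver_sim"`: list with `mutations`
#'   (binary matrix with allele metadata), `expression`, `features` (raw
#'   scores with `NA`s), `clinical`, `gene_sets`, `true_beta`,
#'   `true_driver` (named logical), `true_ips` and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  set.seed(substream_seed(cfg$seed, "simulation"))
  n <- cfg$n_samples; G <- cfg$n_genes; M <- cfg$n_alleles
  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(G))
  gene_syms <- sprintf("MUT%03d", seq_len(M))
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "K")
  pchg <- sprintf("%s%d%s", sample(aa, M, TRUE),
                  sample(100:999, M, TRUE), sample(aa, M, TRUE))
  alleles <- paste0(gene_syms, ":", pchg)

  freq <- runif(M, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
  X <- matrix(0L, n, M, dimnames = list(samples, alleles))
  for (k in seq_len(M)) {
    for (try in 1:100) {
      col <- rbinom(n, 1, freq[k])
      if (sum(col) >= 2) break
      if (try == 100)
        stop("allele frequency too low to obtain 2 carriers at n = ", n)
    }
    X[, k] <- col
  }

  is_driver <- setNames(seq_len(M) <= cfg$n_drivers, alleles)
  true_beta <- matrix(0, M, G, dimnames = list(alleles, genes))
  for (k in which(is_driver)) {
    tg <- sample.int(G, cfg$genes_per_driver)
    true_beta[k, tg] <- sample(c(-1, 1), cfg$genes_per_driver, TRUE) *
      cfg$effect_size
  }

  xc <- colMeans(X); xs <- sqrt(colMeans(X^2) - xc^2)
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Y <- Xs %*% true_beta +
    matrix(rnorm(n * G, sd = cfg$noise_sd), n, G)
  dimnames(Y) <- list(samples, genes)

  # latent impact: drivers shifted up, mapped to GERP-like and SIFT-like
  # raw scores (SIFT low = damaging)
  impact <- rnorm(M) + cfg$feature_informativeness * is_driver
  feat <- matrix(NA_real_, M, max(1, cfg$n_features),
                 dimnames = list(alleles,
                                 c("GERP", "SIFT",
                                   sprintf("FIS%d", seq_len(max(
                                     0, cfg$n_features - 2)) + 2))[
                                       seq_len(max(1, cfg$n_features))]))
  feat[, 1] <- 2 + 2 * impact + rnorm(M, sd = 0.5)
  if (ncol(feat) >= 2)
    feat[, 2] <- stats::plogis(-(impact + rnorm(M, sd = 0.5)))
  if (ncol(feat) > 2)
    for (j in 3:ncol(feat)) feat[, j] <- rnorm(M)  # pure-noise features
  variant_class <- rep("missense", M)
  if (cfg$missing_feature_rate > 0 && ncol(feat) >= 2) {
    ind <- runif(M) < cfg$missing_feature_rate
    feat[ind, 2] <- NA
    variant_class[ind] <- "inframe_indel"
  }
  meta <- data.frame(allele = alleles, gene = gene_syms,
                     protein_change = pchg, variant_class = variant_class,
                     count = as.integer(colSums(X)))
  attr(X, "allele_meta") <- meta

  ips <- rowSums((Xs %*% true_beta) * Y)
  ips_z <- if (stats::sd(ips) > 0) (ips - mean(ips)) / stats::sd(ips)
           else rep(0, n)
  rate <- cfg$baseline_hazard * exp(cfg$log_hr_per_sd * ips_z)
  t_event <- rexp(n, rate)
  cr <- min(max(cfg$censoring_rate, 0), 0.99)
  t_cens <- if (cr > 0) rexp(n, rate * cr / (1 - cr)) else rep(Inf, n)
  clinical <- data.frame(sample_id = samples,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens))

  sets <- list()
  for (k in which(is_driver))
    sets[[paste0("TARGETS_OF_", gene_syms[k])]] <-
      genes[true_beta[k, ] != 0]
  for (d in seq_len(5))
    sets[[sprintf("RANDOM_SET_%d", d)]] <-
      genes[sample.int(G, min(G, 25))]

  structure(list(mutations = X, expression = Y, features = feat,
                 clinical = clinical, gene_sets = sets,
                 true_beta = true_beta, true_driver = is_driver,
                 true_ips = setNames(ips, samples), config = cfg),
            class = "exdriver_sim")
}

#' Simulate a null cohort (no drivers)
#'
#' Convenience wrapper around [simulate_dataset()] with `n_drivers = 0`:
#' expression is independent of mutation status and every allele is a
#' passenger.
#'
#' @param cfg From [simulation_config()]; its `n_drivers` is overridden.
#' @return `"exdriver_sim"` object with an all-zero `true_beta`.
#' @export
simulate_null_dataset <- function(cfg = simulation_config()) {
  cfg$n_drivers <- 0
  cfg$feature_informativeness <- 0
  simulate_dataset(cfg)
}

#' @export
print.exdriver_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic cohort: %d samples, %d genes, %d alleles (%d drivers)\n",
    cfg$n_samples, cfg$n_genes, cfg$n_alleles, sum(x$true_driver)))
  cat(sprintf("  effect size %.2f, noise sd %.2f, seed %d\n",
              cfg$effect_size, cfg$noise_sd, cfg$seed))
  invisible(x)
}

#' Write a synthetic dataset as the pipeline's on-disk input formats
#'
#' Emits the exact TSV/GMT dialects the readers consume: `expression.tsv`,
#' `mutations.tsv` (MAF-like records), `features.tsv`, `clinical.tsv`,
#' `gene_sets.gmt` and a `truth.tsv` sidecar listing the planted drivers.
#' A read round-trip reproduces the matrices exactly.
#'
#' @param ds `"exdriver_sim"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "exdriver_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             features = file.path(dir, "features.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(ds$expression, paths["expression"], "sample_id")
  meta <- attr(ds$mutations, "allele_meta")
  idx <- which(ds$mutations == 1L, arr.ind = TRUE)
  rec <- data.frame(
    sample_id = rownames(ds$mutations)[idx[, 1]],
    gene = meta$gene[idx[, 2]],
    protein_change = meta$protein_change[idx[, 2]],
    variant_class = meta$variant_class[idx[, 2]])
  rec <- rec[order(rec$sample_id, rec$gene, rec$protein_change), ]
  write.table(rec, paths["mutations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(ds$features, paths["features"], "allele")
  cl <- ds$clinical
  cl$time <- sprintf("%.17g", cl$time)
  write.table(cl, paths["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gmt <- vapply(names(ds$gene_sets), function(nm)
    paste(c(nm, "synthetic", ds$gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(gmt, paths["gene_sets"])
  truth <- data.frame(allele = names(ds$true_driver),
                      is_driver = as.integer(ds$true_driver),
                      n_target_genes = rowSums(ds$true_beta != 0))
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# Full-precision writer: %.17g round-trips doubles exactly through text.
write_matrix_tsv <- function(m, path, id_col) {
  txt <- apply(m, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  df <- data.frame(rownames(m), txt, check.names = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
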