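#' Differential expression between mutant and wild-type samples
#'
#' Per-gene two-sided Mann-Whitney U-test comparing carriers of a mutation
#' against non-carriers, with Benjamini-Hochberg adjustment across genes.
#' The test is exact (full enumeration, midranks under ties) when both
#' groups have at most 8 samples, and uses the tie-corrected normal
#' approximation otherwise.
#'
#' @param em Expression matrix, samples x genes.
#' @param mutation Binary vector (length = samples): 1 = mutant.
#' @param fdr Significance threshold on the adjusted p (default 0.05).
#' @param mutation_name Label used in error messages.
#' @return `data.frame` with columns `gene`, `p_value`, `q_value`,
#'   `significant`, `direction` (`"up"` if mutant expression is higher).
#' @export
deg_analysis <- function(em, mutation, fdr = 0.05,
                         mutation_name = "mutation") {
  em <- as.matrix(em)
  mutation <- as.numeric(mutation)
  stopifnot(length(mutation) == nrow(em))
  if (sum(mutation == 1) == 0 || sum(mutation == 0) == 0)
    stop("both mutant and wild-type groups must be non-empty for ",
         mutation_name)
  mut <- mutation == 1
  res <- apply(em, 2, function(v) {
    mw <- mann_whitney(v[mut], v[!mut])
    c(mw$p, stats::median(v[mut]) - stats::median(v[!mut]))
  })
  p <- res[1, ]
  q <- p.adjust(p, "BH")
  data.frame(gene = colnames(em), p_value = as.numeric(p),
             q_value = as.numeric(q), significant = q < fdr,
             direction = ifelse(res[2, ] > 0, "up",
                                ifelse(res[2, ] < 0, "down", "none")),
             row.names = NULL)
}

# Two-sided Mann-Whitney U.  Exact enumeration (midranks, so ties are
# handled consistently) when both groups are small; tie-corrected normal
# approximation (no continuity correction) otherwise.
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    return(list(statistic = u_obs, p = min(p, 1), exact = TRUE))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(list(statistic = u_obs, p = 1, exact = FALSE))
  z <- (u_obs - mu) / sqrt(sig2)
  list(statistic = u_obs, p = min(2 * pnorm(-abs(z)), 1), exact = FALSE)
}

#' Hypergeometric over-representation test against gene-set collections
#'
#' For each set, tests whether the gene list is enriched relative to the
#' background via the upper-tail hypergeometric probability
#' `P[overlap >= observed]`, with sets restricted to the background;
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param gene_list Character vector of selected genes (must be a subset of
#'   `background`).
#' @param background Character vector; the gene universe (e.g. all genes
#'   entering the association analysis).
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param fdr Significance threshold on the adjusted p (default 0.05).
#' @return `data.frame` with columns `set`, `overlap`, `set_size`,
#'   `list_size`, `background_size`, `p_value`, `q_value`, `significant`.
#'   Sets with no background overlap are dropped with a warning.
#' @export
gene_set_enrichment <- function(gene_list, background, sets, fdr = 0.05) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  extra <- setdiff(gene_list, background)
  if (length(extra))
    stop("gene_list contains genes absent from the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    if (length(s) == 0) return(NULL)
    k <- length(intersect(gene_list, s))
    p <- phyper(k - 1, length(s), N - length(s), n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s), list_size = n,
               background_size = N, p_value = p)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning(sum(empty), " set(s) dropped: no overlap with the background")
  rows <- rows[!empty]
  if (length(rows) == 0) stop("no gene set overlaps the background")
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < fdr
  out[order(out$p_value), , drop = FALSE]
}

#' Frequency-based driver baseline
#'
#' Ranks mutations (or genes) by cohort occurrence count and calls driver
#' for counts at or above a fixed cutoff.  In gene-level mode counts are
#' summed over all alleles of a gene, regardless of position or amino-acid
#' change.
#'
#' @param counts Named non-negative counts per allele (or per gene).
#' @param cutoff Minimum count called driver (ties at the cutoff are
#'   drivers).
#' @param genes Optional character vector mapping each allele to a gene;
#'   when supplied, counts are aggregated per gene first.
#' @return `data.frame` with columns `id`, `count`, `call`, sorted by
#'   descending count.
#' @export
frequency_baseline <- function(counts, cutoff, genes = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(genes)) {
    stopifnot(length(genes) == length(counts))
    counts <- tapply(counts, genes, sum)
  }
  ids <- names(counts) %||% as.character(seq_along(counts))
  out <- data.frame(id = ids, count = as.numeric(counts),
                    call = ifelse(counts >= cutoff, "driver", "passenger"),
                    row.names = NULL)
  out[order(-out$count, out$id), , drop = FALSE]
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = P[score(positive) > score(negative)] + 0.5 P[tie]`, computed via
#' the midrank formula; invariant under strictly increasing transforms of
#' the scores.
#'
#' @param scores Numeric scores (higher = more driver-like).
#' @param truth Binary labels (1 = positive class).
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.numeric(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix summary metrics
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Named numeric vector with `ppv`, `npv`, `sensitivity`,
#'   `specificity`; metrics with a zero denominator are `NA`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (sum(cnt) == 0) stop("all counts are zero")
  ratio <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  c(ppv = ratio(tp, fp), npv = ratio(tn, fn),
    sensitivity = ratio(tp, fn), specificity = ratio(tn, fp))
}

#' Test composition differences between groups
#'
#' Compares category counts between groups (e.g. clonal/subclonal status of
#' driver vs passenger mutations) via Fisher's exact test or the Pearson
#' chi-squared test without continuity correction.
#'
#' @param table Non-negative integer matrix (2 x 2 or 2 x k).
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return List with `statistic` (chi-squared statistic, or `NA` for
#'   Fisher), `p_value` and `method`.
#' @export
group_composition_test <- function(table, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (method == "fisher") {
    ft <- fisher.test(table)
    list(statistic = NA_real_, p_value = ft$p.value, method = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(table, correct = FALSE))
    stat <- as.numeric(ct$statistic)
    p <- as.numeric(ct$p.value)
    if (is.nan(stat)) { stat <- 0; p <- 1 }  # degenerate margins
    list(statistic = stat, p_value = p, method = "chisq")
  }
}

#' Compare cancer cell fractions between driver and passenger mutations
#'
#' Two-sided Wilcoxon rank-sum test on cancer cell fraction (CCF) values
#' (exact for small groups, tie-corrected normal approximation otherwise).
#'
#' @param ccf_driver,ccf_passenger Numeric vectors of CCFs in `[0, 1]`.
#' @return List with `statistic` (rank-sum U) and `p_value`.
#' @export
ccf_group_comparison <- function(ccf_driver, ccf_passenger) {
  if (length(ccf_driver) == 0 || length(ccf_passenger) == 0)
    stop("both groups must be non-empty")
  all_v <- c(ccf_driver, ccf_passenger)
  if (any(all_v < 0 | all_v > 1))
    stop("cancer cell fractions must lie in [0, 1]")
  mw <- mann_whitney(ccf_driver, ccf_passenger)
  list(statistic = mw$statistic, p_value = mw$p)
}

#' Integrative prognostic score
#'
#' Per-sample scalar combining mutation status, the fitted association
#' matrix and expression: `IPS_s = sum_k sum_j x_sk beta_kj y_sj`, i.e. a
#' bilinear form of the sample's mutation and expression vectors weighted
#' by the association matrix.
#'
#' @param object Fitted `"exdriver"` model or a coefficient matrix
#'   (alleles x genes).
#' @param mutations Binary mutation matrix, samples x alleles (defaults to
#'   the model's training mutations).
#' @param expression Expression matrix, samples x genes (defaults to the
#'   model's training expression).
#' @return Named numeric vector, one score per sample.
#' @export
prognostic_score <- function(object, mutations = NULL, expression = NULL) {
  if (inherits(object, "exdriver")) {
    beta <- object$beta
    mutations <- mutations %||% object$X_raw
    expression <- expression %||% object$Y
  } else beta <- as.matrix(object)
  X <- as.matrix(mutations); Y <- as.matrix(expression)
  if (ncol(X) != nrow(beta) || ncol(Y) != ncol(beta) || nrow(X) != nrow(Y))
    stop("dimension mismatch between mutations (", nrow(X), "x", ncol(X),
         "), beta (", nrow(beta), "x", ncol(beta), ") and expression (",
         nrow(Y), "x", ncol(Y), ")")
  setNames(rowSums((X %*% beta) * Y), rownames(X))
}

# Exact 1-D k-means by dynamic programming on the sorted values
# (O(k n^2) with prefix sums); deterministic, globally optimal.
kmeans1d <- function(values, k) {
  n <- length(values)
  stopifnot(k >= 1, k <= n)
  ord <- order(values)
  v <- values[ord]
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  segcost <- function(i, j) {  # vectorized over i; cost of v[i..j]
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    len <- j - i + 1
    pmax(s2 - s^2 / len, 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- vapply(1:n, function(j) segcost(1, j), numeric(1))
  for (kk in seq_len(k)[-1]) {
    for (j in kk:n) {
      i <- kk:j  # start of last segment
      cand <- D[kk - 1, i - 1] + segcost(i, j)
      best <- which.min(cand)
      D[kk, j] <- cand[best]
      B[kk, j] <- i[best]
    }
  }
  labs_sorted <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- if (kk == 1) 1L else B[kk, j]
    labs_sorted[i:j] <- kk
    j <- i - 1L
    if (j < 1) break
  }
  labels <- integer(n)
  labels[ord] <- labs_sorted
  centers <- vapply(seq_len(k), function(c) mean(values[labels == c]),
                    numeric(1))
  list(labels = labels, centers = centers, withinss = D[k, n])
}

#' Consensus clustering of 1-D scores with exact k-means
#'
#' For each candidate number of clusters, repeatedly subsamples the scores,
#' clusters each subsample with exact (dynamic-programming) one-dimensional
#' k-means, and records how often each pair of samples co-clusters.  The
#' number of clusters is chosen to maximize the cophenetic correlation
#' between the consensus distances (1 - co-clustering frequency) and their
#' average-linkage dendrogram; final labels come from exact k-means on the
#' full data at the chosen k.
#'
#' @param values Numeric scores (e.g. integrative prognostic scores), one
#'   per sample.
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param n_resample Number of subsamples per k (default 50).
#' @param subsample_fraction Fraction of samples per subsample
#'   (default 0.8).
#' @param seed Integer seed.
#' @return Object of class `"exdriver_strat"`: list with `labels`
#'   (cluster per sample), `k`, `cophenetic` (named by k) and `centers`.
#' @export
kmeans1d_consensus <- function(values, k_range = 2:6, n_resample = 50,
                               subsample_fraction = 0.8, seed = 1) {
  n <- length(values)
  if (n < 2 * max(k_range))
    stop("need at least ", 2 * max(k_range), " samples for k up to ",
         max(k_range))
  if (length(unique(values)) == 1)
    stop("all scores identical; no stratification possible")
  m <- max(2L, floor(subsample_fraction * n))
  coph <- setNames(rep(NA_real_, length(k_range)), k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    together <- matrix(0, n, n)
    both <- matrix(0, n, n)
    for (r in seq_len(n_resample)) {
      set.seed(substream_seed(seed, "consensus", k * 100000L + r))
      idx <- sort(sample.int(n, m))
      vs <- values[idx]
      if (length(unique(vs)) < k) next
      cl <- kmeans1d(vs, k)$labels
      same <- outer(cl, cl, "==") * 1
      together[idx, idx] <- together[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
    cons <- ifelse(both > 0, together / both, 0)
    d <- as.dist(1 - cons)
    hc <- hclust(d, method = "average")
    cd <- cophenetic(hc)
    if (stats::sd(d) > 0 && stats::sd(cd) > 0)
      coph[ki] <- cor(cd, d)
  }
  if (all(is.na(coph))) stop("consensus clustering degenerate for every k")
  k_best <- k_range[which.max(coph)]
  km <- kmeans1d(values, k_best)
  structure(list(labels = setNames(km$labels, names(values)), k = k_best,
                 cophenetic = coph, centers = km$centers),
            class = "exdriver_strat")
}

#' @export
print.exdriver_strat <- function(x, ...) {
  cat("Consensus stratification: k =", x$k, "\n")
  cat("Cophenetic correlation by k:\n")
  print(round(x$cophenetic, 4))
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Log-rank comparison of survival between groups
#'
#' Standard (unweighted) k-group log-rank test with k-1 degrees of freedom,
#' plus Kaplan-Meier summaries (per-group median survival and tabulated
#' survival curves).
#'
#' @param time Survival/censoring times (months).
#' @param event Event indicator (1 = death observed).
#' @param group Group labels (at least two non-empty groups).
#' @return List with `statistic`, `df`, `p_value`, `medians` (per-group
#'   median survival), `n` (group sizes) and `curves` (`data.frame` with
#'   columns `group`, `time`, `n_risk`, `survival`).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2)
    stop("need at least two groups for a log-rank test")
  if (any(tabulate(group, nlevels(group)) == 0))
    stop("every group must be non-empty")
  df <- nlevels(group) - 1
  if (sum(event) == 0) {
    stat <- 0; p <- 1
  } else {
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
    stat <- as.numeric(sd_fit$chisq)
    p <- pchisq(stat, df, lower.tail = FALSE)
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(sf)$table
  med <- if (is.matrix(sm)) sm[, "median"] else sm[["median"]]
  strata <- if (!is.null(sf$strata)) rep(names(sf$strata), sf$strata)
            else rep(levels(group)[1], length(sf$time))
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, survival = sf$surv)
  list(statistic = stat, df = df, p_value = p,
       medians = med, n = table(group), curves = curves)
}

#' Stratify samples by prognostic score and test survival separation
#'
#' Convenience pipeline: consensus-cluster the integrative prognostic
#' scores ([kmeans1d_consensus()]) and compare overall survival between the
#' resulting clusters with a log-rank test.
#'
#' @param ips Named numeric vector of prognostic scores (names = sample
#'   ids).
#' @param clinical `data.frame` with `sample_id`, `time`, `event`.
#' @param k_range,n_resample,subsample_fraction,seed Passed to
#'   [kmeans1d_consensus()].
#' @return List with `stratification` (`"exdriver_strat"`) and `logrank`
#'   (see [logrank_test()]).
#' @export
ips_survival <- function(ips, clinical, k_range = 2:6, n_resample = 50,
                         subsample_fraction = 0.8, seed = 1) {
  common <- intersect(names(ips), clinical$sample_id)
  if (length(common) == 0) stop("no samples shared between ips and clinical")
  ips <- ips[common]
  cl <- clinical[match(common, clinical$sample_id), ]
  strat <- kmeans1d_consensus(ips, k_range = k_range,
                              n_resample = n_resample,
                              subsample_fraction = subsample_fraction,
                              seed = seed)
  lr <- logrank_test(cl$time, cl$event, strat$labels)
  list(stratification = strat, logrank = lr)
}
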