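#' Driver scores: number of expression associations per mutation
#'
#' The driver score of allele k is the number of genes j with a nonzero
#' fitted coefficient `beta[k, j]`.
#'
#' @param object Fitted `"exdriver"` model, or a coefficient matrix
#'   (alleles x genes).
#' @return Named integer vector of scores, one per allele.
#' @export
driver_scores <- function(object) {
  beta <- if (inherits(object, "exdriver")) object$beta else as.matrix(object)
  sc <- rowSums(beta != 0)
  storage.mode(sc) <- "integer"
  sc
}

#' Permutation null distribution of driver scores
#'
#' Shuffles the sample order of the whole expression matrix jointly (one
#' permutation vector per replicate, breaking mutation-expression links
#' while preserving gene-gene correlation), refits the model with an
#' identical configuration, and collects the resulting driver scores.
#'
#' @param object Fitted `"exdriver"` model (its stored training data and
#'   control settings are reused).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation stream (default: the fit's
#'   seed).
#' @param pooling `"pooled"` (default): null scores from all alleles and
#'   permutations form one reference distribution; `"per_allele"`: each
#'   allele is compared only against its own permuted scores.
#' @return Object of class `"exdriver_null"` with elements `scores`
#'   (alleles x n_perm integer matrix), `n_perm` and `pooling`.
#' @export
permutation_null <- function(object, n_perm = 100, seed = NULL,
                             pooling = c("pooled", "per_allele")) {
  stopifnot(inherits(object, "exdriver"))
  pooling <- match.arg(pooling)
  if (n_perm < 1) stop("n_perm must be >= 1")
  seed <- seed %||% object$seed
  M <- nrow(object$beta)
  scores <- matrix(NA_integer_, M, n_perm,
                   dimnames = list(rownames(object$beta), NULL))
  n <- object$n
  for (p in seq_len(n_perm)) {
    set.seed(substream_seed(seed, "permutation", p))
    perm <- sample.int(n)
    Yp <- object$Y[perm, , drop = FALSE]
    rownames(Yp) <- rownames(object$Y)
    fit_p <- suppressWarnings(
      exdriver(Yp, object$X_raw, object$features,
               control = object$control, seed = object$seed))
    sc <- driver_scores(fit_p)
    scores[names(sc), p] <- sc
  }
  scores[is.na(scores)] <- 0L  # alleles dropped as degenerate in a refit
  structure(list(scores = scores, n_perm = n_perm, pooling = pooling),
            class = "exdriver_null")
}

#' Empirical p-values of observed driver scores against a permutation null
#'
#' With add-one smoothing:
#' `p_k = (#\{null >= observed_k\} + 1) / (N_null + 1)`, so no p-value is
#' exactly zero.  Under pooled mode the null multiset combines all alleles
#' and permutations; under per-allele mode each allele uses its own row of
#' permuted scores.
#'
#' @param observed Named integer vector of observed driver scores.
#' @param null `"exdriver_null"` object, or a numeric vector of pooled null
#'   scores.
#' @return Numeric vector of p-values in `(0, 1]`, named as `observed`.
#' @export
empirical_pvalues <- function(observed, null) {
  if (inherits(null, "exdriver_null")) {
    if (null$pooling == "per_allele") {
      if (is.null(names(observed)) ||
          !all(names(observed) %in% rownames(null$scores)))
        stop("per-allele null requires observed scores named by allele")
      ns <- null$scores[names(observed), , drop = FALSE]
      k <- rowSums(sweep(ns, 1, observed, ">=") * 1)
      return(setNames((k + 1) / (ncol(ns) + 1), names(observed)))
    }
    pool <- as.vector(null$scores)
  } else {
    pool <- as.numeric(null)
  }
  if (length(pool) == 0) stop("empty null distribution")
  N <- length(pool)
  vapply(observed, function(o) (sum(pool >= o) + 1) / (N + 1), numeric(1))
}

#' Classify mutations as drivers or passengers from empirical p-values
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @param alpha Significance threshold (default 0.05); the call is driver
#'   iff (adjusted) p is strictly below `alpha`.
#' @param adjust `"none"` (default) or `"BH"` (Benjamini-Hochberg).
#' @return Character vector `"driver"`/`"passenger"`, named as `p`.
#' @export
classify_drivers <- function(p, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(p) == 0) return(setNames(character(0), names(p)))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  padj <- if (adjust == "BH") p.adjust(p, "BH") else p
  setNames(ifelse(padj < alpha, "driver", "passenger"), names(p))
}

#' Assemble the per-mutation driver score table
#'
#' Combines driver scores, empirical p-values against a permutation null,
#' BH-adjusted q-values and driver/passenger calls into one table, sorted
#' by ascending p then descending score.
#'
#' @param object Fitted `"exdriver"` model.
#' @param null `"exdriver_null"` from [permutation_null()].
#' @param alpha Call threshold (default 0.05).
#' @param adjust p-value adjustment used for the call, `"none"` (default)
#'   or `"BH"`.
#' @return `data.frame` with columns `allele`, `gene`, `protein_change`,
#'   `score`, `p_value`, `q_value`, `call`.
#' @export
driver_score_table <- function(object, null, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  sc <- driver_scores(object)
  p <- empirical_pvalues(sc, null)
  q <- p.adjust(p, "BH")
  call <- classify_drivers(p, alpha = alpha, adjust = adjust)
  meta <- object$allele_meta
  if (is.null(meta)) {
    parts <- strsplit(names(sc), ":", fixed = TRUE)
    meta <- data.frame(allele = names(sc),
                       gene = vapply(parts, `[`, "", 1),
                       protein_change = vapply(parts, function(x)
                         paste(x[-1], collapse = ":"), ""))
  }
  out <- data.frame(allele = names(sc),
                    gene = meta$gene[match(names(sc), meta$allele)],
                    protein_change =
                      meta$protein_change[match(names(sc), meta$allele)],
                    score = as.integer(sc), p_value = p, q_value = q,
                    call = call, row.names = NULL)
  out[order(out$p_value, -out$score, out$allele), , drop = FALSE]
}

#' Write a driver score table to TSV
#' @param table Output of [driver_score_table()].
#' @param path Output path.
#' @export
write_driver_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
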