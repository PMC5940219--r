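test_that("Mann-Whitney DEG test matches exact enumeration", {
  # fully separated groups of 3: two-sided exact p = 0.1
  em <- cbind(g1 = c(1, 2, 3, 7, 8, 9))
  mut <- c(1, 1, 1, 0, 0, 0)
  tab <- deg_analysis(em, mut)
  expect_equal(tab$p_value, 0.1)
  expect_equal(tab$p_value, mw_enum_oracle(c(1, 2, 3), c(7, 8, 9)))
  expect_equal(tab$direction, "down")

  # identical values: no separation, p = 1
  em2 <- cbind(g1 = rep(2, 6))
  expect_equal(deg_analysis(em2, mut)$p_value, 1)

  expect_error(deg_analysis(em, rep(1, 6)), "non-empty")
})

test_that("exact Mann-Whitney agrees with enumeration under ties", {
  set.seed(44)
  for (i in 1:10) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(1:4, 6, replace = TRUE)
    expect_equal(exdriver:::mann_whitney(x, y)$p, mw_enum_oracle(x, y))
  }
})

test_that("large-sample Mann-Whitney approximates the exact test", {
  set.seed(45)
  x <- rnorm(30); y <- rnorm(35, 0.8)
  approx_p <- exdriver:::mann_whitney(x, y)$p
  exact_p <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(approx_p, exact_p, tolerance = 0.05)
})

test_that("DEG q-values are a monotone rearrangement of p-values", {
  set.seed(46)
  em <- matrix(rnorm(40 * 30), 40, 30,
               dimnames = list(NULL, paste0("g", 1:30)))
  mut <- rep(c(1, 0), each = 20)
  em[mut == 1, 1:5] <- em[mut == 1, 1:5] + 2
  tab <- deg_analysis(em, mut)
  expect_true(all(tab$q_value >= tab$p_value))
  expect_true(all(tab$q_value <= 1))
  o <- order(tab$p_value)
  expect_true(all(diff(tab$q_value[o]) >= 0))
  expect_identical(tab$significant, tab$q_value < 0.05)
})

test_that("hypergeometric enrichment matches combinatorial arithmetic", {
  bg <- paste0("G", 1:10)
  sets <- list(inset = bg[1:5], off = c("X1", "X2"))
  expect_warning(tab <- gene_set_enrichment(bg[1:4], bg, sets),
                 "dropped")
  expect_equal(tab$p_value[tab$set == "inset"], 5 / 210)
  expect_equal(tab$p_value[tab$set == "inset"],
               hyper_enum_oracle(4, 5, 10, 4))

  # overlap 0 with a list of 1: certain event, p = 1
  tab2 <- gene_set_enrichment(bg[6], bg, list(s = bg[1:5]))
  expect_equal(tab2$p_value, 1)

  expect_error(gene_set_enrichment(c(bg[1], "NOPE"), bg, sets),
               "absent from the background")
})

test_that("enrichment p equals enumeration over random small cases", {
  set.seed(47)
  for (i in 1:5) {
    bg <- paste0("G", 1:12)
    set_size <- sample(3:8, 1)
    list_size <- sample(2:6, 1)
    gl <- sample(bg, list_size)
    st <- list(s = bg[seq_len(set_size)])
    got <- gene_set_enrichment(gl, bg, st)$p_value
    expect_equal(got, hyper_enum_oracle(sum(gl %in% st$s), set_size, 12,
                                        list_size))
  }
})

test_that("frequency baseline ranks and calls by count", {
  tab <- frequency_baseline(c(m1 = 5, m2 = 2, m3 = 1), cutoff = 2)
  expect_equal(tab$call, c("driver", "driver", "passenger"))
  expect_equal(tab$id, c("m1", "m2", "m3"))
  # gene-level aggregation regardless of protein change
  tabg <- frequency_baseline(c(a = 2, b = 1), cutoff = 3,
                             genes = c("TP53", "TP53"))
  expect_equal(tabg$count, 3)
  expect_equal(tabg$call, "driver")
})

test_that("AUC handles ties and extremes and matches pair counting", {
  expect_equal(roc_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(1, 2, 9, 10), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(3, 2, 2, 1), c(1, 1, 0, 0)), 0.875)
  expect_equal(roc_auc(c(3, 2, 2, 1), c(1, 1, 0, 0)),
               auc_pairs_oracle(c(3, 2, 2, 1), c(1, 1, 0, 0)))
  set.seed(48)
  sc <- rnorm(40); tr <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(sc, tr), auc_pairs_oracle(sc, tr))
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(sc), tr), roc_auc(sc, tr))
  expect_error(roc_auc(sc, rep(1, 40)), "both classes")
})

test_that("confusion metrics handle the validation-assay counts", {
  cm <- confusion_metrics(tp = 16, fp = 1, tn = 1, fn = 1)
  expect_equal(round(cm[["ppv"]], 2), 0.94)
  expect_equal(cm[["npv"]], 0.5)
  expect_true(is.na(confusion_metrics(0, 0, 1, 1)[["ppv"]]))
  expect_error(confusion_metrics(0, 0, 0, 0), "all counts are zero")
})

test_that("group composition tests match exact references", {
  t1 <- matrix(c(10, 0, 0, 10), 2, 2)
  f <- group_composition_test(t1, "fisher")
  expect_equal(f$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  t2 <- matrix(5, 2, 2)
  expect_equal(group_composition_test(t2, "fisher")$p_value, 1)
  expect_equal(group_composition_test(t2, "chisq")$p_value, 1)

  t3 <- rbind(c(3, 6, 9), c(3, 6, 9))
  c3 <- group_composition_test(t3, "chisq")
  expect_equal(c3$statistic, 0)
  expect_equal(c3$p_value, 1)
  expect_error(group_composition_test(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("CCF comparison validates its domain and tests ranks", {
  same <- ccf_group_comparison(c(0.5, 0.7), c(0.5, 0.7))
  expect_equal(same$p_value, 1)
  r <- ccf_group_comparison(c(0.9, 0.95, 1.0), c(0.1, 0.15, 0.2))
  expect_equal(r$p_value, 0.1)
  expect_error(ccf_group_comparison(c(1.2), c(0.5)), "\\[0, 1\\]")
})

test_that("integrative prognostic score is the stated bilinear form", {
  beta <- rbind(c(1, 2), c(3, 4))  # alleles x genes
  X <- rbind(s1 = c(1, 0), s2 = c(0, 0))
  Y <- rbind(s1 = c(1, 1), s2 = c(5, 5))
  ips <- prognostic_score(beta, X, Y)
  expect_equal(unname(ips), c(3, 0))
  # bilinearity in expression
  expect_equal(unname(prognostic_score(beta, X, 2 * Y)), c(6, 0))
  # a single-nonzero-row beta ignores all other alleles
  b1 <- matrix(0, 3, 2); b1[2, ] <- c(1, -1)
  X3 <- cbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0))
  Y3 <- matrix(rnorm(6), 3, 2)
  ips1 <- prognostic_score(b1, X3, Y3)
  X3b <- X3; X3b[, c(1, 3)] <- X3[c(3, 1, 2), c(1, 3)]
  expect_equal(prognostic_score(b1, X3b, Y3), ips1)
  expect_error(prognostic_score(beta, X3, Y3), "dimension mismatch")
})

test_that("exact 1-D k-means finds the optimal split", {
  km <- exdriver:::kmeans1d(c(0, 0.1, 10, 10.1), 2)
  expect_equal(km$labels, c(1, 1, 2, 2))
  expect_equal(km$centers, c(0.05, 10.05))
  # global optimum beats random Lloyd restarts on a harder instance
  set.seed(49)
  v <- c(rnorm(20), rnorm(20, 3), rnorm(20, 10))
  km3 <- exdriver:::kmeans1d(v, 3)
  best_lloyd <- min(replicate(20, kmeans(v, 3)$tot.withinss))
  expect_lte(km3$withinss, best_lloyd + 1e-8)
})

test_that("consensus clustering recovers two well-separated blobs", {
  for (s in 1:3) {
    set.seed(700 + s)
    v <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
    st <- kmeans1d_consensus(v, seed = s)
    expect_equal(st$k, 2)
    expect_equal(length(unique(st$labels[1:50])), 1)
  }
  set.seed(710)
  v2 <- c(rnorm(30), rnorm(30, 8))
  st1 <- kmeans1d_consensus(v2, seed = 5)
  st2 <- kmeans1d_consensus(v2, seed = 5)
  expect_identical(st1$cophenetic, st2$cophenetic)
  expect_error(kmeans1d_consensus(rep(1, 50)), "identical")
})

test_that("log-rank test matches hand tabulation and handles edge cases", {
  # identical survival experience in both groups
  r0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # all deaths at distinct times: compare to the tabulation oracle
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); gr <- c("A", "A", "B", "B")
  r <- logrank_test(tm, ev, gr)
  expect_equal(r$statistic, logrank_oracle(tm, ev, gr), tolerance = 1e-10)

  # no deaths at all: nothing to compare
  rc <- logrank_test(c(5, 6, 7, 8), c(0, 0, 0, 0), c(1, 1, 2, 2))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)

  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two groups")
})

test_that("log-rank has power under hazard ratio 3 and holds size under 1", {
  rejections_hr3 <- 0
  for (s in 1:10) {
    set.seed(800 + s)
    grp <- rep(1:2, each = 100)
    tm <- rexp(200, rate = ifelse(grp == 1, 0.02, 0.06))
    cens <- rexp(200, 0.01)
    r <- logrank_test(pmin(tm, cens), as.integer(tm <= cens), grp)
    rejections_hr3 <- rejections_hr3 + (r$p_value < 0.05)
  }
  expect_gte(rejections_hr3, 9)

  rejections_hr1 <- 0
  for (s in 1:40) {
    set.seed(900 + s)
    grp <- rep(1:2, each = 100)
    tm <- rexp(200, 0.02)
    r <- logrank_test(tm, rep(1L, 200), grp)
    rejections_hr1 <- rejections_hr1 + (r$p_value < 0.05)
  }
  expect_lte(rejections_hr1 / 40, 0.15)
})

test_that("ips_survival separates clusters with distinct hazards", {
  set.seed(60)
  ips <- setNames(c(rnorm(60, 0, 0.3), rnorm(60, 5, 0.3)),
                  sprintf("s%03d", 1:120))
  grp <- rep(1:2, each = 60)
  tm <- rexp(120, ifelse(grp == 1, 0.01, 0.05))
  clin <- data.frame(sample_id = names(ips), time = tm, event = 1L)
  res <- ips_survival(ips, clin, seed = 2)
  expect_equal(res$stratification$k, 2)
  expect_lt(res$logrank$p_value, 0.05)
  expect_true(all(c("group", "time", "n_risk", "survival") %in%
                    names(res$logrank$curves)))
})
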