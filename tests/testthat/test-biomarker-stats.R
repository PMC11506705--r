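# Cohort statistics: logit/BH, rank tests, ROC, MCC, clustering, PCA.

test_that("logit transform is antisymmetric and clamps boundaries", {
  expect_equal(logit_transform(0.5), 0)
  withr::with_seed(51, {
    p <- runif(20, 0.01, 0.99)
    expect_equal(logit_transform(p), -logit_transform(1 - p))
  })
  expect_warning(z <- logit_transform(0), "clamped")
  expect_equal(z, log(1e-6 / (1 - 1e-6)))
  expect_error(logit_transform(1.2), "\\[0, 1\\]")
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  withr::with_seed(52, {
    for (rep in 1:20) {
      p <- runif(sample(1:12, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      # monotone in sorted p, capped at 1, never below the raw p
      expect_false(is.unsorted(adj[order(p)]))
      expect_true(all(adj <= 1 & adj >= p))
    }
  })
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
})

test_that("method comparison flags only truly shifted contrasts", {
  withr::with_seed(53, {
    cells <- c("HeLa", "K562", "T47D")
    bands <- c("high", "intermediate", "low")
    grid <- expand.grid(cell = cells, band = bands, method = c("PRM", "SDS"),
                        rep = 1:3, stringsAsFactors = FALSE)
    base <- c(high = 60, intermediate = 30, low = 10)
    grid$percent <- base[grid$band] + rnorm(nrow(grid), sd = 0.5)
    # identical generating percentages -> nothing significant
    res0 <- method_comparison(grid)
    expect_true(all(res0$label == "n.s."))
    # a large synthetic offset in one (cell, band) -> only that contrast fires
    shifted <- grid
    sel <- shifted$cell == "HeLa" & shifted$band == "low" &
      shifted$method == "SDS"
    shifted$percent[sel] <- shifted$percent[sel] + 30
    res1 <- method_comparison(shifted)
    hit <- res1$cell == "HeLa" & res1$band == "low"
    expect_true(all(res1$p_adj[hit] < 0.001))
    expect_true(all(res1$label[!hit] == "n.s."))
  })
  expect_error(method_comparison(
    data.frame(percent = c(10, 12, 11), method = c("PRM", "PRM", "SDS"),
               cell = "HeLa", band = "low")), "fewer than 2 replicates")
})

test_that("MCC equals the printed formula and the phi identity", {
  expect_equal(mcc(confusion_matrix(2, 5, 1, 0)), 10 / sqrt(180))
  expect_equal(round(mcc(confusion_matrix(2, 5, 1, 0)), 4), 0.7454)
  expect_equal(mcc(confusion_matrix(10, 10, 0, 0)), 1)
  expect_equal(mcc(confusion_matrix(0, 0, 5, 5)), -1)
  expect_equal(mcc(confusion_matrix(0, 3, 0, 2)), 0)   # zero factor convention
  withr::with_seed(54, {
    for (rep in 1:50) {
      cts <- sample(0:8, 4, replace = TRUE)
      if (sum(cts) == 0) cts[1] <- 1
      cm <- confusion_matrix(cts[1], cts[2], cts[3], cts[4])
      expect_equal(mcc(cm), oracle_mcc_phi(cts[1], cts[2], cts[3], cts[4]),
                   tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney U counts pairs with half-credit ties", {
  expect_equal(mann_whitney_u(c(5, 6, 7), c(1, 2)), 0)    # complete separation
  expect_equal(mann_whitney_u(c(1, 2), c(5, 6, 7)), 6)    # complete reversal
  expect_equal(mann_whitney_u(c(1, 3), c(3)), 1.5)        # one tie -> 0.5
  # agreement with wilcox.test's statistic (W = pairs group1 above group2)
  withr::with_seed(55, {
    for (rep in 1:20) {
      g1 <- rnorm(sample(3:8, 1)); g2 <- rnorm(sample(3:8, 1))
      U <- mann_whitney_u(g1, g2)
      W <- suppressWarnings(stats::wilcox.test(g1, g2)$statistic)
      expect_equal(U, length(g1) * length(g2) - unname(W))
    }
  })
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Wendt r maps U to [-1, 1] with the expected anchors", {
  expect_equal(brcc(0, 8, 2), 1)
  expect_equal(brcc(8, 8, 2), 0)
  expect_equal(brcc(16, 8, 2), -1)
  expect_error(brcc(17, 8, 2), "U must lie")
})

test_that("critical r agrees with the exact wilcoxon distribution everywhere", {
  # independent oracle: R's exact Mann-Whitney null CDF pwilcox
  for (n1 in 1:6) {
    for (n2 in 1:(12 - n1)) {
      if (n2 < 1) next
      crit <- brcc_critical(n1, n2, 0.05)
      us <- 0:(n1 * n2)
      ok <- us[stats::pwilcox(us, n2, n1) <= 0.05]
      if (length(ok) == 0) {
        expect_true(is.na(crit$critical_u))
      } else {
        expect_equal(crit$critical_u, max(ok))
        expect_equal(crit$critical_r, 1 - 2 * max(ok) / (n1 * n2))
      }
    }
  }
})

test_that("the (8, 2) cohort needs r >= 0.875 at one-sided alpha 0.05", {
  crit <- brcc_critical(8, 2, 0.05)
  expect_equal(crit$critical_u, 1)
  expect_equal(crit$p_at_critical, 2 / 45, tolerance = 1e-12)
  expect_equal(crit$critical_r, 0.875)
  expect_equal(round(crit$critical_r, 2), 0.88)
})

test_that("rank_test ties U, r and significance together", {
  rt <- rank_test(c(40, 55, 55, 60, 62, 65), c(120, 140))
  expect_equal(rt$U, 12)         # non-responders all above: U = n1*n2
  expect_equal(rt$U_min, 0)
  expect_equal(rt$r_min, 1)
  expect_true(rt$significant)
})

test_that("ROC reproduces the pair-counting oracle and the U identity", {
  pos <- c(10, 9); neg <- c(9.5, 8, 7, 6, 5, 4)
  r <- roc_curve(c(pos, neg), rep(c("pos", "neg"), c(2, 6)), positive = "pos")
  expect_equal(r$auc, 11 / 12)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 5 / 6)
  expect_equal(r$youden_j, 5 / 6)
  # perfect separation
  rp <- roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0), positive = "1")
  expect_equal(rp$auc, 1); expect_equal(rp$youden_j, 1)
  # AUC = U'/(n1*n2) for every random instance
  withr::with_seed(56, {
    for (rep in 1:20) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      sc <- round(c(rnorm(n1, 1), rnorm(n2)), 1)   # rounding forces some ties
      lab <- rep(c("p", "n"), c(n1, n2))
      r <- roc_curve(sc, lab, positive = "p")
      Uprime <- mann_whitney_u(sc[lab == "n"], sc[lab == "p"])
      expect_equal(r$auc, Uprime / (n1 * n2), tolerance = 1e-12)
      # J-optimal point lies on the curve
      expect_true(any(abs(r$points$sensitivity - r$sensitivity) < 1e-12 &
                        abs(r$points$specificity - r$specificity) < 1e-12))
    }
  })
  expect_error(roc_curve(1:3, c("a", "a", "a")), "two classes")
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(57, {
    for (rep in 1:10) {
      sc <- rnorm(12); lab <- sample(c(0, 1), 12, replace = TRUE)
      if (length(unique(lab)) < 2) next
      ours <- roc_curve(sc, lab, positive = "1")
      ref <- suppressMessages(pROC::roc(lab, sc, direction = "<"))
      expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    }
  })
})

test_that("classify_at builds the confusion matrix at a threshold", {
  sc <- c(10, 9, 9.5, 8, 7, 6, 5, 4)
  lab <- rep(c("pos", "neg"), c(2, 6))
  cm <- classify_at(sc, lab, 8.5, positive = "pos")
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 2L, tn = 5L, fp = 1L, fn = 0L))
})

test_that("average-linkage correlation clustering matches brute force", {
  withr::with_seed(58, {
    for (rep in 1:10) {
      n <- sample(4:8, 1)
      m <- matrix(rnorm(n * 5), nrow = n)
      rownames(m) <- paste0("s", seq_len(n))
      got <- hierarchical_cluster(m, k = 2)
      oracle <- oracle_average_linkage(1 - cor(t(m)), k = 2)
      expect_equal(sort(got$hclust$height), sort(oracle$heights),
                   tolerance = 1e-9)
      expect_true(same_partition(got$clusters, oracle$membership))
    }
  })
  # duplicated profiles are at distance zero and merge first
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 1, 0), d = c(0, 5, 1))
  got <- hierarchical_cluster(m)
  expect_equal(got$hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(as.matrix(got$distance)["a", "b"], 0, tolerance = 1e-12)
  # anticorrelated profiles sit at distance 2
  anti <- rbind(u = c(1, 2, 3), v = c(3, 2, 1), w = c(1, 3, 1))
  expect_equal(as.matrix(hierarchical_cluster(anti)$distance)["u", "v"], 2,
               tolerance = 1e-12)
  expect_error(hierarchical_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance")
})

test_that("PCA variance percentages behave and signs are canonical", {
  # collinear two-feature data: one component carries everything
  m <- cbind(x = c(1, 2, 3, 4), y = 2 * c(1, 2, 3, 4))
  p <- pca_profiles(m, scale. = FALSE)
  expect_equal(p$percent_variance[1], 100, tolerance = 1e-9)
  withr::with_seed(59, {
    m2 <- matrix(rnorm(40), nrow = 8)
    p2 <- pca_profiles(m2)
    expect_equal(sum(p2$percent_variance), 100, tolerance = 1e-9)
    # largest-magnitude loading positive on every component
    for (j in seq_len(ncol(p2$loadings))) {
      v <- p2$loadings[, j]
      expect_gt(v[which.max(abs(v))], 0)
    }
    # explained variance invariant under orthogonal feature rotation
    qr_q <- qr.Q(qr(matrix(rnorm(25), 5)))
    p3 <- pca_profiles(m2 %*% qr_q, scale. = FALSE)
    p2u <- pca_profiles(m2, scale. = FALSE)
    expect_equal(p3$percent_variance, p2u$percent_variance, tolerance = 1e-9)
  })
  expect_error(pca_profiles(cbind(c(1, 1, 1), c(1, 2, 3))), "constant column")
})
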