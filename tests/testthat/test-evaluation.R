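# pair-counting AUROC oracle: P(score_pos > score_neg) + 0.5 P(tie)
pair_count_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

test_that("AUROC equals brute-force pair counting, with ties", {
  withr::with_seed(21, {
    for (i in 1:5) {
      n <- 50
      scores <- sample(rnorm(20), n, replace = TRUE)  # heavy ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      rp <- roc_pr(scores, labels)
      expect_equal(rp$auroc, pair_count_auroc(scores, labels))
    }
  })
})

test_that("perfect separation gives AUROC 1 and APS 1; all-tied gives 0.5", {
  rp <- roc_pr(c(3, 4, 5, 0, 1, 2), c(1, 1, 1, 0, 0, 0))
  expect_equal(rp$auroc, 1)
  expect_equal(rp$aps, 1)
  rp2 <- roc_pr(rep(1, 10), rep(0:1, 5))
  expect_equal(rp2$auroc, 0.5)
})

test_that("APS equals naive step-curve summation over threshold blocks", {
  naive_aps <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    n1 <- sum(labels == 1)
    prev_r <- 0; aps <- 0
    for (t in thr) {
      sel <- scores >= t
      tp <- sum(labels[sel] == 1)
      prec <- tp / sum(sel)
      rec <- tp / n1
      aps <- aps + (rec - prev_r) * prec
      prev_r <- rec
    }
    aps
  }
  withr::with_seed(22, {
    for (i in 1:5) {
      scores <- sample(rnorm(30), 120, replace = TRUE)
      labels <- rbinom(120, 1, 0.3)
      rp <- roc_pr(scores, labels)
      expect_equal(rp$aps, naive_aps(scores, labels))
    }
  })
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(23, {
    scores <- rnorm(200); labels <- rbinom(200, 1, 0.5)
    a <- roc_pr(scores, labels)$auroc
    expect_equal(roc_pr(exp(scores), labels)$auroc, a)
    expect_equal(roc_pr(qlogis(plogis(scores)), labels)$auroc, a)
  })
})

test_that("random scores give APS near prevalence", {
  withr::with_seed(24, {
    scores <- rnorm(2000); labels <- rbinom(2000, 1, 0.1)
    expect_lt(abs(roc_pr(scores, labels)$aps - 0.1), 0.03)
  })
})

test_that("AUROC agrees with an independent ROC implementation", {
  withr::with_seed(25, {
    scores <- rnorm(300); labels <- rbinom(300, 1, 0.4)
    ours <- roc_pr(scores, labels)$auroc
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs)
  })
})

test_that("MPRA filtering applies barcode, p-value and class rules", {
  tab <- tibble::tibble(
    ref = c("A", "C", "GT", "ACG", "T"),
    alt = c("G", "T", "G", "A", "C"),
    barcodes = c(9L, 12L, 15L, 30L, 9L),
    p_value = c(1e-6, 2e-5, 1e-7, 1e-8, 1e-9)
  )
  kept <- filter_mpra(tab)
  # row1 fails barcodes, row2 fails p, row3 passes (1bp DEL), row4 wrong class,
  # row5 fails barcodes
  expect_equal(nrow(kept), 1)
  expect_equal(kept$ref, "GT")
  # permissive thresholds keep every SNV/1bp-DEL row
  expect_equal(nrow(filter_mpra(tab, min_barcodes = 0, alpha = 1)), 4)
})

test_that("filter_mpra equals a naive row-by-row filter on random tables", {
  withr::with_seed(26, {
    n <- 200
    tab <- tibble::tibble(
      ref = sample(c("A", "C", "AT", "GGG"), n, TRUE),
      alt = sample(c("G", "T", "A"), n, TRUE),
      barcodes = rpois(n, 12),
      p_value = 10^-runif(n, 0, 8)
    )
    tab <- tab[tab$ref != tab$alt, ]
    got <- filter_mpra(tab)
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      cls_ok <- (nchar(tab$ref[i]) == 1 && nchar(tab$alt[i]) == 1) ||
        (nchar(tab$ref[i]) == 2 && nchar(tab$alt[i]) == 1)
      keep[i] <- cls_ok && tab$barcodes[i] >= 10 && tab$p_value[i] < 1e-5
    }
    expect_equal(got, tab[keep, ])
  })
})

test_that("correlate handles ties, absolute values, and rejects constants", {
  # hand-computable 4-point case with one tie in scores:
  # scores (1, 2, 2, 4) -> ranks (1, 2.5, 2.5, 4); effects (1,2,3,4)
  s <- c(1, 2, 2, 4); e <- c(1, 2, 3, 4)
  rs <- c(1, 2.5, 2.5, 4); re <- 1:4
  want <- sum((rs - mean(rs)) * (re - mean(re))) /
    sqrt(sum((rs - mean(rs))^2) * sum((re - mean(re))^2))
  expect_equal(correlate(s, e, method = "spearman"), want)
  expect_equal(correlate(abs(e), -e, absolute = TRUE, method = "spearman"), 1)
  expect_error(correlate(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("independent scores correlate near zero under a fixed permutation", {
  withr::with_seed(27, {
    e <- rnorm(1000)
    s <- sample(e)
    expect_lt(abs(correlate(s, e, method = "spearman")), 0.08)
  })
})

test_that("bootstrap correlation: degenerate runs and sd behavior", {
  withr::with_seed(28, {
    x <- rnorm(500); y <- x + rnorm(500, sd = 0.6)
    full <- correlate(x, y, method = "spearman")
    b1 <- bootstrap_correlation(x, y, n_runs = 1, fraction = 1, seed = 2)
    expect_equal(b1$estimate, full)
    expect_equal(b1$sd, 0)
    # monotone pair set: mean 1, sd 0
    b2 <- bootstrap_correlation(1:50, (1:50)^2, n_runs = 20, fraction = 0.8,
                                seed = 3)
    expect_equal(b2$estimate, 1)
    expect_equal(b2$sd, 0)
    # estimate close to full-sample value
    b3 <- bootstrap_correlation(x, y, n_runs = 200, fraction = 0.8, seed = 4)
    expect_lt(abs(b3$estimate - full), 3 * b3$sd / sqrt(200) * 50)
    expect_lt(abs(b3$estimate - full), 0.05)
    # deterministic per seed
    b4 <- bootstrap_correlation(x, y, n_runs = 200, fraction = 0.8, seed = 4)
    expect_equal(b3, b4)
  })
})

test_that("bootstrap sd shrinks as the subsample fraction grows", {
  withr::with_seed(29, {
    x <- rnorm(400); y <- x + rnorm(400)
    sds <- vapply(c(0.5, 0.8, 1.0), function(f) {
      bootstrap_correlation(x, y, n_runs = 150, fraction = f, seed = 5)$sd
    }, 0)
    expect_true(all(diff(sds) < 0))
  })
})

test_that("weighted averaging weights by variant count", {
  one <- tibble::tibble(correlation = 0.7, n_variants = 10)
  expect_equal(weighted_average(one), 0.7)
  two <- tibble::tibble(correlation = c(0.2, 0.8), n_variants = c(100, 300))
  expect_equal(weighted_average(two), 0.65)
  withr::with_seed(30, {
    tab <- tibble::tibble(correlation = runif(10, -1, 1),
                          n_variants = sample(5:50, 10))
    naive <- 0; tot <- 0
    for (i in 1:10) {
      naive <- naive + tab$correlation[i] * tab$n_variants[i]
      tot <- tot + tab$n_variants[i]
    }
    expect_equal(weighted_average(tab), naive / tot)
  })
})

test_that("MAF correlation is Pearson with validated input", {
  expect_equal(maf_correlation(-(1:10) / 20, (1:10) / 20), -1)
  withr::with_seed(31, {
    s <- rnorm(100); m <- runif(100, 0, 0.5)
    expect_equal(maf_correlation(s, m),
                 correlate(s, m, method = "pearson"))
  })
  expect_error(maf_correlation(1:5, c(0.1, 0.2, 0.3, 0.6, 0.1)), "0.5")
})
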