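test_that("Mann-Whitney AUC handles separation, ties and the 4-pair case", {
  expect_equal(auc_mann_whitney(c(3, 4), c(1, 2))$auc, 1.0)
  expect_equal(auc_mann_whitney(rep(2, 5), rep(2, 7))$auc, 0.5)
  # brute force over the 4 pairs: (1 + 1 + 0.5 + 1)/4
  expect_equal(auc_mann_whitney(c(2, 3), c(1, 2))$auc, 0.875)
  expect_error(auc_mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("AUC equals trapezoidal ROC integration on random data", {
  trapezoid_auc <- function(pos, neg) {
    # empirical ROC by threshold sweep, trapezoidal area
    th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  withr::with_seed(42, {
    for (i in 1:25) {
      pos <- round(rnorm(sample(3:30, 1), mean = runif(1)), 1) # many ties
      neg <- round(rnorm(sample(3:30, 1)), 1)
      expect_equal(auc_mann_whitney(pos, neg)$auc, trapezoid_auc(pos, neg),
                   tolerance = 1e-12)
    }
  })
})

test_that("DeLong test is symmetric and sane under the null", {
  withr::with_seed(7, {
    pos <- rnorm(30)
    neg <- rnorm(30)
  })
  d <- delong_test(pos, neg)
  expect_true(abs(d$auc - 0.5) < 0.2)
  expect_gt(d$p_value, 0.05)
  swapped <- delong_test(neg, pos)
  expect_equal(swapped$auc, 1 - d$auc, tolerance = 1e-12)
  expect_equal(swapped$p_value, d$p_value, tolerance = 1e-12)
  expect_warning(delong_test(c(10, 11, 12), c(1, 2, 3)), "separation")
  expect_error(delong_test(1, 1:5), ">= 2")
})

test_that("paired DeLong detects a better marker on shared subjects", {
  withr::with_seed(11, {
    x_pos <- rnorm(40, 1)
    x_neg <- rnorm(40, 0)
    noise_pos <- rnorm(40)
    noise_neg <- rnorm(40)
  })
  same <- suppressWarnings(delong_paired_test(x_pos, x_neg, x_pos, x_neg))
  expect_equal(same$difference, 0)
  better <- delong_paired_test(x_pos, x_neg, noise_pos, noise_neg)
  expect_gt(better$auc1, better$auc2)
  expect_lt(better$p_value, 0.05)
  expect_error(delong_paired_test(x_pos, x_neg, noise_pos, noise_neg[-1]),
               "identical subjects")
})

test_that("nonparametric battery applies the declared family and Bonferroni", {
  withr::with_seed(3, {
    n <- 30
    long <- rbind(
      data.frame(id = 1:n, compartment = "medial", variant = "A",
                 kl_group = rep(c("KL01", "KL2", "KL34"), length.out = n),
                 value = rnorm(n) + 1), # medial shifted up by 1
      data.frame(id = 1:n, compartment = "lateral", variant = "A",
                 kl_group = rep(c("KL01", "KL2", "KL34"), length.out = n),
                 value = rnorm(n)))
  })
  design <- list(
    list(test = "kruskal_wallis", value = "value", group = "kl_group",
         label = "KL groups"),
    list(test = "wilcoxon", value = "value", within = "compartment",
         id = "id", levels = c("medial", "lateral"), label = "med vs lat"),
    list(test = "friedman", value = "value", within = "compartment",
         id = "id", label = "variants"))
  out <- nonparametric_battery(long, design)
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$bonferroni_adjusted_alpha), 0.05 / 3)
  # the planted +1 paired shift is detected at n = 30
  expect_lt(out$p_value[out$label == "med vs lat"], 0.01)

  # pairing mismatch errors
  broken <- long[-1, ]
  expect_error(nonparametric_battery(broken, design[2]), "pairing mismatch")
})

test_that("Kruskal-Wallis null calibration holds over replicates", {
  rejections <- withr::with_seed(19, {
    vapply(1:100, function(i) {
      x <- rnorm(45)
      g <- rep(c("a", "b", "c"), each = 15)
      kruskal.test(x, factor(g))$p.value < 0.05
    }, logical(1))
  })
  expect_lte(mean(rejections), 0.10)
})

test_that("JSN-degeneration verification separates signal from noise", {
  withr::with_seed(23, {
    n <- 500
    frac_m <- runif(n, 0, 0.5)
    frac_l <- runif(n, 0, 0.3)
    deg <- data.frame(id = 1:n, fraction_medial = frac_m,
                      fraction_lateral = frac_l,
                      fraction_overall = (frac_m + frac_l) / 2)
    # perfectly linear relation
    jsn_lin <- data.frame(id = 1:n,
                          jsn_medial = 40 * deg$fraction_overall + 2,
                          jsn_lateral = 0)
    # independent JSN
    jsn_null <- data.frame(id = 1:n, jsn_medial = rnorm(n, 5, 3),
                           jsn_lateral = rnorm(n, 5, 3))
  })
  lin <- verify_jsn_vs_degeneration(jsn_lin, deg)
  expect_gt(lin$adjusted_r2, 0.99)
  expect_lt(lin$p_value, 1e-10)
  null <- verify_jsn_vs_degeneration(jsn_null, deg)
  expect_lt(abs(null$adjusted_r2), 0.05)
  expect_error(verify_jsn_vs_degeneration(jsn_lin[1:2, ], deg[1:2, ]),
               "at least 3")
  # crosstab diagonal equals n when the compartments always agree
  deg2 <- deg
  deg2$fraction_medial <- 1
  deg2$fraction_lateral <- 0
  jsn2 <- data.frame(id = 1:n, jsn_medial = 10, jsn_lateral = 1)
  agree <- verify_jsn_vs_degeneration(jsn2, deg2)
  expect_equal(sum(diag(agree$crosstab)), n)
})
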