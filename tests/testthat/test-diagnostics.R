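test_that("Clopper-Pearson intervals match the published values", {
  expect_equal(round(clopper_pearson(18, 20), 3), c(lo = 0.683, hi = 0.988))
  expect_equal(round(clopper_pearson(26, 63), 3), c(lo = 0.290, hi = 0.544))
  expect_identical(clopper_pearson(0, 10)[["lo"]], 0)
  expect_identical(clopper_pearson(10, 10)[["hi"]], 1)
  expect_error(clopper_pearson(5, 4), "0 <= k <= n")
  expect_error(clopper_pearson(-1, 4), "0 <= k <= n")
})

test_that("Clopper-Pearson is equivariant under success/failure swap", {
  for (k in c(0, 3, 11, 20)) {
    ci <- clopper_pearson(k, 20)
    sw <- clopper_pearson(20 - k, 20)
    expect_equal(unname(ci), unname(c(1 - sw["hi"], 1 - sw["lo"])))
  }
})

test_that("Clopper-Pearson intervals cover at >= 95% in simulation", {
  set.seed(99)
  k <- rbinom(10000, 20, 0.9)
  covered <- vapply(k, function(ki) {
    ci <- clopper_pearson(ki, 20)
    ci["lo"] <= 0.9 && 0.9 <= ci["hi"]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("diagnostic metrics reproduce the published table", {
  m <- diagnostic_metrics(contingency_counts(26, 2, 37, 18))
  expect_equal(format_percent(m["sensitivity", "estimate"]), "41.3%")
  expect_equal(format_percent(m["specificity", "estimate"]), "90%")
  expect_equal(format_percent(m["ppv", "estimate"]), "92.9%")
  expect_equal(format_percent(m["npv", "estimate"]), "32.7%")
  expect_equal(round(unlist(m["sensitivity", c("lo", "hi")]), 3),
               c(lo = 0.290, hi = 0.544))
  expect_equal(round(unlist(m["specificity", c("lo", "hi")]), 3),
               c(lo = 0.683, hi = 0.988))
  expect_equal(round(unlist(m["ppv", c("lo", "hi")]), 3),
               c(lo = 0.765, hi = 0.991))
  expect_equal(round(unlist(m["npv", c("lo", "hi")]), 3),
               c(lo = 0.207, hi = 0.467))
  expect_output(print(m), "41.3% \\(26/63\\) \\(95% CI: 29% to 54.4%\\)")
})

test_that("degenerate tables yield NA metrics, not errors", {
  perfect <- diagnostic_metrics(contingency_counts(10, 0, 0, 10))
  expect_true(all(perfect$estimate == 1))
  useless <- diagnostic_metrics(contingency_counts(5, 5, 5, 5))
  expect_equal(useless["ppv", "estimate"], 0.5)
  expect_equal(useless["npv", "estimate"], 0.5)
  no_pos <- diagnostic_metrics(contingency_counts(0, 0, 0, 12))
  expect_true(is.na(no_pos["sensitivity", "estimate"]))
  expect_true(is.na(no_pos["ppv", "estimate"]))
  expect_output(print(no_pos), "undefined")
  expect_error(contingency_counts(1, -1, 0, 0), "nonnegative")
  expect_error(contingency_counts(0, 0, 0, 0), "total")
})

test_that("kappa and agreement reproduce the published concordance", {
  tab <- contingency_counts(21, 3, 4, 55)
  expect_equal(round(cohen_kappa(tab), 3), 0.797)
  expect_equal(round(agreement_rate(tab), 3), 0.916)
  expect_equal(agreement_rate(tab), 76 / 83)
  expect_identical(cohen_kappa(contingency_counts(7, 0, 0, 9)), 1)
  expect_equal(cohen_kappa(contingency_counts(25, 25, 25, 25)), 0)
  expect_identical(agreement_rate(contingency_counts(0, 1, 1, 0)), 0)
  # label-swap invariance (swap both rows and columns)
  swapped <- contingency_counts(55, 4, 3, 21)
  expect_equal(cohen_kappa(swapped), cohen_kappa(tab))
  # degenerate margins
  expect_true(is.na(cohen_kappa(contingency_counts(9, 0, 0, 0))))
})

test_that("percent formatting rounds half away from zero to one decimal", {
  expect_identical(format_percent(0.413), "41.3%")
  expect_identical(format_percent(0.9), "90%")
  expect_identical(format_percent(0.33665), "33.7%")
  expect_identical(format_percent(0.10449), "10.4%")
  expect_identical(format_percent(0.125049), "12.5%")
})

test_that("the packaged study tables reproduce every derived count", {
  tabs <- carotid_study_tables()
  grades <- c("absence", "occ_lt50", "occ_50_70", "occ_70_99", "occ_100")
  expect_identical(sum(as.matrix(tabs$stenosis[, grades])), 96L)
  expect_identical(sum(tabs$plaque$absence + tabs$plaque$presence), 96L)
  # HR/RBS/HPF agreement among the 83 HR(+) cases
  expect_identical(as.integer(tabs$rbs_vs_hpf), c(21L, 4L, 3L, 55L))
  expect_equal(round(cohen_kappa(tabs$rbs_vs_hpf), 3), 0.797)
  expect_equal(format_percent(agreement_rate(tabs$rbs_vs_hpf)), "91.6%")
  # bruit detection vs plaque among HR(+) cases
  expect_identical(as.integer(tabs$bruit_vs_plaque), c(26L, 37L, 2L, 18L))
  m <- diagnostic_metrics(tabs$bruit_vs_plaque)
  expect_equal(format_percent(m["sensitivity", "estimate"]), "41.3%")
  # bruit-positive rates among HR(+) cases, overall and by occlusion grade
  sten <- tabs$stenosis[tabs$stenosis$hr == "+", ]
  bruit <- sten$rbs == "+" | sten$hpf == "+"
  rate <- function(cols) {
    part <- as.matrix(sten[, cols, drop = FALSE])
    sum(part[bruit, ]) / sum(part)
  }
  expect_identical(sum(as.matrix(sten[, grades])), 83L)
  expect_equal(format_percent(rate(grades)), "33.7%")         # 28/83
  expect_equal(format_percent(rate("absence")), "10%")        # 2/20
  expect_equal(format_percent(rate(c("occ_lt50", "occ_50_70"))),
               "34.4%")                                       # 11/32
  expect_equal(format_percent(rate("occ_70_99")), "46.7%")    # 14/30
})
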