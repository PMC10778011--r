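# Reconstructed ultrasound staging matrix (diagonal and marginals pinned by
# the published per-class rows; off-diagonals completed consistently).
hfus_completed <- matrix(
  c(
    55, 1, 0,
    2, 12, 1,
    0, 4, 23
  ),
  3, 3,
  byrow = TRUE,
  dimnames = list(breslow_levels(), breslow_levels())
)

test_that("confusion matrices count true/predicted pairs", {
  perfect <- build_confusion(
    rep(breslow_levels(), c(4, 3, 2)),
    rep(breslow_levels(), c(4, 3, 2))
  )
  expect_equal(unclass(perfect), diag(c(4, 3, 2)), ignore_attr = TRUE)

  single <- build_confusion("<1mm", ">2mm")
  expect_equal(single[1, 3], 1L)
  expect_equal(sum(single), 1L)

  set.seed(500)
  tr <- sample(breslow_levels(), 500, replace = TRUE)
  pr <- sample(breslow_levels(), 500, replace = TRUE)
  expect_equal(sum(build_confusion(tr, pr)), 500L)
  expect_error(build_confusion(tr, pr[-1]), class = "breslowmsi_input_error")
})

test_that("one-vs-rest collapse conserves counts and matches enumeration", {
  for (k in 1:3) {
    counts <- one_vs_rest(diag(c(5, 6, 7)), k)
    expect_equal(unname(counts["fp"]), 0)
    expect_equal(unname(counts["fn"]), 0)
  }
  # reconstructed ultrasound matrix, thin-melanoma class
  expect_equal(
    unname(one_vs_rest(hfus_completed, 1)),
    c(55, 1, 2, 40)
  )
  # brute-force recount over raw label pairs on random matrices
  set.seed(77)
  for (i in 1:50) {
    cm <- matrix(rpois(9, 6), 3, 3)
    if (sum(cm) == 0) cm[1, 1] <- 1
    lab <- labels_from_matrix(cm)
    for (k in 1:3) {
      pos <- breslow_levels()[k]
      oracle <- c(
        tp = sum(lab$truth == pos & lab$pred == pos),
        fn = sum(lab$truth == pos & lab$pred != pos),
        fp = sum(lab$truth != pos & lab$pred == pos),
        tn = sum(lab$truth != pos & lab$pred != pos)
      )
      expect_equal(one_vs_rest(cm, k), oracle)
    }
  }
})

test_that("binary class metrics reproduce the published per-class rows", {
  # ultrasound <1mm row
  m <- class_metrics(55, 1, 2, 40)
  expect_equal(m$sensitivity, 0.982, tolerance = 0.001)
  expect_equal(m$specificity, 0.952, tolerance = 0.001)
  expect_equal(m$kappa, 0.937, tolerance = 0.001)
  # multispectral 1-2mm row
  expect_equal(class_metrics(9, 6, 27, 57)$kappa, 0.177, tolerance = 0.001)
  # perfect test
  p <- class_metrics(10, 0, 0, 20)
  expect_equal(
    unlist(p[c("sensitivity", "specificity", "ppv", "npv", "kappa")]),
    c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, kappa = 1)
  )
  expect_error(class_metrics(0, 0, 1, 5), class = "breslowmsi_domain_error")
})

test_that("micro-averaging pools one-vs-rest counts", {
  d <- micro_average(diag(c(3, 3, 3)))
  expect_equal(unlist(d), c(
    sensitivity = 1, specificity = 1, ppv = 1, npv = 1
  ), ignore_attr = TRUE)

  m <- micro_average(hfus_completed)
  expect_equal(m$sensitivity, 90 / 98, tolerance = 1e-12)
  expect_equal(m$specificity, 0.960, tolerance = 0.001)

  # micro sensitivity = micro PPV = accuracy on any single-label matrix
  set.seed(88)
  for (i in 1:25) {
    cm <- matrix(rpois(9, 8), 3, 3)
    if (sum(cm) == 0) cm[2, 2] <- 3
    mm <- micro_average(cm)
    expect_equal(mm$sensitivity, mm$ppv, tolerance = 1e-12)
    expect_equal(mm$specificity, mm$npv, tolerance = 1e-12)
    expect_equal(mm$sensitivity, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("kappa matches its closed-form cases and the marginals identity", {
  expect_equal(cohen_kappa(diag(c(10, 10, 10))), 1)
  expect_equal(cohen_kappa(matrix(4, 3, 3)), 0)
  expect_equal(
    kappa_from_marginals(c(55, 12, 23), c(56, 15, 27), c(57, 17, 24)),
    0.858,
    tolerance = 0.001
  )
  # kappa from (diagonal, marginals) equals kappa from the full matrix
  set.seed(99)
  for (i in 1:200) {
    cm <- matrix(rpois(9, 5), 3, 3)
    diag(cm) <- diag(cm) + 1 # avoid degenerate all-zero marginals
    expect_equal(
      cohen_kappa(cm),
      kappa_from_marginals(diag(cm), rowSums(cm), colSums(cm)),
      tolerance = 1e-12
    )
    # invariant under uniform scaling of all cells
    expect_equal(cohen_kappa(cm), cohen_kappa(cm * 7), tolerance = 1e-12)
  }
  expect_error(
    cohen_kappa(matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
    class = "breslowmsi_domain_error"
  )
})

test_that("kappa agrees with a from-scratch oracle on label pairs", {
  set.seed(101)
  for (i in 1:20) {
    tr <- sample(breslow_levels(), 200, replace = TRUE)
    pr <- ifelse(runif(200) < 0.6, tr, sample(breslow_levels(), 200, replace = TRUE))
    expect_equal(
      cohen_kappa(build_confusion(tr, pr)),
      kappa_oracle(tr, pr),
      tolerance = 1e-12
    )
  }
})

test_that("the asymptotic kappa interval behaves and matches a bootstrap", {
  # zero-variance limit: perfect agreement pins the interval at (1, 1)
  ci_perfect <- kappa_ci(diag(c(10, 15, 20)))
  expect_equal(ci_perfect$low, 1)
  expect_equal(ci_perfect$high, 1)

  ci <- kappa_ci(hfus_completed)
  # half-width close to the published 0.763-0.952 interval
  printed_half <- (0.952 - 0.763) / 2
  expect_lt(abs((ci$high - ci$low) / 2 - printed_half) / printed_half, 0.25)

  # bootstrap oracle for the same SE
  lab <- labels_from_matrix(hfus_completed)
  set.seed(202)
  boot <- replicate(10000, {
    idx <- sample(length(lab$truth), replace = TRUE)
    kappa_oracle(lab$truth[idx], lab$pred[idx])
  })
  expect_lt(abs(sd(boot) - ci$se) / ci$se, 0.25)

  # SE scales as 1/sqrt(n): doubling all cells shrinks the width by sqrt(2)
  ci2 <- kappa_ci(2 * hfus_completed)
  expect_equal(
    (ci2$high - ci2$low) / (ci$high - ci$low),
    1 / sqrt(2),
    tolerance = 0.03
  )
  expect_error(kappa_ci(diag(c(2, 1, 1))), class = "breslowmsi_input_error")
})

test_that("per-category MSE averages squared errors within each stratum", {
  t6 <- c(0.4, 0.8, 1.5, 1.9, 3.0, 5.0)
  e6 <- c(0.5, 0.6, 1.2, 2.1, 2.5, 6.0)
  cats <- categorize_thickness(t6)
  out <- mse_by_category(t6, e6, cats)
  # direct-sum oracle per stratum
  for (lv in breslow_levels()) {
    idx <- which(as.character(cats) == lv)
    expect_equal(
      out$mse[out$category == lv],
      sum((e6[idx] - t6[idx])^2) / length(idx)
    )
  }
  expect_equal(out$mse[out$category == "overall"], mean((e6 - t6)^2))

  # exact estimates give zero everywhere; a constant offset gives d^2
  zero <- mse_by_category(t6, t6, cats)
  expect_true(all(zero$mse == 0))
  off <- mse_by_category(t6, t6 + 0.3, cats)
  expect_true(all(abs(off$mse - 0.09) < 1e-12))

  # an empty category is absent, not zero
  thin <- mse_by_category(c(0.4, 0.6), c(0.5, 0.5), c("<1mm", "<1mm"))
  expect_false("1-2mm" %in% thin$category)
})

test_that("evaluate_classification assembles a coherent report", {
  set.seed(303)
  n <- 300
  truth_mm <- pmin(pmax(rlnorm(n, 0.1, 0.86), 0.14), 8)
  est_mm <- pmax(truth_mm + rnorm(n, 0, 0.35), 0.01)
  df <- tibble::tibble(
    truth_mm = truth_mm,
    est_mm = est_mm,
    truth = categorize_thickness(truth_mm),
    pred = categorize_thickness(est_mm)
  )
  ev <- evaluate_classification(df, truth, pred,
    true_mm = truth_mm, est_mm = est_mm
  )
  expect_s3_class(ev, "breslow_eval")
  expect_equal(sum(ev$confusion), n)
  expect_equal(nrow(tidy(ev)), 3)
  gl <- glance(ev)
  # micro identities visible in the totals row
  expect_equal(gl$sensitivity, gl$ppv, tolerance = 1e-12)
  expect_equal(gl$specificity, gl$npv, tolerance = 1e-12)
  expect_equal(gl$kappa, cohen_kappa(ev$confusion))
  expect_true(ev$kappa_low <= ev$kappa && ev$kappa <= ev$kappa_high)
  # MSE column flows from mse_by_category
  expect_equal(gl$mse, mean((est_mm - truth_mm)^2))
  # per-class kappas match the one-vs-rest collapse
  for (k in 1:3) {
    counts <- one_vs_rest(ev$confusion, k)
    expect_equal(
      tidy(ev)$kappa[k],
      class_metrics(counts["tp"], counts["fn"], counts["fp"], counts["tn"])$kappa
    )
  }
})
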