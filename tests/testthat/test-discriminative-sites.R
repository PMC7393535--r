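test_that("rank AUC matches hand-enumerated pair probabilities", {
  expect_equal(site_auc(c(0.3, 0.4), c(0.1, 0.2)), 1.0)
  expect_equal(site_auc(0.1, 0.1), 0.5)
  expect_equal(site_auc(c(0.3, 0.1), c(0.2, 0.1)), 0.625)  # (2 + 0.5) / 4
  expect_error(site_auc(numeric(0), 0.1), "empty")
})

test_that("rank AUC equals pair enumeration on exhaustive random inputs", {
  set.seed(77)
  for (i in 1:1000) {
    a <- sample(seq(0, 0.1, by = 0.02), sample(1:6, 1), replace = TRUE)
    b <- sample(seq(0, 0.1, by = 0.02), sample(1:6, 1), replace = TRUE)
    expect_equal(rank_auc(a, b), auc_by_enumeration(a, b))
  }
})

test_that("AUC symmetry and monotone-transform invariance hold", {
  set.seed(12)
  for (i in 1:20) {
    a <- runif(5); b <- runif(4)
    expect_equal(rank_auc(a, b) + rank_auc(b, a), 1)
    expect_equal(rank_auc(exp(3 * a), exp(3 * b)), rank_auc(a, b))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(30)
  a <- runif(12, 0.3, 1); b <- runif(15, 0, 0.7)
  ref <- suppressMessages(pROC::auc(
    pROC::roc(c(rep(1, 12), rep(0, 15)), c(a, b), direction = "<")))
  expect_equal(rank_auc(a, b), as.numeric(ref))
})

test_that("DMS selection applies a strict threshold in descending order", {
  aucs <- data.frame(site_id = c("s1", "s2", "s3"),
                     auc = c(0.9, 0.65, 0.3), n_msi = 5L, n_mss = 5L)
  sel <- select_dms(aucs, 0.65)
  expect_equal(sel$site_id, "s1")
  all_sel <- select_dms(aucs, 0)
  expect_equal(all_sel$auc, c(0.9, 0.65, 0.3))
  expect_equal(select_dms(aucs, 0, top_k = 2)$site_id, c("s1", "s2"))
})

test_that("per-site AUC table skips uncovered classes and flags true targets", {
  spec <- cohort_spec(n_sites = 200L, n_normals = 2L, n_msi = 16L,
                      n_mss = 16L, coverage = 60, msi_fraction = 0.2)
  co <- generate_cohort(spec, seed = 41)
  tab <- site_auc_table(co$estimates, co$labels)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$n_msi >= 1 & tab$n_mss >= 1))
  # truly elevated sites should dominate a high-threshold panel
  sel <- select_dms(tab, 0.75)
  truth <- co$truth$msi_target[match(sel$site_id, co$truth$site_id)]
  expect_gte(mean(truth), 0.9)
  # held-out samples must not enter selection
  lab2 <- co$labels
  lab2$split[lab2$label %in% c("MSI", "MSS")][1:4] <- "test"
  tab2 <- site_auc_table(co$estimates, lab2)
  expect_true(all(tab2$n_msi + tab2$n_mss <= 28))
})

test_that("cohort evaluation ranks samples by score with tie handling", {
  calls <- data.frame(sample_id = c("a", "b", "c", "d"),
                      msi_score = c(30, 25, 2, 1))
  labels <- data.frame(sample_id = c("a", "b", "c", "d"),
                       label = c("MSI", "MSI", "MSS", "MSS"))
  ev <- evaluate_cohort(calls, labels)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  calls$msi_score <- rep(7, 4)
  expect_equal(evaluate_cohort(calls, labels)$auc, 0.5)
})

test_that("cohort AUC equals pair enumeration for small cohorts", {
  set.seed(55)
  for (i in 1:200) {
    n1 <- sample(1:4, 1); n0 <- sample(1:4, 1)
    sc <- round(runif(n1 + n0, 0, 40), 1)
    calls <- data.frame(sample_id = paste0("s", seq_len(n1 + n0)),
                        msi_score = sc)
    labels <- data.frame(sample_id = calls$sample_id,
                         label = c(rep("MSI", n1), rep("MSS", n0)))
    expect_equal(evaluate_cohort(calls, labels)$auc,
                 auc_by_enumeration(sc[seq_len(n1)], sc[n1 + seq_len(n0)]))
  }
})

test_that("undefined scores are excluded with a warning; empty classes error", {
  calls <- data.frame(sample_id = c("a", "b", "c"),
                      msi_score = c(20, NA, 1))
  labels <- data.frame(sample_id = c("a", "b", "c"),
                       label = c("MSI", "MSI", "MSS"))
  expect_warning(ev <- evaluate_cohort(calls, labels), "undefined")
  expect_equal(ev$n_msi, 1L)
  labels$label <- "MSI"
  expect_error(suppressWarnings(evaluate_cohort(calls, labels)), "both classes")
})
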