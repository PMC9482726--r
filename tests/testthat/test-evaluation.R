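test_that("confusion metrics handle perfect, degenerate and invalid inputs", {
  perfect <- confusion_metrics(5, 0, 0, 5)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, mcc = 1))
  one_class <- confusion_metrics(0, 0, 4, 6)  # everything called mild
  expect_equal(one_class$mcc, 0)
  expect_equal(one_class$sensitivity, 0)
  no_pos <- confusion_metrics(0, 2, 0, 8)  # no severe samples at all
  expect_true(is.na(no_pos$sensitivity))
  expect_error(confusion_metrics(-1, 0, 0, 1), class = "rg_validation_error")
})

test_that("AUC equals the exhaustive pair average and survives monotone maps", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("severe", "severe", "mild", "mild")), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("severe", "mild"), 3)), 0.5)
  set.seed(31)
  for (rep in 1:20) {
    risks <- round(runif(12), 2)  # rounding provokes ties
    truths <- sample(rep(c("severe", "mild"), 6))
    expect_equal(roc_auc(risks, truths), brute_auc(risks, truths))
    expect_equal(roc_auc(qlogis(pmin(pmax(risks, 0.01), 0.99)), truths),
                 roc_auc(risks, truths))
  }
  expect_error(roc_auc(c(0.1, 0.2), c("severe", "severe")),
               class = "rg_validation_error")
})

test_that("NRI/IDI match a direct-count oracle and are antisymmetric", {
  ident <- reclassification(c(0.2, 0.7), c(0.2, 0.7), c("mild", "severe"))
  expect_equal(ident$nri, 0)
  expect_equal(ident$idi, 0)

  # one severe sample crosses the 0.5 cutpoint upward; everyone else fixed
  old <- c(0.4, 0.3, 0.8, 0.6, 0.2)
  new <- c(0.6, 0.3, 0.8, 0.6, 0.2)
  truths <- c("severe", "severe", "severe", "mild", "mild")
  r <- reclassification(old, new, truths)
  expect_equal(r$nri, 1 / 3)

  set.seed(77)
  for (rep in 1:30) {
    o <- runif(30); n <- runif(30)
    tr <- sample(rep(c("severe", "mild"), 15))
    got <- reclassification(o, n, tr)
    want <- brute_nri_idi(o, n, tr)
    expect_equal(got$nri, want$nri)
    expect_equal(got$idi, want$idi)
    rev <- reclassification(n, o, tr)
    expect_equal(rev$nri, -got$nri)
    expect_equal(rev$idi, -got$idi)
  }
  expect_error(reclassification(0.1, 0.2, "severe", cutpoints = c(0.2, 0.5, 1)),
               class = "rg_validation_error")
  # row/column sums conserve the per-class sample counts
  o <- runif(20); n <- runif(20)
  tr <- sample(rep(c("severe", "mild"), 10))
  r <- reclassification(o, n, tr)
  expect_equal(sum(r$table_events), 10)
  expect_equal(sum(r$table_nonevents), 10)
})

test_that("saturation stopping rule matches the worked walkthrough", {
  acc <- c(`6` = 0.7, `8` = 0.8, `10` = 0.8, `12` = 0.75, `14` = 0.75,
           `16` = 0.75, `18` = 0.9)
  seen <- integer(0)
  scan <- saturation_scan(k_start = 6, k_step = 2, patience = 3, k_max = 40,
                          evaluator = function(k) {
                            seen <<- c(seen, k)
                            acc[[as.character(k)]]
                          })
  expect_equal(seen, seq(6, 16, by = 2))  # stops after k = 16
  expect_equal(scan$chosen_k, 8)

  dec <- saturation_scan(k_start = 6, k_step = 2, patience = 3, k_max = 40,
                         evaluator = function(k) 1 / k)
  expect_equal(dec$chosen_k, 6)
  expect_error(saturation_scan(k_start = 10, k_max = 8, evaluator = identity),
               class = "rg_validation_error")
})

test_that("LOOCV runs one fold per sample with no leakage from the held-out sample", {
  co <- small_cohort(seed = 6)
  res <- run_loocv(co$genotypes, co$annotations, co$phenotypes, k = 8)
  expect_equal(nrow(res$per_sample), 33L)
  expect_equal(length(res$fold_variants), 33L)
  expect_true(all(vapply(res$fold_variants, length, integer(1)) == 8L))
  expect_equal(sum(res$confusion), 33)
  expect_equal(res$confusion[["tp"]] + res$confusion[["fn"]], 15)
  expect_equal(res$confusion[["tn"]] + res$confusion[["fp"]], 18)

  # perturbing the held-out sample's dosages leaves its fold's selection alone
  i <- 5L
  geno2 <- co$genotypes
  geno2[i, ] <- sample(c(0L, 1L, 2L), ncol(geno2), replace = TRUE)
  sel2 <- {
    tr <- setdiff(seq_len(nrow(geno2)), i)
    scan <- assoc_scan(geno2[tr, ], co$annotations, co$phenotypes$severity[tr])
    select_top_k(rank_variants(scan), 8)
  }
  expect_identical(res$fold_variants[[i]], sel2)
})

test_that("a separable cohort is classified almost perfectly out-of-fold", {
  co <- small_cohort(seed = 8)  # includes a planted hom-alt severity marker
  res <- run_loocv(co$genotypes, co$annotations, co$phenotypes, k = 6)
  expect_gte(res$metrics$accuracy, 0.9)
  expect_gte(res$metrics$auc, 0.95)
  expect_true(all(res$per_sample$risk > 0 & res$per_sample$risk < 1))
})

test_that("label-permuted LOOCV accuracy collapses to the majority-class rate", {
  co <- simulate_cohort(cohort_spec(n_severe = 9, n_mild = 11,
                                    n_variants = 200, n_genes = 40,
                                    planted_risk_variants = 5,
                                    planted_ig_genes = NULL,
                                    subphenotype_severe_counts =
                                      c(iq = 9L, verbal = 8L,
                                        attention = 14L, memory = 9L),
                                    seed = 13))
  majority <- 11 / 20
  set.seed(99)
  accs <- replicate(100, {
    phen <- co$phenotypes
    phen$severity <- sample(phen$severity)
    run_loocv(co$genotypes, co$annotations, phen, k = 4)$metrics$accuracy
  })
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - majority), max(3 * se, 0.08))
  expect_lt(mean(accs), majority + 0.1)
})

test_that("risk-score clustering labels, flags discordance and matches UPGMA", {
  preds <- data.frame(sample_id = c("a", "b", "c", "d"),
                      risk = c(0.9, 0.85, 0.1, 0.12),
                      true = c("severe", "severe", "mild", "mild"))
  cl <- cluster_risk_scores(preds)
  expect_equal(length(cl$discordant), 0L)
  expect_equal(cl$assignments$cluster, c("high-risk", "high-risk",
                                         "low-risk", "low-risk"))
  expect_equal(cl$assignments$sample_id, c("a", "b", "d", "c"))  # by risk desc

  swapped <- data.frame(sample_id = c("x", "y"), risk = c(0.9, 0.2),
                        true = c("mild", "severe"))
  cl2 <- cluster_risk_scores(swapped)
  expect_setequal(cl2$discordant, c("x", "y"))

  set.seed(14)
  risks <- runif(20)
  preds3 <- data.frame(sample_id = sprintf("s%02d", 1:20), risk = risks,
                       true = sample(rep(c("severe", "mild"), 10)))
  cl3 <- cluster_risk_scores(preds3)
  expect_equal(sort(cl3$hclust$height), brute_upgma_heights(risks))
  expect_error(cluster_risk_scores(preds3[1, , drop = FALSE], n_clusters = 2),
               class = "rg_validation_error")
})
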