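test_that("single-variant predictions route to the documented leaves", {
  # destabilized past the root threshold -> non-responsive
  p <- predictTree(list(ddg = 1.96, binds_ligand = FALSE, n_contacts = 2,
                        p_inv = 43))
  expect_false(p$label)
  expect_equal(p$p1, 0.28)
  expect_equal(p$leaf, "root_destab")
  # few contacts -> responsive
  p <- predictTree(list(ddg = 0.28, binds_ligand = FALSE, n_contacts = 3,
                        p_inv = 183))
  expect_true(p$label)
  expect_equal(p$p1, 0.60)
  expect_equal(p$leaf, "small_contacts")
  # intermediate ddg with many inverse-parallel relations -> non-responsive
  p <- predictTree(list(ddg = 1.05, binds_ligand = FALSE, n_contacts = 5,
                        p_inv = 219))
  expect_false(p$label)
  expect_equal(p$p1, 0.34)
  expect_equal(p$leaf, "pinv_high")
  # remaining leaves
  expect_equal(predictTree(list(ddg = 1.0, binds_ligand = TRUE,
                                n_contacts = 9, p_inv = 0))$leaf, "ligand")
  expect_equal(predictTree(list(ddg = -2.0, binds_ligand = FALSE,
                                n_contacts = 9, p_inv = 0))$leaf,
               "over_stabilized")
  expect_equal(predictTree(list(ddg = 0.5, binds_ligand = FALSE,
                                n_contacts = 9, p_inv = 0))$leaf, "mid_ddg")
  expect_equal(predictTree(list(ddg = 1.0, binds_ligand = FALSE,
                                n_contacts = 9, p_inv = 10))$leaf,
               "pinv_low")
})

test_that("missing features are reported by name", {
  expect_error(predictTree(list(ddg = 1, binds_ligand = FALSE,
                                n_contacts = 2)), "p_inv")
  expect_error(predictTree(list(binds_ligand = FALSE, n_contacts = 2,
                                p_inv = 1)), "ddg")
})

test_that("prediction is deterministic including the trace", {
  f <- list(ddg = 1.05, binds_ligand = FALSE, n_contacts = 5, p_inv = 219)
  expect_identical(predictTree(f), predictTree(f))
  expect_match(paste(predictTree(f)$trace, collapse = " | "), "p_inv 219")
})

test_that("label flips monotonically at the destabilization root", {
  base <- list(binds_ligand = FALSE, n_contacts = 2, p_inv = 10)
  ddgs <- seq(-3, 5, by = 0.1)
  labels <- vapply(ddgs, function(d)
    predictTree(c(base, ddg = d))$label, logical(1))
  past_root <- ddgs >= 1.7
  expect_true(all(!labels[past_root]))  # never flips back to responsive
})

test_that("batch prediction equals row-wise prediction under shuffling", {
  g <- gaucherVariants()
  shuf <- g[sample(nrow(g)), ]
  batch <- predictTreeBatch(shuf)
  for (k in seq_len(nrow(shuf))) {
    single <- predictTree(shuf[k, ])
    expect_equal(batch$responsive[k], single$label)
    expect_equal(batch$p1[k], single$p1)
    expect_equal(batch$leaf[k], single$leaf)
  }
  expect_equal(nrow(predictTreeBatch(g[0, ])), 0)
})

test_that("worked-example routing is robust across admissible thresholds", {
  g <- gaucherVariants()
  expected_leaf <- c("small_contacts", "root_destab", "small_contacts",
                     "pinv_high", "root_destab", "small_contacts",
                     "small_contacts")
  for (pinv_high in c(1L, 50L, 100L, 219L)) {
    for (contacts_small in c(4L, 5L)) {
      th <- treeThresholds(contacts_small = contacts_small,
                           pinv_high = pinv_high)
      out <- predictTreeBatch(g, thresholds = th)
      expect_equal(out$leaf, expected_leaf,
                   info = sprintf("pinv_high=%d contacts_small=%d",
                                  pinv_high, contacts_small))
    }
  }
})

test_that("leaf probability overrides are validated", {
  lp <- defaultLeafProbs(mid_ddg = 0.7)
  expect_equal(unname(lp["mid_ddg"]), 0.7)
  expect_error(defaultLeafProbs(nonsense = 0.5), "unknown leaf")
  expect_error(defaultLeafProbs(mid_ddg = 1.5), "\\[0, 1\\]")
  expect_error(treeThresholds(ddg_low = 2), "ddg_low < ddg_mid")
})

test_that("evaluatePredictions summarizes agreement with assays", {
  g <- gaucherVariants()
  pred <- predictTreeBatch(g)
  first3 <- evaluatePredictions(pred$responsive[1:3], g$responsive[1:3])
  expect_equal(first3$n_correct, 3)
  last4 <- evaluatePredictions(pred$responsive[4:7], g$responsive[4:7])
  expect_equal(last4$n_correct, 1)  # only N188S
  perfect <- evaluatePredictions(c(TRUE, TRUE, FALSE, FALSE),
                                 c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$mcc, 1.0)
  expect_error(evaluatePredictions(TRUE, c(TRUE, FALSE)), "length")
})
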