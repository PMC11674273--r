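test_that("delta Cq and fold change follow the comparative Cq method", {
  expect_equal(delta_cq(25, 20), 5)
  expect_equal(delta_cq(20, 20), 0)
  expect_equal(delta_cq(18.3, 20.1), -1.8)
  expect_error(delta_cq(Inf, 20), "finite")

  expect_equal(fold_change(5, 5), 1)       # equal dCq: no change
  expect_equal(fold_change(4, 5), 2)       # one cycle earlier = doubling
  expect_equal(fold_change(8, 5), 0.125)   # ddCq = 3 -> 2^-3
  expect_error(fold_change(NA, 1), "finite")
})

test_that("Cq tables convert to fold-change triplicates block-wise", {
  # noiseless table with true FC 4: built by hand, must invert exactly
  cq <- rbind(
    data.frame(chemical = "A", gene = "HMOX1", condition = "treated",
               replicate = 1:3, cq = 25 - 2),
    data.frame(chemical = "A", gene = "HMOX1", condition = "solvent_control",
               replicate = 1:3, cq = 25),
    data.frame(chemical = "A", gene = "GAPDH", condition = "treated",
               replicate = 1:3, cq = 20),
    data.frame(chemical = "A", gene = "GAPDH", condition = "solvent_control",
               replicate = 1:3, cq = 20)
  )
  fc <- foldchange_from_cq(cq)
  expect_equal(fc$fc, rep(4, 3))
  # mean-control pairing agrees when controls are constant
  expect_equal(foldchange_from_cq(cq, control = "mean")$fc, rep(4, 3))

  # treated identical to control: all ratios 1
  cq1 <- cq
  cq1$cq[cq1$gene == "HMOX1"] <- 25
  expect_equal(foldchange_from_cq(cq1)$fc, rep(1, 3))

  # missing reference block is a named error
  expect_error(foldchange_from_cq(cq[cq$gene != "GAPDH", ]), "reference")
  # missing control rows for the target
  expect_error(
    foldchange_from_cq(cq[!(cq$gene == "HMOX1" &
                              cq$condition == "solvent_control"), ]),
    "HMOX1"
  )
})

test_that("replicate noise propagates as log2-normal fold-change error", {
  tf <- matrix(2.5, 50, 1, dimnames = list(sprintf("c%02d", 1:50), "HMOX1"))
  sc <- qpcr_scenario(tf, replicate_noise_sd = 0.1, seed = 202)
  fc <- foldchange_from_cq(generate_cq(sc))
  # paired ddCq combines four N(0, 0.1) draws: sd 0.2 on the log2 scale
  err <- abs(log2(fc$fc / 2.5))
  expect_gte(mean(err <= 3 * 0.2), 0.95)
  expect_lt(max(err), 5 * 0.2)
})

test_that("gene positivity implements the replicate-majority rule", {
  rule <- decision_rule()
  # saccharin HMOX1: one replicate exactly at threshold must count
  expect_true(gene_positive(c(2.0, 1.1, 2.2), rule))
  # potassium dichromate JUN: no replicate reaches 2-fold
  expect_false(gene_positive(c(1.3, 1.0, 1.0), rule))
  # strict comparison drops exact-threshold replicates
  strict <- decision_rule(inclusive = FALSE)
  expect_false(gene_positive(c(2.0, 2.0, 0.1), strict))
  expect_true(gene_positive(c(2.0, 2.0, 0.1), rule))
  # down-regulation never counts toward positivity
  expect_false(gene_positive(c(0.1, 0.2, 0.1), rule))

  expect_error(gene_positive(c(2, 2), rule), "3 replicates")
  expect_error(gene_positive(c(2, -1, 2), rule), "positive")
  expect_error(decision_rule(threshold = 1), "> 1")
  expect_error(decision_rule(quorum = 4), "quorum")
})

test_that("positivity equals a brute-force oracle over a value grid", {
  vals <- c(0.5, 1.0, 1.99, 2.0, 2.01, 4.0)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  for (quorum in 1:3) {
    for (inclusive in c(TRUE, FALSE)) {
      rule <- decision_rule(quorum = quorum, inclusive = inclusive)
      got <- apply(grid, 1, function(v) gene_positive(v, rule))
      # independent brute-force count-and-compare
      want <- apply(grid, 1, function(v) {
        hits <- 0
        for (x in v) {
          if ((inclusive && x >= 2) || (!inclusive && x > 2)) hits <- hits + 1
        }
        hits >= quorum
      })
      expect_equal(got, want)
    }
  }
})

test_that("panel classification is an OR over genes and reproduces the reported calls", {
  # benzoyl peroxide: sensitizer via JUN alone
  fit <- rt_hclat(make_fc(bp = list(HMOX1 = c(1.9, 1.4, 1.5),
                                    JUN = c(3.0, 2.2, 2.0))))
  expect_equal(fit$judgments$call, "sensitizer")
  expect_false(fit$judgments$HMOX1_positive)
  expect_true(fit$judgments$JUN_positive)
  # cobalt chloride: sensitizer via HMOX1 alone
  fit <- rt_hclat(make_fc(co = list(HMOX1 = c(11.4, 18.0, 18.8),
                                    JUN = c(1.4, 1.4, 1.2))))
  expect_equal(fit$judgments$call, "sensitizer")
  # 1,2-propanediol: negative on both genes
  fit <- rt_hclat(make_fc(pd = list(HMOX1 = c(0.4, 0.4, 0.7),
                                    JUN = c(0.6, 0.6, 0.7))))
  expect_equal(fit$judgments$call, "non_sensitizer")
  # a panel gene missing from the data is a named error
  expect_error(rt_hclat(make_fc(x = list(HMOX1 = c(1, 1, 1)))), "JUN")
})

test_that("judgments are invariant to replicate and panel order, monotone in fc", {
  set.seed(91)
  for (i in 1:25) {
    h <- runif(3, 0.2, 4)
    j <- runif(3, 0.2, 4)
    fc <- make_fc(x = list(HMOX1 = h, JUN = j))
    base <- rt_hclat(fc)$judgments$call
    # replicate permutation
    fc2 <- make_fc(x = list(HMOX1 = sample(h), JUN = sample(j)))
    expect_equal(rt_hclat(fc2)$judgments$call, base)
    # panel permutation
    rev_rule <- decision_rule(panel = c("JUN", "HMOX1"))
    expect_equal(rt_hclat(fc, rule = rev_rule)$judgments$call, base)
    # raising any replicate never flips sensitizer -> non_sensitizer
    if (base == "sensitizer") {
      k <- sample(3, 1)
      h2 <- h; h2[k] <- h2[k] * 2
      up <- make_fc(x = list(HMOX1 = h2, JUN = j))
      expect_equal(rt_hclat(up)$judgments$call, "sensitizer")
    }
  }
})

test_that("the bundled 28-chemical panel reproduces every reported judgment", {
  fit <- rt_hclat(hmox1_jun_panel(), chemicals = study_chemicals())
  reported <- hmox1_jun_reported_judgments()
  got <- fit$judgments$call[match(reported$chemical, fit$judgments$chemical)]
  expect_equal(got, gsub("-", "_", reported$printed_call))
  expect_equal(sum(got == "sensitizer"), 22)
  expect_equal(sum(got == "non_sensitizer"), 6)
})
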