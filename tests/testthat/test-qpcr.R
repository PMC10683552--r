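make_records <- function(...) {
  data.frame(...)
}

test_that("delta_ct averages technical replicates then subtracts reference", {
  recs <- rbind(
    data.frame(sample_id = "s1", group = "dominant", gene = "actb2",
               replicate = 1:2, Ct = c(20, 20)),
    data.frame(sample_id = "s1", group = "dominant", gene = "drd1b",
               replicate = 1:2, Ct = c(24.0, 24.2))
  )
  d <- delta_ct(recs)
  expect_equal(d$delta_ct[d$gene == "drd1b"], 4.1)   # mean(24, 24.2) - 20
  expect_equal(d$delta_ct[d$gene == "actb2"], 0)     # reference vs itself

  simple <- rbind(
    data.frame(sample_id = "s1", group = "g", gene = "actb2",
               replicate = 1, Ct = 20),
    data.frame(sample_id = "s1", group = "g", gene = "x",
               replicate = 1, Ct = 24))
  expect_equal(delta_ct(simple)$delta_ct[2], 4)

  noref <- simple[simple$gene != "actb2", ]
  expect_error(delta_ct(noref), "actb2")
  tworefs <- rbind(simple, data.frame(sample_id = "s2", group = "g",
                                      gene = "x", replicate = 1, Ct = 25))
  expect_error(delta_ct(tworefs), "s2")
  bad <- simple; bad$Ct[1] <- -1
  expect_error(delta_ct(bad), "Ct")
})

test_that("delta_delta_ct normalizes group means to the control group", {
  recs <- rbind(
    expand.grid(sample_id = paste0("d", 1:2), gene = c("actb2", "x"),
                replicate = 1, stringsAsFactors = FALSE),
    expand.grid(sample_id = paste0("i", 1:2), gene = c("actb2", "x"),
                replicate = 1, stringsAsFactors = FALSE)
  )
  recs$group <- ifelse(grepl("^d", recs$sample_id), "dominant", "isolate")
  recs$Ct <- ifelse(recs$gene == "actb2", 20,
                    ifelse(recs$group == "dominant", 24, 25))
  dd <- delta_delta_ct(delta_ct(recs))
  row <- dd[dd$gene == "x" & dd$group == "dominant", ]
  expect_equal(row$delta_delta_ct, -1)               # 4 - 5
  ctrl <- dd[dd$gene == "x" & dd$group == "isolate", ]
  expect_equal(ctrl$delta_delta_ct, 0)               # control vs itself
  expect_equal(row$n, 2)

  # single-sample groups are handled (mean of one)
  one <- recs[recs$sample_id != "d2", ]
  dd1 <- delta_delta_ct(delta_ct(one))
  expect_equal(dd1$n[dd1$group == "dominant" & dd1$gene == "x"], 1)

  expect_error(delta_delta_ct(delta_ct(recs), control_group = "communal"),
               "control group")
})

test_that("relative expression applies efficiency correction and log2", {
  dd <- data.frame(gene = "x", group = "dominant", delta_delta_ct = -1,
                   d_ct_gene = -1, d_ct_ref = 0)
  eff100 <- data.frame(gene = c("x", "actb2"), efficiency_percent = 100)

  r <- relative_expression(dd, eff100)
  expect_equal(r$fold_change, 2)                     # 2^-(-1)
  expect_equal(r$log2_fold_change, 1)

  dd0 <- dd; dd0$delta_delta_ct <- 0; dd0$d_ct_gene <- 0
  r0 <- relative_expression(dd0, eff100)
  expect_equal(r0$fold_change, 1)
  expect_equal(r0$log2_fold_change, 0)

  # the dat primer (90.9% efficiency, factor 1.909): fold = 1.909 at
  # delta-delta-Ct = -1 with the reference unchanged
  effdat <- data.frame(gene = c("slc6a3", "actb2"),
                       efficiency_percent = c(90.9, 90.9))
  dddat <- data.frame(gene = "slc6a3", group = "dominant",
                      delta_delta_ct = -1, d_ct_gene = -1, d_ct_ref = 0)
  rdat <- relative_expression(dddat, effdat)
  expect_equal(rdat$fold_change, 1.909, tolerance = 1e-12)
  # the simple per-gene power method agrees here
  rdat2 <- relative_expression(dddat, effdat, method = "ddct")
  expect_equal(rdat2$fold_change, 1.909, tolerance = 1e-12)

  # monotone decreasing in delta-delta-Ct; equals 2^-ddct at 100%
  ddct_seq <- seq(-3, 3, by = 0.5)
  dd_many <- data.frame(gene = "x", group = "g", delta_delta_ct = ddct_seq,
                        d_ct_gene = ddct_seq, d_ct_ref = 0)
  r_many <- relative_expression(dd_many, eff100)
  expect_true(all(diff(r_many$fold_change) < 0))
  expect_equal(r_many$fold_change, 2^(-ddct_seq))

  expect_error(relative_expression(dd, data.frame(gene = "actb2",
                                                  efficiency_percent = 100)),
               "missing efficiency")
})

test_that("Table-1 primer efficiencies parse and bound amplification factors", {
  eff <- primer_efficiencies()
  expect_setequal(eff$gene, c("actb2", "th", "ddc", "slc18a2", "slc6a3",
                              "drd1b", "drd2a", "drd2b", "drd3"))
  expect_equal(eff$efficiency_percent[eff$gene == "actb2"], 99.1)
  expect_equal(eff$amplification_factor[eff$gene == "slc6a3"], 1.909)
  expect_equal(eff$amplification_factor[eff$gene == "drd1b"], 2.042)
  expect_true(all(eff$amplification_factor > 1 &
                    eff$amplification_factor <= 2.5))
})

test_that("known fold changes are recovered from synthetic Ct tables", {
  # zero noise, fold 2, 100% efficiency: recovery is exact
  eff100 <- data.frame(gene = c("x", "actb2"), efficiency_percent = 100)
  lf <- data.frame(gene = "x", group = "dominant", log2_fold = 1)
  ct0 <- gen_ct_table(lf, efficiencies = eff100, noise_sd = 0,
                      technical_sd = 0, n_replicates = 3, seed = 1)
  r0 <- analyze_qpcr(ct0, efficiencies = eff100)
  expect_equal(r0$log2_fold_change, 1, tolerance = 1e-12)

  # fold 1 everywhere: all delta-delta-Ct are zero
  lf1 <- data.frame(gene = c("x", "y"), group = "dominant", log2_fold = 0)
  effxy <- data.frame(gene = c("x", "y", "actb2"), efficiency_percent = 100)
  ct1 <- gen_ct_table(lf1, efficiencies = effxy, noise_sd = 0,
                      technical_sd = 0, n_replicates = 3, seed = 1)
  dd1 <- delta_delta_ct(delta_ct(ct1))
  expect_equal(dd1$delta_delta_ct, rep(0, nrow(dd1)), tolerance = 1e-12)

  # realistic noise, real efficiencies: log2 fold within +/- 0.3
  lf2 <- data.frame(gene = c("drd1b", "slc6a3", "ddc"),
                    group = rep(c("dominant", "subordinate"), each = 3),
                    log2_fold = c(0.8, 1.5, 0.6, -1.2, -0.4, 0))
  ct2 <- gen_ct_table(lf2, noise_sd = 0.2, n_replicates = 10, seed = 99)
  r2 <- analyze_qpcr(ct2)
  r2 <- merge(r2, lf2, by = c("gene", "group"))
  expect_true(all(abs(r2$log2_fold_change - r2$log2_fold) < 0.3))
})
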