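test_that("spot filter applies the three removal rules", {
  base <- data.frame(fg_ch1 = 1000, bg_ch1 = 100, bg_sd_ch1 = 10,
                     fg_ch2 = 1000, bg_ch2 = 100, bg_sd_ch2 = 10,
                     qc_flag = FALSE)
  expect_equal(nrow(filter_spots(base)$kept), 1)

  low_sig <- base; low_sig$fg_ch1 <- 199; low_sig$fg_ch2 <- 199
  res <- filter_spots(low_sig)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$log$rule, "low_signal")

  # < 100 in only one channel is not removal
  one_ch <- base; one_ch$fg_ch1 <- 199
  expect_equal(nrow(filter_spots(one_ch)$kept), 1)

  low_snr <- base; low_snr$fg_ch1 <- base$bg_ch1 + 2 * base$bg_sd_ch1
  res2 <- filter_spots(low_snr)
  expect_equal(res2$log$rule, "low_snr")

  flagged <- base; flagged$qc_flag <- TRUE
  expect_equal(filter_spots(flagged)$log$rule, "flagged")
})

test_that("per-gene statistics match the textbook one-sample t test", {
  expect_error(gene_statistics(matrix(1, 3, 1)), "replicates")

  gs <- gene_statistics(matrix(c(1, 1, 1, 1, -2, -1, 1, 2), 2, 4, byrow = TRUE))
  expect_equal(gs$mean_logfc, c(1, 0))
  expect_equal(gs$p_value[1], 0) # zero variance, nonzero mean
  expect_equal(gene_statistics(matrix(0, 1, 4))$p_value, 1)

  withr::with_seed(31, {
    x <- matrix(rnorm(50 * 4, sd = 0.5), 50, 4)
    gs2 <- gene_statistics(x)
    oracle <- apply(x, 1, function(r) t.test(r)$p.value)
    expect_equal(gs2$p_value, oracle)
    expect_equal(gs2$mean_logfc, rowMeans(x))
  })
})

test_that("the significance filter reproduces brute-force BH selection", {
  tab <- data.frame(mean_logfc = rep(1, 10), p_value = rep(1, 10))
  expect_equal(de_filter(tab)$n_total_called, 0)
  expect_error(de_filter(tab, fdr = 1.5), "fdr")

  withr::with_seed(41, {
    for (i in 1:20) {
      p <- round(runif(10), 3)
      lfc <- rnorm(10, sd = 1.5)
      tab <- data.frame(mean_logfc = lfc, p_value = p)
      de <- de_filter(tab, fdr = 0.2, lfc_threshold = 0.585)
      expected <- bh_reject_brute_force(p, 0.2) & abs(lfc) >= 0.585
      expect_identical(de$table$call != "unaffected", expected)
      up_ok <- de$table$call == "up"
      expect_identical(up_ok, expected & lfc >= 0.585)
    }
  })
})

test_that("planted effects are called with the correct direction", {
  p <- tiny_expr_params(sigma = 0.1, effect_range = c(1, 1.4))
  study <- simulate_expression_study(p)
  gs <- gene_statistics(as.matrix(study$genes[paste0("ratio_", 1:4)]))
  tab <- cbind(study$genes, p_value = gs$p_value)
  de <- de_filter(tab)
  expect_identical(de$table$call, de$table$truth)
  expect_equal(de$n_up, 20)
  expect_equal(de$n_down, 30)
})

test_that("calls are monotone in the fdr and lfc thresholds", {
  p <- tiny_expr_params(sigma = 0.3)
  study <- simulate_expression_study(p)
  gs <- gene_statistics(as.matrix(study$genes[paste0("ratio_", 1:4)]))
  tab <- cbind(study$genes, p_value = gs$p_value)
  n_called <- vapply(c(0.01, 0.05, 0.1, 0.25),
                     function(q) de_filter(tab, fdr = q)$n_total_called,
                     numeric(1))
  expect_true(all(diff(n_called) >= 0))
  n_called_lfc <- vapply(c(0.3, 0.585, 0.9, 1.2),
                         function(l) de_filter(tab, lfc_threshold = l)$n_total_called,
                         numeric(1))
  expect_true(all(diff(n_called_lfc) <= 0))
})

test_that("2x2 TAD enrichment equals the exact hypergeometric test", {
  # direct contingency check against the reference implementation
  tab <- matrix(c(1, 11, 9, 3), 2, 2)
  expect_equal(woundquant:::fisher_2x2_exact(tab),
               fisher.test(tab)$p.value)

  # via the gene-table interface
  genes <- data.frame(
    call = rep(c("up", "unaffected"), c(12, 12)),
    tad_id = c(rep("a", 1), rep("b", 11), rep("a", 9), rep("b", 3)))
  res <- tad_enrichment(genes)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value,
               fisher.test(matrix(c(1, 11, 9, 3), 2, 2))$p.value)

  withr::with_seed(55, {
    for (i in 1:25) {
      t2 <- matrix(rpois(4, 8), 2, 2)
      if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
      expect_equal(woundquant:::fisher_2x2_exact(t2), fisher.test(t2)$p.value)
    }
  })
})

test_that("degenerate and malformed contingencies are handled", {
  all_un <- data.frame(call = rep("unaffected", 30),
                       tad_id = rep(c("a", "b", "c"), 10))
  expect_equal(tad_enrichment(all_un)$p_value, 1)
  expect_error(tad_enrichment(data.frame(call = character(), tad_id = character())),
               "empty|must")
  # unmapped genes are excluded and counted
  genes <- data.frame(call = rep(c("up", "unaffected"), c(5, 20)),
                      tad_id = c(rep("a", 5), rep("b", 15), rep(NA, 5)))
  expect_equal(tad_enrichment(genes)$n_unmapped, 5)
})

test_that("Monte-Carlo Rx2 p-values are stable across seeds", {
  genes <- data.frame(
    call = rep(c("up", "unaffected"), c(30, 270)),
    tad_id = paste0("t", c(rep(1:3, 10), (seq_len(270) %% 30) + 1)))
  r1 <- tad_enrichment(genes, seed = 1)
  r2 <- tad_enrichment(genes, seed = 2)
  expect_equal(r1$method, "monte-carlo")
  expect_false(is.na(r1$mc_se))
  expect_lt(abs(r1$p_value - r2$p_value),
            3 * sqrt(r1$mc_se^2 + r2$mc_se^2))
  # determinism for one seed
  expect_identical(r1$p_value, tad_enrichment(genes, seed = 1)$p_value)
})

test_that("TAD clustering of planted genes is detected as enrichment", {
  n_runs <- 100
  hits <- vapply(seq_len(n_runs), function(s) {
    p_on <- tiny_expr_params(tad_clustering = TRUE, sigma = 0.1,
                             effect_range = c(1, 1.4), rng_seed = s)
    p_off <- tiny_expr_params(tad_clustering = FALSE, sigma = 0.1,
                              effect_range = c(1, 1.4), rng_seed = s)
    run <- function(pp) {
      g <- simulate_expression_study(pp)$genes
      gs <- gene_statistics(as.matrix(g[paste0("ratio_", 1:4)]))
      de <- de_filter(cbind(g, p_value = gs$p_value))
      tad_enrichment(de, n_sim = 10000, seed = s)$p_value
    }
    run(p_on) < run(p_off)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("bootstrap median CI is deterministic and degenerate-safe", {
  expect_error(bootstrap_median(numeric(0)), "at least 2")
  b <- bootstrap_median(rep(2.5, 20))
  expect_equal(unlist(b[c("median", "ci_low", "ci_high")]),
               c(median = 2.5, ci_low = 2.5, ci_high = 2.5))

  x <- withr::with_seed(13, rlnorm(200, log(2.5), 0.6))
  b1 <- bootstrap_median(x, seed = 9)
  b2 <- bootstrap_median(x, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$median && b1$median <= b1$ci_high)
})

test_that("delta-delta-Cq efficiency follows the 2^-ddCq law", {
  same <- delta_delta_cq(20, 15, 20, 15)
  expect_equal(same$knockdown_pct, 0)

  one <- delta_delta_cq(21, 15, 20, 15)
  expect_equal(one$delta_delta_cq, 1)
  expect_equal(one$knockdown_pct, 50)

  three <- delta_delta_cq(23, 15, 20, 15)
  expect_equal(three$knockdown_pct, 87.5)

  # technical replicates averaged first
  reps <- delta_delta_cq(c(22.9, 23.1), c(15, 15), c(19.8, 20.2), c(14.9, 15.1))
  expect_equal(reps$knockdown_pct, 87.5)

  # invariance under a constant Cq shift; monotone in ddCq
  shifted <- delta_delta_cq(23 + 5, 15 + 5, 20 + 5, 15 + 5)
  expect_equal(shifted$knockdown_pct, three$knockdown_pct)
  effs <- vapply(seq(0, 4, by = 0.5),
                 function(d) delta_delta_cq(20 + d, 15, 20, 15)$knockdown_pct,
                 numeric(1))
  expect_true(all(diff(effs) > 0))

  expect_error(delta_delta_cq(20, NA, 20, 15), "Cq")
})
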