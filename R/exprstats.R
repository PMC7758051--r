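# Post-wounding expression statistics: spot filtering, per-gene statistics,
# the FDR / fold-change significance filter, TAD enrichment, the gene-size
# bootstrap, and delta-delta-Cq knockdown efficiency.

#' Filter array spots by quality rules
#'
#' Removes a spot if any of three rules fires: (1) the foreground does not
#' exceed the background by more than 3 background standard deviations in a
#' channel; (2) the background-subtracted signal is below 100 in both
#' channels; (3) the spot carries a QC flag. The removal log records which
#' rule fired for every removed spot.
#'
#' @param spots data.frame with columns `fg_ch1`, `bg_ch1`, `bg_sd_ch1`,
#'   `fg_ch2`, `bg_ch2`, `bg_sd_ch2`, `qc_flag` (and any id columns).
#' @param min_signal Background-subtracted signal threshold (default 100).
#' @param sd_mult Background SD multiplier (default 3).
#' @return List with `kept` and `removed` data.frames and a `log` data.frame
#'   (`spot`, `rule`) naming the first rule that fired per removed spot.
#' @export
filter_spots <- function(spots, min_signal = 100, sd_mult = 3) {
  need <- c("fg_ch1", "bg_ch1", "bg_sd_ch1", "fg_ch2", "bg_ch2", "bg_sd_ch2", "qc_flag")
  if (!all(need %in% names(spots))) {
    stop("spots must contain columns: ", paste(need, collapse = ", "))
  }
  low_snr <- (spots$fg_ch1 <= spots$bg_ch1 + sd_mult * spots$bg_sd_ch1) |
             (spots$fg_ch2 <= spots$bg_ch2 + sd_mult * spots$bg_sd_ch2)
  low_signal <- (spots$fg_ch1 - spots$bg_ch1 < min_signal) &
                (spots$fg_ch2 - spots$bg_ch2 < min_signal)
  flagged <- as.logical(spots$qc_flag)
  removed <- low_snr | low_signal | flagged
  rule <- ifelse(low_snr, "low_snr", ifelse(low_signal, "low_signal", "flagged"))
  id <- if ("spot_id" %in% names(spots)) spots$spot_id else seq_len(nrow(spots))
  list(kept = spots[!removed, , drop = FALSE],
       removed = spots[removed, , drop = FALSE],
       log = data.frame(spot = id[removed], rule = rule[removed],
                        stringsAsFactors = FALSE))
}

#' Per-gene mean log fold change and t-test p-value
#'
#' A plain one-sample two-sided t test of the replicate log2 ratios against
#' zero. This is a documented stand-in for a moderated-statistics array fit:
#' it is used for synthetic studies, while real per-gene p-values can be
#' ingested directly by [de_filter()]. Genes with zero replicate variance
#' get p = 1 when the mean is 0 and p = 0 otherwise (the limiting values).
#'
#' @param ratios Numeric matrix (genes x replicates) of log2 ratios, at
#'   least two replicates.
#' @return data.frame with `mean_logfc`, `t`, `p_value` per gene.
#' @export
gene_statistics <- function(ratios) {
  ratios <- as.matrix(ratios)
  k <- ncol(ratios)
  if (k < 2) stop("at least 2 replicates per gene are required")
  m <- rowMeans(ratios)
  s <- sqrt(rowSums((ratios - m)^2) / (k - 1))
  tstat <- m / (s / sqrt(k))
  p <- 2 * stats::pt(-abs(tstat), df = k - 1)
  zero_var <- s == 0
  p[zero_var] <- ifelse(m[zero_var] == 0, 1, 0)
  data.frame(mean_logfc = m, t = tstat, p_value = p,
             row.names = rownames(ratios))
}

#' Significance filter for differential expression
#'
#' Calls a gene up-regulated if its Benjamini-Hochberg adjusted p-value is
#' at or below `fdr` and its log2 fold change is at least `lfc_threshold`
#' (down-regulated with the opposite sign); everything else is unaffected.
#' The defaults are an FDR of 5% and |log2 ratio| >= 0.585 (a 1.5-fold
#' change).
#'
#' @param table data.frame with one row per gene.
#' @param fdr False discovery rate threshold, in (0, 1).
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param logfc_col,p_col Column names holding the log fold change and the
#'   p-value; defaults auto-detect `mean_logfc`/`logFC` and `p_value`/`p`,
#'   so externally produced tables can be ingested via column mapping.
#' @return A `de_result`: the table with `p_adj` and `call` columns plus
#'   counts `n_up`, `n_down`, `n_total_called`.
#' @export
de_filter <- function(table, fdr = 0.05, lfc_threshold = 0.585,
                      logfc_col = NULL, p_col = NULL) {
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr <= 0 || fdr >= 1) {
    stop("fdr must lie in (0, 1)")
  }
  logfc_col <- logfc_col %||% intersect(c("mean_logfc", "logFC", "logfc"), names(table))[1]
  p_col <- p_col %||% intersect(c("p_value", "p", "P.Value"), names(table))[1]
  if (is.na(logfc_col) || is.na(p_col)) {
    stop("could not locate log fold change / p-value columns; pass logfc_col and p_col")
  }
  lfc <- table[[logfc_col]]
  p <- table[[p_col]]
  if (any(is.na(p))) stop("p-values must be present for every gene")
  p_adj <- stats::p.adjust(p, method = "BH")
  call <- rep("unaffected", nrow(table))
  call[p_adj <= fdr & lfc >= lfc_threshold] <- "up"
  call[p_adj <= fdr & lfc <= -lfc_threshold] <- "down"
  out <- table
  out$logFC <- lfc
  out$p_adj <- p_adj
  out$call <- call
  structure(list(table = out,
                 n_up = sum(call == "up"), n_down = sum(call == "down"),
                 n_total_called = sum(call != "unaffected"),
                 fdr = fdr, lfc_threshold = lfc_threshold),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes called (%d up, %d down) of %d at FDR %.2g, |logFC| >= %.3g\n",
              x$n_total_called, x$n_up, x$n_down, nrow(x$table),
              x$fdr, x$lfc_threshold))
  invisible(x)
}

# Two-sided Fisher's exact test for a 2x2 table by hypergeometric
# enumeration: sum the probabilities of all tables (conditional on margins)
# no more probable than the observed one.
fisher_2x2_exact <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# log conditional probability of an Rx2 table given its margins
log_prob_rx2 <- function(tab) {
  sum(lchoose(rowSums(tab), tab[, 1])) - lchoose(sum(tab), sum(tab[, 1]))
}

#' Fisher's exact test of independence for TAD enrichment
#'
#' Builds the TAD-by-regulation contingency table (TADs as rows; regulated
#' versus unaffected genes as columns, restricted to genes on the array) and
#' tests independence with Fisher's exact test: exact hypergeometric
#' enumeration for 2x2 tables, and a Monte-Carlo p-value conditional on the
#' margins (Patefield sampling, probability ordering, at least 1e4 tables)
#' for larger tables, reported with its Monte-Carlo standard error. Genes
#' without a TAD assignment are excluded and counted in the removal log.
#'
#' @param de Either a `de_result` or a data.frame with a `call` column.
#' @param tad_id TAD assignment per gene (character/factor; `NA` = unmapped).
#'   Defaults to the `tad_id` column of the table.
#' @param regulation Which calls count as regulated: `"any"` (default),
#'   `"up"` or `"down"`.
#' @param n_sim Number of Monte-Carlo tables for R x 2 testing.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `p_value`, `mc_se` (`NA` for the exact 2x2 path),
#'   `method`, the contingency `table`, and `n_unmapped`.
#' @export
tad_enrichment <- function(de, tad_id = NULL, regulation = c("any", "up", "down"),
                           n_sim = 10000, seed = 1) {
  regulation <- match.arg(regulation)
  tab_df <- if (inherits(de, "de_result")) de$table else as.data.frame(de)
  if (!"call" %in% names(tab_df)) stop("de must provide a 'call' column")
  tad_id <- tad_id %||% tab_df$tad_id
  if (is.null(tad_id)) stop("every gene must be mapped to a TAD or explicitly unmapped (NA)")
  if (length(tad_id) != nrow(tab_df)) stop("tad_id must have one entry per gene")

  mapped <- !is.na(tad_id)
  n_unmapped <- sum(!mapped)
  call <- tab_df$call[mapped]
  tad <- as.character(tad_id)[mapped]
  regulated <- switch(regulation,
                      any = call != "unaffected",
                      up = call == "up",
                      down = call == "down")
  keep <- regulated | call == "unaffected"
  tab <- table(tad = tad[keep],
               status = factor(ifelse(regulated[keep], "regulated", "unaffected"),
                               levels = c("regulated", "unaffected")))
  if (nrow(tab) == 0 || sum(tab) == 0) stop("empty contingency table")
  tab <- unclass(tab)

  if (sum(tab[, "regulated"]) == 0 || sum(tab[, "unaffected"]) == 0) {
    # a degenerate column: the observed table is the only one compatible
    # with its margins
    return(list(p_value = 1, mc_se = NA_real_, method = "degenerate",
                table = tab, n_unmapped = n_unmapped))
  }
  if (nrow(tab) == 2) {
    p <- fisher_2x2_exact(tab)
    return(list(p_value = min(p, 1), mc_se = NA_real_, method = "exact",
                table = tab, n_unmapped = n_unmapped))
  }
  n_sim <- max(n_sim, 10000)
  lp_obs <- log_prob_rx2(tab)
  hits <- with_seed(seed, {
    sims <- stats::r2dtable(n_sim, rowSums(tab), colSums(tab))
    sum(vapply(sims, log_prob_rx2, numeric(1)) <= lp_obs + 1e-7)
  })
  p <- (1 + hits) / (n_sim + 1)
  list(p_value = p, mc_se = sqrt(p * (1 - p) / n_sim), method = "monte-carlo",
       table = tab, n_unmapped = n_unmapped)
}

#' Bootstrap median with percentile confidence interval
#'
#' Sample median plus a percentile (2.5%, 97.5% by default) bootstrap
#' confidence interval from `n_boot` resamples; deterministic for a given
#' seed.
#'
#' @param values Numeric vector (at least 2 values), e.g. gene sizes in kb.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf_level Confidence level.
#' @return Named list `median`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_median <- function(values, n_boot = 1000, seed = 1, conf_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot, replace = TRUE),
                  ncol = n_boot)
    apply(matrix(values[idx], ncol = n_boot), 2, stats::median)
  })
  alpha <- 1 - conf_level
  ci <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(median = stats::median(values), ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot)
}

#' Knockdown efficiency by the delta-delta-Cq method
#'
#' Technical replicates are averaged first; then
#' `dCq = Cq_target - Cq_reference` per condition,
#' `ddCq = dCq_knockdown - dCq_control`, relative expression `2^-ddCq`, and
#' knockdown efficiency `(1 - 2^-ddCq) * 100` percent.
#'
#' @param cq_target_kd,cq_ref_kd Target and reference-gene Cq values in the
#'   knockdown condition (vectors of technical replicates allowed).
#' @param cq_target_ctrl,cq_ref_ctrl The same for the control condition.
#' @return Named list `delta_delta_cq`, `relative_expression`,
#'   `knockdown_pct`.
#' @export
delta_delta_cq <- function(cq_target_kd, cq_ref_kd, cq_target_ctrl, cq_ref_ctrl) {
  vals <- list(cq_target_kd, cq_ref_kd, cq_target_ctrl, cq_ref_ctrl)
  if (any(vapply(vals, function(v) length(v) == 0 || anyNA(v), logical(1)))) {
    stop("all four Cq inputs must be present and free of NA")
  }
  d_kd <- mean(cq_target_kd) - mean(cq_ref_kd)
  d_ctrl <- mean(cq_target_ctrl) - mean(cq_ref_ctrl)
  ddcq <- d_kd - d_ctrl
  rel <- 2^(-ddcq)
  list(delta_delta_cq = ddcq, relative_expression = rel,
       knockdown_pct = (1 - rel) * 100)
}
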