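# Configuration and the end-to-end pipeline drivers tying the modules
# together, plus the CSV plumbing with provenance headers.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its default:
#' ring reference time 120 s, closure-fraction 0.5 for t_half, profile
#' width 10 px, kymograph ROI 5.3 x 94.9 um, FDR 5%, |log2 ratio|
#' threshold 0.585 (1.5-fold), 1000 bootstrap iterations. Every value can
#' be overridden, and the configuration is echoed into the provenance
#' header of every CSV the pipeline writes.
#'
#' @param pixel_size Micrometres per pixel of the stacks processed.
#' @param ring_reference_time_s Timepoint of the ring-geometry measurement.
#' @param thalf_fraction Fraction of the maximum area defining t_half.
#' @param profile_width_px Number of lines averaged by [line_profile()].
#' @param kymo_length_um,kymo_width_um Kymograph ROI, micrometres.
#' @param closure_area_um2 Wound-closure area threshold.
#' @param fdr False discovery rate of the significance filter.
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @param n_boot Bootstrap iterations for the gene-size median.
#' @param seed Seed driving every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.22,
                            ring_reference_time_s = 120,
                            thalf_fraction = 0.5,
                            profile_width_px = 10,
                            kymo_length_um = 94.9,
                            kymo_width_um = 5.3,
                            closure_area_um2 = 1,
                            fdr = 0.05,
                            lfc_threshold = 0.585,
                            n_boot = 1000,
                            seed = 1L) {
  if (thalf_fraction < 0.35 || thalf_fraction > 0.5) {
    stop("thalf_fraction must lie in [0.35, 0.5]")
  }
  structure(list(pixel_size = pixel_size,
                 ring_reference_time_s = ring_reference_time_s,
                 thalf_fraction = thalf_fraction,
                 profile_width_px = profile_width_px,
                 kymo_length_um = kymo_length_um,
                 kymo_width_um = kymo_width_um,
                 closure_area_um2 = closure_area_um2,
                 fdr = fdr, lfc_threshold = lfc_threshold,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_header <- function(config, stage) {
  vals <- vapply(config, function(v) paste(format(v), collapse = ","), character(1))
  c(sprintf("# woundquant %s", stage),
    sprintf("# config: %s", paste(names(vals), vals, sep = "=", collapse = "; ")))
}

#' Write a table as CSV with a provenance header
#'
#' @param x data.frame.
#' @param path Output path.
#' @param config A `pipeline_config` echoed as comment lines.
#' @param stage Stage label for the header.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, config = NULL, stage = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(config_header(config, stage), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Simulate a wound stack and write it to disk
#'
#' Wraps [simulate_wound_stack()]: renders the stack, writes the TIFF with
#' its JSON sidecar (parameters and seed included) and the ground-truth
#' trajectory as CSV.
#'
#' @param config A `pipeline_config` (supplies the seed used when `params`
#'   is left at its defaults).
#' @param out_dir Output directory (created if needed).
#' @param params Optional [wound_sim_params()]; defaults derive the seed and
#'   pixel size from `config`.
#' @param stack_id Basename for the output files.
#' @param verbose Log one line per stage.
#' @return Invisible list with `stack_path`, `truth_path`, `stack`, `truth`.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir = ".",
                         params = NULL, stack_id = "simulated_wound",
                         verbose = TRUE) {
  if (is.null(params)) {
    params <- wound_sim_params(pixel_size = config$pixel_size,
                               rng_seed = config$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_wound_stack(params)
  stack_path <- file.path(out_dir, paste0(stack_id, ".tif"))
  side_extra <- params
  class(side_extra) <- NULL
  side_extra$frame_times <- NULL
  write_stack(sim$stack, stack_path, extra = list(sim_params = side_extra))
  truth_df <- data.frame(frame_time_s = sim$truth$frame_times,
                         wound_radius_um = sim$truth$wound_radius,
                         area_um2 = sim$truth$implied_area)
  truth_path <- file.path(out_dir, paste0(stack_id, "_truth.csv"))
  write_table_csv(truth_df, truth_path, config, "ground_truth")
  log_stage(verbose, "simulate", "%d frames (%dx%d px) -> %s",
            length(sim$stack), params$image_shape[1], params$image_shape[2],
            stack_path)
  invisible(list(stack_path = stack_path, truth_path = truth_path,
                 stack = sim$stack, truth = sim$truth))
}

#' Quantify one stack end to end
#'
#' Runs segmentation, repair metrics, the dynamic profile and the kymograph
#' on a stack (path or in-memory), writing the wound trace, the one-row
#' metrics table, the profile table and the kymograph matrix as CSV. On a
#' stage failure the partial outputs written so far are kept and an error
#' manifest (`<stack_id>_errors.csv`) names the failed stage.
#'
#' @param config A `pipeline_config`.
#' @param stack A `wound_stack` or a path readable by [read_stack()].
#' @param out_dir Output directory.
#' @param stack_id Basename for outputs.
#' @param verbose Log one line per stage.
#' @return Invisible list with `metrics`, `trace`, `profiles`, `kymograph`
#'   and the paths written; `errors` lists any failed stages.
#' @export
run_quantify <- function(config = pipeline_config(), stack, out_dir = ".",
                         stack_id = "stack", verbose = TRUE) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "wound_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  errors <- data.frame(stage = character(), error = character())
  out <- list()

  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      errors[nrow(errors) + 1L, ] <<- c(stage, conditionMessage(e))
      log_stage(verbose, stage, "FAILED: %s", conditionMessage(e))
      NULL
    })
  }

  out$metrics <- run_stage("summarize_repair", function() {
    m <- summarize_repair(stack, config)
    paths$metrics <<- file.path(out_dir, paste0(stack_id, "_metrics.csv"))
    write_table_csv(repair_metrics_row(m, stack_id), paths$metrics,
                    config, "repair_metrics")
    tr <- m$trace$areas
    paths$trace <<- file.path(out_dir, paste0(stack_id, "_trace.csv"))
    write_table_csv(data.frame(frame_time_s = tr$frame_time,
                               area_um2 = tr$area_um2,
                               closed_flag = tr$closed),
                    paths$trace, config, "wound_trace")
    log_stage(verbose, "summarize_repair",
              "fold=%.3f rate=%.4f um^2/s width=%.2f um",
              m$expansion_fold, m$contraction_rate_um2_s, m$ring_width_um)
    m
  })

  out$profiles <- run_stage("dynamic_profile", function() {
    pr <- dynamic_profile(stack, width_px = config$profile_width_px)
    flat <- do.call(rbind, Map(function(p, t) {
      cbind(frame_time_s = t, p)
    }, pr, stack$frame_times))
    paths$profiles <<- file.path(out_dir, paste0(stack_id, "_profiles.csv"))
    write_table_csv(flat, paths$profiles, config, "dynamic_profile")
    log_stage(verbose, "dynamic_profile", "%d frames x %d positions",
              length(pr), nrow(pr[[1]]))
    pr
  })

  out$kymograph <- run_stage("kymograph", function() {
    # clamp the configured ROI to the field of view (small simulated frames
    # can be narrower than the configured band)
    d <- dim(stack$frames[[1]])
    len <- min(config$kymo_length_um, (d[2] - 2) * stack$pixel_size)
    wid <- min(config$kymo_width_um, (d[1] - 2) * stack$pixel_size)
    if (len < config$kymo_length_um || wid < config$kymo_width_um) {
      log_stage(verbose, "kymograph", "roi clamped to %.1f x %.1f um", len, wid)
    }
    ky <- kymograph(stack, length_um = len, width_um = wid)
    df <- as.data.frame(unclass(ky))
    names(df) <- sprintf("t_%g", attr(ky, "frame_times"))
    df <- cbind(position_um = attr(ky, "position_um"), df)
    paths$kymograph <<- file.path(out_dir, paste0(stack_id, "_kymograph.csv"))
    write_table_csv(df, paths$kymograph, config, "kymograph")
    log_stage(verbose, "kymograph", "%d x %d", nrow(ky), ncol(ky))
    ky
  })

  if (nrow(errors) > 0) {
    paths$errors <- file.path(out_dir, paste0(stack_id, "_errors.csv"))
    write_table_csv(errors, paths$errors, config, "error_manifest")
  }
  invisible(c(out, list(paths = paths, errors = errors)))
}

#' Run the expression-statistics pipeline
#'
#' Spot filter, per-gene statistics (if replicate ratio columns are
#' present), the significance filter, TAD enrichment, and gene-size
#' bootstrap summaries of the up / down / unaffected sets, assembled into
#' one report. Row conservation (kept + removed = input) is asserted for
#' every filter.
#'
#' @param config A `pipeline_config`.
#' @param spots Spot-level data.frame (see [filter_spots()]), or `NULL` to
#'   skip spot filtering.
#' @param genes Per-gene data.frame with replicate `ratio_*` columns or
#'   precomputed `mean_logfc` / `p_value` columns, plus optional
#'   `gene_size_kb` and `tad_id`.
#' @param out_dir Optional output directory for the DE table CSV.
#' @param verbose Log one line per stage.
#' @return List with `spot_filter`, `de`, `tad`, `size_summary`, `report`.
#' @export
run_expression <- function(config = pipeline_config(), spots = NULL, genes,
                           out_dir = NULL, verbose = TRUE) {
  report <- list()
  sf <- NULL
  if (!is.null(spots)) {
    sf <- filter_spots(spots)
    stopifnot(nrow(sf$kept) + nrow(sf$removed) == nrow(spots))
    report$spots_in <- nrow(spots)
    report$spots_removed <- nrow(sf$removed)
    report$spot_rules <- table(sf$log$rule)
    log_stage(verbose, "filter_spots", "%d of %d spots removed",
              nrow(sf$removed), nrow(spots))
    if ("spot_id" %in% names(spots) && "gene_id" %in% names(genes)) {
      genes <- genes[genes$gene_id %in% sf$kept$spot_id, , drop = FALSE]
    }
  }

  ratio_cols <- grep("^ratio_", names(genes), value = TRUE)
  if (length(ratio_cols) >= 2) {
    gs <- gene_statistics(as.matrix(genes[ratio_cols]))
    genes$mean_logfc <- gs$mean_logfc
    genes$p_value <- gs$p_value
  }
  de <- de_filter(genes, fdr = config$fdr, lfc_threshold = config$lfc_threshold)
  stopifnot(de$n_up + de$n_down == de$n_total_called)
  report$n_genes <- nrow(de$table)
  report$n_up <- de$n_up; report$n_down <- de$n_down
  report$n_total_called <- de$n_total_called
  log_stage(verbose, "de_filter", "%d called (%d up, %d down) of %d",
            de$n_total_called, de$n_up, de$n_down, nrow(de$table))

  tad <- NULL
  if ("tad_id" %in% names(de$table)) {
    tad <- tryCatch(tad_enrichment(de, n_sim = 10000, seed = config$seed),
                    error = function(e) NULL)
    if (!is.null(tad)) {
      report$tad_p <- tad$p_value
      log_stage(verbose, "tad_enrichment", "p = %.4g (%s)",
                tad$p_value, tad$method)
    }
  }

  size_summary <- NULL
  if ("gene_size_kb" %in% names(de$table)) {
    size_summary <- do.call(rbind, lapply(c("up", "down", "unaffected"), function(cl) {
      v <- de$table$gene_size_kb[de$table$call == cl]
      if (length(v) < 2) return(NULL)
      b <- bootstrap_median(v, n_boot = config$n_boot, seed = config$seed)
      data.frame(call = cl, n = length(v), mean_kb = mean(v),
                 median_kb = b$median, ci_low = b$ci_low, ci_high = b$ci_high)
    }))
    log_stage(verbose, "gene_size", "bootstrap medians for %d classes",
              if (is.null(size_summary)) 0 else nrow(size_summary))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- intersect(c("gene_id", "logFC", "p_value", "p_adj", "call"),
                      names(de$table))
    write_table_csv(de$table[keep], file.path(out_dir, "de_result.csv"),
                    config, "de_result")
  }
  list(spot_filter = sf, de = de, tad = tad, size_summary = size_summary,
       report = report)
}
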