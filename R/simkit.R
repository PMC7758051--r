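# Synthetic wound-repair movies and expression studies with known ground truth.

#' Default acquisition time grid
#'
#' One pre-wound frame at -30 s, then a frame every 30 s out to 900 s,
#' followed by one every 60 s out to 2400 s -- the cadence of single-colour
#' live imaging in the embryo wounding assay.
#'
#' @return Numeric vector of frame times in seconds relative to wounding.
#' @export
default_frame_times <- function() {
  c(-30, seq(0, 900, by = 30), seq(960, 2400, by = 60))
}

#' Parameters for a simulated wound-repair stack
#'
#' Bundles the geometry, trajectory, intensity and noise parameters of the
#' phenomenological wound simulator and validates their invariants. The wound
#' opens at t = 0 at radius `r0`, expands smoothly (half-cosine ramp) to
#' `expansion_fold_true` times its initial area at `t_max_true`, then closes
#' by a linear area decay of magnitude `closure_rate_true`. A bright
#' actomyosin ring of width `ring_width_true` abuts the wound edge, flanked
#' by a dimmer, wider actin halo; the unwounded cortex fluoresces at
#' `cortex_baseline`.
#'
#' @param image_shape Integer (H, W) in pixels.
#' @param pixel_size Physical pixel size, micrometres per pixel.
#' @param frame_times Frame timestamps in seconds relative to wounding;
#'   strictly increasing with exactly one pre-wound frame (t < 0).
#' @param r0 Initial (t = 0) wound radius, micrometres.
#' @param expansion_fold_true Maximum area / initial area; >= 1.
#' @param t_max_true Time of maximal wound area, seconds.
#' @param closure_rate_true Magnitude of the post-peak linear area decay,
#'   square micrometres per second.
#' @param post_half_rate Optional shallower decay rate applied once the area
#'   has fallen to half its maximum, emulating the observed slope change of
#'   the area curve after that point; `NULL` keeps a single linear segment.
#' @param ring_width_true Actin ring width, micrometres.
#' @param ring_amplitude Ring intensity above the cortex baseline.
#' @param halo_width Width of the outer actin halo, micrometres.
#' @param halo_amplitude Halo intensity above the cortex baseline.
#' @param cortex_baseline Unwounded cortex intensity; must be positive and
#'   below `ring_amplitude`.
#' @param remodel_area Wound area (square micrometres) below which ring and
#'   halo amplitudes fade out in proportion to the remaining area, emulating
#'   ring disassembly and cortical remodeling around closure.
#' @param edge_softness Length scale (micrometres) of the smooth radial
#'   transitions between wound interior, ring, halo and cortex.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation (intensity units);
#'   defaults to 5\% of `ring_amplitude`.
#' @param poisson_gain Intensity units per photon for the Poisson model.
#' @param rng_seed Integer seed controlling all simulator randomness.
#'
#' @return An object of class `wound_sim_params` (a validated list).
#' @export
wound_sim_params <- function(image_shape = c(192L, 192L),
                             pixel_size = 0.22,
                             frame_times = default_frame_times(),
                             r0 = 6,
                             expansion_fold_true = 1.4,
                             t_max_true = 60,
                             closure_rate_true = 0.15,
                             post_half_rate = NULL,
                             ring_width_true = 2,
                             ring_amplitude = 120,
                             halo_width = 3,
                             halo_amplitude = 35,
                             cortex_baseline = 40,
                             remodel_area = 50,
                             edge_softness = 0.15,
                             noise_model = c("gaussian", "none", "poisson"),
                             noise_sd = 0.05 * ring_amplitude,
                             poisson_gain = 1,
                             rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_shape) == 2, all(image_shape >= 16))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (sum(frame_times < 0) != 1) stop("frame_times must contain exactly one pre-wound frame (t < 0)")
  if (!any(frame_times >= 0)) stop("frame_times must contain post-wound frames")
  if (expansion_fold_true < 1) stop("expansion_fold_true must be >= 1")
  if (r0 <= 0 || ring_width_true <= 0 || halo_width <= 0) stop("all lengths must be positive")
  if (t_max_true < 0) stop("t_max_true must be >= 0")
  if (closure_rate_true < 0) stop("closure_rate_true must be >= 0")
  if (!(ring_amplitude > cortex_baseline && cortex_baseline > 0)) {
    stop("require ring_amplitude > cortex_baseline > 0")
  }
  if (remodel_area <= 0) stop("remodel_area must be positive")
  if (!is.null(post_half_rate) && (post_half_rate < 0 || post_half_rate > closure_rate_true)) {
    stop("post_half_rate must lie in [0, closure_rate_true]")
  }
  p <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    frame_times = frame_times, r0 = r0,
    expansion_fold_true = expansion_fold_true, t_max_true = t_max_true,
    closure_rate_true = closure_rate_true, post_half_rate = post_half_rate,
    ring_width_true = ring_width_true, ring_amplitude = ring_amplitude,
    halo_width = halo_width, halo_amplitude = halo_amplitude,
    cortex_baseline = cortex_baseline, remodel_area = remodel_area,
    edge_softness = edge_softness,
    noise_model = noise_model, noise_sd = noise_sd,
    poisson_gain = poisson_gain, rng_seed = as.integer(rng_seed)
  )
  # geometry check: fully expanded wound + ring + halo must fit inside image
  r_max <- sqrt(expansion_fold_true) * r0 + ring_width_true + halo_width
  half_extent <- min(image_shape) / 2 * pixel_size
  if (r_max >= half_extent) {
    stop(sprintf("wound (+ring, +halo) of radius %.1f um exceeds image half-extent %.1f um",
                 r_max, half_extent))
  }
  class(p) <- "wound_sim_params"
  p
}

#' Noiseless wound-area trajectory
#'
#' Evaluates the piecewise area trajectory underlying the simulator: zero
#' before wounding, a half-cosine ramp from `pi * r0^2` at t = 0 up to
#' `expansion_fold_true` times that at `t_max_true`, then linear decay at
#' `closure_rate_true` (optionally switching to `post_half_rate` once the
#' area falls to half its maximum), clamped at zero after closure.
#'
#' @param params A [wound_sim_params()] object.
#' @param t Times in seconds; must lie within the simulated frame range.
#' @return Wound area(s) in square micrometres.
#' @export
area_trajectory <- function(params, t) {
  stopifnot(inherits(params, "wound_sim_params"))
  rng <- range(params$frame_times)
  if (any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9)) {
    stop("t outside the simulated frame-time range")
  }
  a0 <- pi * params$r0^2
  amax <- params$expansion_fold_true * a0
  tm <- params$t_max_true
  rate <- params$closure_rate_true
  ramp <- function(ti) {
    if (tm <= 0) return(amax)
    a0 + (amax - a0) * (1 - cos(pi * pmin(ti, tm) / tm)) / 2
  }
  decay <- function(ti) {
    a <- amax - rate * (ti - tm)
    if (!is.null(params$post_half_rate)) {
      t_half <- tm + (amax / 2) / max(rate, .Machine$double.eps)
      late <- ti > t_half
      a[late] <- amax / 2 - params$post_half_rate * (ti[late] - t_half)
    }
    pmax(a, 0)
  }
  out <- numeric(length(t))
  pre <- t < 0
  up <- !pre & t <= tm
  down <- !pre & t > tm
  out[up] <- ramp(t[up])
  out[down] <- decay(t[down])
  out
}

# Continuous radial intensity profile of the rendered frame at wound radius
# rw (um). A logistic step of scale `soft` smooths every transition. As the
# wound closes, ring and halo amplitudes fade in proportion to the remaining
# wound area (remodeling), so the rendered movie changes linearly in time
# through closure rather than with the square-root steepness of the radius.
radial_profile_fun <- function(params, rw) {
  soft <- params$edge_softness
  w <- params$ring_width_true
  hw <- params$halo_width
  fade <- if (rw <= 0) 0 else min(1, pi * rw^2 / params$remodel_area)
  function(r) {
    if (rw <= 0) {
      return(rep(params$cortex_baseline, length(r)))
    }
    s1 <- stats::plogis((r - rw) / soft)           # wound edge
    s2 <- stats::plogis((r - (rw + w)) / soft)     # ring outer edge
    s3 <- stats::plogis((r - (rw + w + hw)) / soft) # halo outer edge
    params$cortex_baseline * s1 +
      fade * params$ring_amplitude * (s1 - s2) +
      fade * params$halo_amplitude * (s2 - s3)
  }
}

# Mean of the radial profile over the annulus between its half-maximum
# crossings: the closed-form counterpart of the measured ring mean intensity.
implied_ring_stats <- function(params, rw) {
  f <- radial_profile_fun(params, rw)
  if (rw <= 0) return(list(mean = NA_real_, inner = NA_real_, outer = NA_real_))
  r_far <- rw + params$ring_width_true + params$halo_width + 3
  baseline <- f(r_far)
  peak <- stats::optimize(f, c(max(rw - 1, 0), rw + params$ring_width_true + 1),
                          maximum = TRUE)
  half <- baseline + (peak$objective - baseline) / 2
  g <- function(r) f(r) - half
  inner <- stats::uniroot(g, c(1e-6, peak$maximum))$root
  outer <- stats::uniroot(g, c(peak$maximum, r_far))$root
  num <- stats::integrate(function(r) f(r) * 2 * pi * r, inner, outer)$value
  den <- pi * (outer^2 - inner^2)
  list(mean = num / den, inner = inner, outer = outer)
}

#' Simulate a wound-repair time-lapse stack
#'
#' Renders one frame per entry of `params$frame_times`: uniform cortex before
#' wounding, and afterwards a dark (membrane-plug) wound interior surrounded
#' by a bright actomyosin ring and an outer halo, all moving with the wound
#' edge as the area follows [area_trajectory()]. Noise is applied last.
#' Identical parameters and seed give bit-identical stacks.
#'
#' @param params A [wound_sim_params()] object.
#' @return A list with components `stack` (a `wound_stack`: list of frame
#'   matrices plus `frame_times`, `pixel_size`, `channel_label`) and `truth`
#'   (a `wound_ground_truth` with per-frame radii and the analytically
#'   implied repair metrics).
#' @export
simulate_wound_stack <- function(params) {
  stopifnot(inherits(params, "wound_sim_params"))
  h <- params$image_shape[1]; w_px <- params$image_shape[2]
  ps <- params$pixel_size
  cy <- (h + 1) / 2; cx <- (w_px + 1) / 2
  dist_um <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w_px) - cx)^2, "+")) * ps

  areas <- area_trajectory(params, params$frame_times)
  radii <- sqrt(areas / pi)

  frames <- vector("list", length(params$frame_times))
  for (i in seq_along(frames)) {
    ti <- params$frame_times[i]
    if (ti < 0 || radii[i] <= 0) {
      fr <- matrix(params$cortex_baseline, h, w_px)
    } else {
      f <- radial_profile_fun(params, radii[i])
      fr <- matrix(f(as.vector(dist_um)), h, w_px)
    }
    frames[[i]] <- fr
  }

  frames <- with_seed(params$rng_seed, {
    lapply(frames, function(fr) {
      fr <- switch(params$noise_model,
        none = fr,
        gaussian = fr + matrix(stats::rnorm(length(fr), sd = params$noise_sd),
                               nrow(fr)),
        poisson = {
          g <- params$poisson_gain
          matrix(stats::rpois(length(fr), lambda = pmax(fr, 0) / g) * g, nrow(fr))
        })
      pmax(fr, 0)
    })
  })

  stack <- new_wound_stack(frames, params$frame_times, ps,
                           channel_label = "actin")

  post <- params$frame_times >= 0
  open_post <- post & radii > 0
  ring_inner <- ifelse(open_post, radii, NA_real_)
  ring_outer <- ifelse(open_post, radii + params$ring_width_true, NA_real_)

  # reference-time ring statistics from the closed-form profile at the radius
  # the wound actually has at the reference time (120 s)
  ref_t <- 120
  ref_rw <- sqrt(area_trajectory(params, min(ref_t, max(params$frame_times))) / pi)
  rs_ref <- if (ref_rw > 0) implied_ring_stats(params, ref_rw) else list(mean = NA_real_)

  truth <- structure(list(
    frame_times = params$frame_times,
    wound_radius = ifelse(post, radii, 0),
    ring_inner_radius = ring_inner,
    ring_outer_radius = ring_outer,
    implied_area = ifelse(post, areas, 0),
    implied_expansion_fold = params$expansion_fold_true,
    implied_t_max = params$t_max_true,
    implied_contraction_rate = params$closure_rate_true,
    implied_ring_width = params$ring_width_true,
    implied_ring_mean_intensity = rs_ref$mean,
    implied_relative_ring_intensity = rs_ref$mean / params$cortex_baseline,
    params = params
  ), class = "wound_ground_truth")

  list(stack = stack, truth = truth)
}

#' Parameters for a simulated wounded-vs-unwounded expression study
#'
#' Describes a planted-truth two-channel array study with the design of the
#' post-wounding screen: four independent replicates of wounded versus
#' unwounded samples, per-gene log2 ratios equal to a planted effect plus
#' i.i.d. Gaussian noise. Defaults mirror the study scale: ~8000 genes on the
#' array, 80 up- and 173 down-regulated, 1169 TADs.
#'
#' @param n_genes Number of genes on the array.
#' @param n_replicates Number of independent replicates (default 4).
#' @param n_up,n_down Number of planted up-/down-regulated genes.
#' @param effect_range Range (log2 units) from which planted effect
#'   magnitudes are drawn uniformly; chosen to bracket the observed top
#'   fold-changes (|logFC| roughly 0.7-1.4).
#' @param sigma Replicate noise standard deviation (log2 units).
#' @param size_medians_kb Named median transcript sizes (kb) for the
#'   `unaffected`, `up` and `down` classes; gene sizes are log-normal with
#'   these medians (unaffected default 2.5 kb, the average transcript size of
#'   the syncytial embryo; up-regulated genes larger, down-regulated smaller).
#' @param size_sdlog Log-scale SD of the gene-size distribution.
#' @param n_tads Number of topologically associating domains genes map onto.
#' @param tad_clustering If `TRUE`, planted genes are concentrated in a few
#'   TADs; if `FALSE` (default) they are scattered at random.
#' @param spot_frac_low_snr,spot_frac_low_signal,spot_frac_flagged Fractions
#'   of array spots constructed to violate, respectively, the 3-SD-above-
#'   background rule, the background-subtracted-signal < 100 rule, and the
#'   QC flag rule.
#' @param rng_seed Integer seed.
#' @return An object of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_genes = 7977,
                            n_replicates = 4,
                            n_up = 80,
                            n_down = 173,
                            effect_range = c(0.7, 1.4),
                            sigma = 0.15,
                            size_medians_kb = c(unaffected = 2.5, up = 3.7, down = 1.9),
                            size_sdlog = 0.6,
                            n_tads = 1169,
                            tad_clustering = FALSE,
                            spot_frac_low_snr = 0.03,
                            spot_frac_low_signal = 0.03,
                            spot_frac_flagged = 0.02,
                            rng_seed = 1L) {
  if (n_up + n_down > n_genes) stop("n_up + n_down must not exceed n_genes")
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_replicates < 2) stop("need at least 2 replicates")
  stopifnot(all(c("unaffected", "up", "down") %in% names(size_medians_kb)))
  p <- list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
            n_up = as.integer(n_up), n_down = as.integer(n_down),
            effect_range = effect_range, sigma = sigma,
            size_medians_kb = size_medians_kb, size_sdlog = size_sdlog,
            n_tads = as.integer(n_tads), tad_clustering = isTRUE(tad_clustering),
            spot_frac_low_snr = spot_frac_low_snr,
            spot_frac_low_signal = spot_frac_low_signal,
            spot_frac_flagged = spot_frac_flagged,
            rng_seed = as.integer(rng_seed))
  class(p) <- "expr_sim_params"
  p
}

#' Simulate an expression study with planted truth
#'
#' Generates (i) a spot-level table with foreground/background statistics per
#' channel, in which configurable fractions of spots violate each spot-filter
#' rule, and (ii) a per-gene expression table of replicate log2 ratios
#' (wounded vs unwounded) with planted up/down effects, gene sizes, TAD
#' assignments and truth labels.
#'
#' @param params An [expr_sim_params()] object.
#' @return List with `spots` (data.frame) and `genes` (data.frame with
#'   replicate ratio columns `ratio_1..k`, `mean_logfc`, `gene_size_kb`,
#'   `tad_id`, `truth`).
#' @export
simulate_expression_study <- function(params) {
  stopifnot(inherits(params, "expr_sim_params"))
  with_seed(params$rng_seed, {
    n <- params$n_genes; k <- params$n_replicates
    truth <- rep("unaffected", n)
    planted <- sample.int(n, params$n_up + params$n_down)
    up_idx <- planted[seq_len(params$n_up)]
    down_idx <- setdiff(planted, up_idx)
    truth[up_idx] <- "up"; truth[down_idx] <- "down"

    effect <- numeric(n)
    if (params$n_up > 0)
      effect[up_idx] <- stats::runif(params$n_up, params$effect_range[1], params$effect_range[2])
    if (params$n_down > 0)
      effect[down_idx] <- -stats::runif(params$n_down, params$effect_range[1], params$effect_range[2])

    ratios <- matrix(stats::rnorm(n * k, mean = effect, sd = params$sigma), n, k)
    colnames(ratios) <- paste0("ratio_", seq_len(k))

    med <- params$size_medians_kb[truth]
    gene_size <- stats::rlnorm(n, meanlog = log(med), sdlog = params$size_sdlog)

    # contiguous gene -> TAD assignment; planted genes optionally piled into
    # a handful of TADs to exercise the enrichment test
    tad_id <- sort(sample.int(params$n_tads, n, replace = TRUE))
    if (params$tad_clustering && length(planted) > 0) {
      n_cl <- max(1L, ceiling(length(planted) / 50))
      tad_id[planted] <- sample.int(n_cl, length(planted), replace = TRUE)
    }

    genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n)), ratios,
                        mean_logfc = rowMeans(ratios),
                        gene_size_kb = gene_size,
                        tad_id = paste0("tad", tad_id),
                        truth = truth, stringsAsFactors = FALSE)

    # spot table: one spot per gene, two channels, planted rule violations
    bg <- matrix(stats::rlnorm(n * 2, log(80), 0.2), n, 2)
    bg_sd <- matrix(stats::rlnorm(n * 2, log(8), 0.3), n, 2)
    fg <- bg + matrix(stats::rlnorm(n * 2, log(1500), 0.5), n, 2)
    fail <- sample(c("none", "low_snr", "low_signal", "flagged"), n, replace = TRUE,
                   prob = c(1 - params$spot_frac_low_snr - params$spot_frac_low_signal -
                              params$spot_frac_flagged,
                            params$spot_frac_low_snr, params$spot_frac_low_signal,
                            params$spot_frac_flagged))
    snr_bad <- fail == "low_snr"
    ch_bad <- sample.int(2, sum(snr_bad), replace = TRUE)
    for (j in 1:2) {
      sel <- which(snr_bad)[ch_bad == j]
      # below background + 3 SD in that channel; the background SD is raised
      # so that fg - bg stays >= 100 there and only the SNR rule fires
      bg_sd[sel, j] <- pmax(bg_sd[sel, j], 60)
      fg[sel, j] <- bg[sel, j] + 2 * bg_sd[sel, j]
    }
    sig_bad <- fail == "low_signal"
    if (any(sig_bad)) {
      delta <- matrix(stats::runif(sum(sig_bad) * 2, 40, 99), sum(sig_bad), 2)
      fg[sig_bad, ] <- bg[sig_bad, ] + delta
      # keep these spots clear of the SNR rule so only the signal rule fires
      bg_sd[sig_bad, ] <- delta / 3.5
    }
    spots <- data.frame(
      spot_id = genes$gene_id,
      fg_ch1 = fg[, 1], bg_ch1 = bg[, 1], bg_sd_ch1 = bg_sd[, 1],
      fg_ch2 = fg[, 2], bg_ch2 = bg[, 2], bg_sd_ch2 = bg_sd[, 2],
      qc_flag = fail == "flagged",
      truth_fail = fail, stringsAsFactors = FALSE
    )
    list(spots = spots, genes = genes)
  })
}
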