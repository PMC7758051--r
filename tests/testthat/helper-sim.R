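# Shared fixtures: small, fast simulation parameter sets built in code.

# Compact wound movie: 112x112 px, one pre-wound frame, 30 s cadence to 600 s.
tiny_wound_params <- function(...) {
  defaults <- list(image_shape = c(112L, 112L),
                   frame_times = c(-30, seq(0, 600, by = 30)),
                   r0 = 4, expansion_fold_true = 1.4, t_max_true = 60,
                   closure_rate_true = 0.2, ring_width_true = 2,
                   noise_model = "none", rng_seed = 1L)
  do.call(wound_sim_params, utils::modifyList(defaults, list(...)))
}

# Small expression study for fast tests.
tiny_expr_params <- function(...) {
  defaults <- list(n_genes = 400, n_up = 20, n_down = 30, n_tads = 40,
                   rng_seed = 1L)
  do.call(expr_sim_params, utils::modifyList(defaults, list(...)))
}

# Random connected pixel mask grown by a lazy random walk from the center.
random_connected_mask <- function(n_steps = 40, dim_hw = c(32L, 32L)) {
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  pos <- round(dim_hw / 2)
  m[pos[1], pos[2]] <- TRUE
  for (i in seq_len(n_steps)) {
    step <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
    pos <- pmin(pmax(pos + step, 2), dim_hw - 1)
    m[pos[1], pos[2]] <- TRUE
  }
  m
}

# Brute-force Feret oracle: max pairwise distance over all boundary pixels.
feret_brute_force <- function(mask, pixel_size = 1) {
  b <- which(woundquant:::mask_boundary(mask), arr.ind = TRUE)
  if (nrow(b) == 1) return(0)
  d2 <- outer(b[, 1], b[, 1], "-")^2 + outer(b[, 2], b[, 2], "-")^2
  sqrt(max(d2)) * pixel_size
}

# Brute-force Benjamini-Hochberg oracle: largest k with p_(k) <= k q / m.
bh_reject_brute_force <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rejected <- rep(FALSE, m)
  if (is.finite(k)) rejected[o[seq_len(k)]] <- TRUE
  rejected
}
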