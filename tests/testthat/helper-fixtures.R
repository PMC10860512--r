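# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately use the most naive formulation available (double
# loops, vote counting, textbook sums of squares) so they stay independent
# of the implementation they check.

# Small fast domain spec for training-heavy tests (32 px slices).
tiny_spec <- function(name = "tiny", ...) {
  domain_spec(name = name, image_size = 32L, n_slices_range = c(6L, 8L),
              pixel_spacing_mm = 2.5, slice_thickness_mm = 3,
              tumour_radius_range_mm = c(6, 10), ...)
}

tiny_net <- function(input_size = 32L, depth = 2L, base_channels = 4L, ...) {
  network_config(input_size = input_size, depth = depth,
                 base_channels = base_channels, ...)
}

tiny_train_cfg <- function(epochs_max = 3L, learning_rate = 1e-3, ...) {
  train_config(epochs_max = epochs_max, batch_size = 6L,
               learning_rate = learning_rate, val_fraction = 0.2,
               early_stop_patience = 10L, ...)
}

random_mask <- function(dims, p = 0.3) {
  array(stats::rbinom(prod(dims), 1L, p), dims)
}

# Brute-force confusion counts: explicit loop over every voxel.
oracle_confusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; r <- ref[i] != 0
    if (p && r) tp <- tp + 1L
    else if (p && !r) fp <- fp + 1L
    else if (!p && r) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force consensus: per-voxel vote counting with explicit loops.
oracle_consensus_region <- function(masks, k) {
  d <- dim(masks[[1]])
  out <- array(0L, d)
  for (i in seq_along(out)) {
    votes <- 0L
    for (m in masks) if (m[i] != 0) votes <- votes + 1L
    if (votes >= k) out[i] <- 1L
  }
  out
}

# Textbook one-way ANOVA from sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values); k <- nlevels(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  msb <- ss_between / (k - 1)
  msw <- ss_within / (N - k)
  f <- msb / msw
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Textbook Tukey HSD via the studentized range distribution.
oracle_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values); k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  msw <- ss_within / (N - k)
  lv <- levels(groups)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[j] - means[i]) / se
    out[[paste(lv[j], lv[i], sep = "-")]] <-
      unname(stats::ptukey(q, k, N - k, lower.tail = FALSE))
  }
  unlist(out)
}

# A small trained-from-scratch slice problem reused by training tests.
single_slice_fixture <- function(seed = 11L) {
  s <- generate_subject(tiny_spec(), seed)
  v <- window_normalize(s$volume)
  sl <- to_slices(v, s$truth_mask, include_empty = FALSE)
  i <- which.max(sl$mask_voxels)
  n <- nrow(sl$image[[i]])
  list(x = array(sl$image[[i]], c(n, n, 1L, 1L)),
       y = array(sl$mask[[i]], c(n, n, 1L, 1L)))
}
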