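# Geometric evaluation of segmentations: voxel confusion counts, Dice /
# precision / recall, pairwise inter-observer agreement, model-vs-observer
# comparison, and consensus-region recall.
#
# Metrics are volume-level per subject (3D voxel counts over the whole
# restacked prediction). Degenerate conventions: both masks empty -> all
# metrics 1 with a degenerate flag; prediction empty against a non-empty
# reference -> dsc = 0, recall = 0, precision undefined (NA, flagged).

#' Voxelwise confusion counts between two masks
#'
#' @param pred,ref Binary arrays on the same grid.
#' @return A named list `tp`, `fp`, `fn`, `tn` (class `gtv_confusion`);
#'   counts always sum to the grid size.
#' @export
confusion <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("grid mismatch")
  p <- pred != 0; r <- ref != 0
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(p) - tp - fp - fn),
            class = "gtv_confusion")
}

#' Dice similarity coefficient from confusion counts
#' @param c A `gtv_confusion`.
#' @return `2tp / (2tp + fp + fn)`; 1 when both masks are empty.
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) 1 else 2 * c$tp / den
}

#' Precision (positive predictive value) from confusion counts
#' @param c A `gtv_confusion`.
#' @return `tp / (tp + fp)`; 1 when both masks are empty, `NA` when only
#'   the prediction is empty (undefined; excluded from aggregation).
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) { if (c$fn == 0) 1 else NA_real_ }
  else c$tp / (c$tp + c$fp)
}

#' Recall (sensitivity) from confusion counts
#' @param c A `gtv_confusion`.
#' @return `tp / (tp + fn)`; 1 when the reference is empty and the
#'   prediction is too, `NA` when only the reference is empty.
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) { if (c$fp == 0) 1 else NA_real_ }
  else c$tp / (c$tp + c$fn)
}

# One tidy metric record for a (predictor, reference) mask pair.
metric_record <- function(pred, ref, subject_id, predictor, reference) {
  cc <- confusion(pred, ref)
  tibble::tibble(subject_id = subject_id, predictor = predictor,
                 reference = reference,
                 dsc = dsc(cc), precision = precision(cc),
                 recall = recall(cc),
                 ref_voxels = cc$tp + cc$fn,
                 degenerate = (cc$tp + cc$fp == 0) || (cc$tp + cc$fn == 0))
}

#' Pairwise inter-observer Dice agreement
#'
#' One record per unordered observer pair (`K` observers give
#' `K(K-1)/2` records; with the 5-observer design, 10).
#'
#' @param masks List of `K >= 2` binary masks on a shared grid.
#' @param subject_id Label carried into every record.
#' @return Tibble `subject_id`, `predictor`, `reference`, `dsc`.
#' @export
pairwise_observer_dsc <- function(masks, subject_id = "subject") {
  K <- length(masks)
  if (K < 2) stop("need at least two observers")
  rows <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    if (!identical(dim(masks[[i]]), dim(masks[[j]]))) stop("grid mismatch")
    cc <- confusion(masks[[i]], masks[[j]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = subject_id,
      predictor = paste0("obs", i), reference = paste0("obs", j),
      dsc = dsc(cc))
  }
  dplyr::bind_rows(rows)
}

#' Compare a model prediction against each observer
#'
#' One record per observer, with the observer mask as reference
#' (5 observers give 5 records).
#'
#' @param pred Binary predicted mask.
#' @param masks List of observer masks on the same grid.
#' @param subject_id,model Labels for the record.
#' @return Tibble of metric records (dsc, precision, recall per observer).
#' @export
model_vs_observers <- function(pred, masks, subject_id = "subject",
                               model = "model") {
  dplyr::bind_rows(lapply(seq_along(masks), function(k) {
    metric_record(pred, masks[[k]], subject_id, model, paste0("obs", k))
  }))
}

#' Consensus regions from multiple observers
#'
#' Votes per voxel; region at level `k` is the set of voxels marked by at
#' least `k` observers ("k or more"), so regions are nested:
#' `region(K) ⊆ ... ⊆ region(1) = union`.
#'
#' @param masks List of `K >= 2` binary masks on a shared grid.
#' @return Object of class `gtv_consensus` with elements `K` and `votes`.
#' @export
consensus_regions <- function(masks) {
  K <- length(masks)
  if (K < 2) stop("need at least two observers")
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("grid mismatch")
  votes <- Reduce(`+`, lapply(masks, function(m) (m != 0) * 1L))
  structure(list(K = K, votes = votes), class = "gtv_consensus")
}

#' Extract the level-k consensus region
#' @param cr A `gtv_consensus`.
#' @param k Agreement level in `1..K`.
#' @return Binary mask array of voxels marked by at least `k` observers.
#' @export
consensus_region <- function(cr, k) {
  stopifnot(inherits(cr, "gtv_consensus"), k >= 1, k <= cr$K)
  array(as.integer(cr$votes >= k), dim(cr$votes))
}

#' Recall of a prediction against each consensus level
#'
#' For level `k` the reference is the region marked by at least `k`
#' observers; recall answers "what share of that region did the model
#' segment". Reported from the strictest level (`K`) down to the union.
#'
#' @param pred Binary predicted mask.
#' @param cr A `gtv_consensus` on the same grid.
#' @param subject_id,model Labels for the records.
#' @return Tibble `level`, `recall`, `region_voxels`, `degenerate`.
#' @export
consensus_recall <- function(pred, cr, subject_id = "subject",
                             model = "model") {
  stopifnot(inherits(cr, "gtv_consensus"))
  if (!identical(dim(pred), dim(cr$votes))) stop("grid mismatch")
  dplyr::bind_rows(lapply(rev(seq_len(cr$K)), function(k) {
    reg <- cr$votes >= k
    nv <- sum(reg)
    tibble::tibble(subject_id = subject_id, model = model, level = k,
                   recall = if (nv == 0) NA_real_ else
                     sum((pred != 0) & reg) / nv,
                   region_voxels = nv, degenerate = nv == 0)
  }))
}

#' Evaluate a model on a cohort against ground truth
#'
#' Predicts every subject volume slice-wise and scores it against the truth
#' mask at volume level.
#'
#' @param model A trained `gtv_model`.
#' @param cohort A `gtv_cohort` (HU volumes; windowing is applied here).
#' @param label Model label for the records.
#' @param threshold Binarization threshold on the sigmoid output.
#' @return Tibble of per-subject metric records.
#' @export
evaluate_model <- function(model, cohort, label = "model", threshold = 0.5) {
  dplyr::bind_rows(lapply(cohort, function(s) {
    v <- window_normalize(s$volume)
    pred <- predict_volume(model, v, threshold = threshold)
    metric_record(pred, s$truth_mask, s$id, label, "truth")
  }))
}
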