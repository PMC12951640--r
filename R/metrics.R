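# ISBI-style evaluation: voxel-wise overlap (DSC, PPV, TPR), lesion-wise
# detection rates over connected components (LTPR, LFPR), cohort lesion
# volume correlation (VC), and the weighted composite
#   Score = DSC/8 + PPV/8 + LTPR/4 + (1 - LFPR)/4 + VC/4.

#' Voxel-wise overlap metrics
#'
#' `DSC = 2|P∩R| / (|P|+|R|)`, `PPV = |P∩R| / |P|`, `TPR = |P∩R| / |R|`.
#' Conventions for empty masks: both empty gives (1, 1, 1); empty prediction
#' against a nonempty reference gives (0, 0, 0); a nonempty prediction
#' against an empty reference gives (0, 0, 0).
#'
#' @param pred,ref binary 3D masks on one grid.
#' @return named numeric vector `c(dsc, ppv, tpr)`.
#' @export
voxel_metrics <- function(pred, ref) {
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  stopifnot(identical(dim(pred), dim(ref)))
  p <- sum(pred); r <- sum(ref); tp <- sum(pred & ref)
  if (p == 0 && r == 0) return(c(dsc = 1, ppv = 1, tpr = 1))
  c(dsc = if (p + r > 0) 2 * tp / (p + r) else 1,
    ppv = if (p > 0) tp / p else 0,
    tpr = if (r > 0) tp / r else 0)
}

#' Lesion-wise detection metrics
#'
#' Lesions are connected components (26-connectivity by default). A
#' reference lesion counts as detected when it shares at least one voxel
#' with the prediction; a predicted lesion counts as false when it overlaps
#' no reference voxel. `LTPR = detected / n_ref_lesions`;
#' `LFPR = false / n_pred_lesions`. Conventions: with no reference lesions
#' `LTPR = 1`; with no predicted lesions `LFPR = 0`.
#'
#' @param pred,ref binary 3D masks.
#' @param connectivity component connectivity (6, 18 or 26).
#' @return named numeric vector `c(ltpr, lfpr)`.
#' @export
lesion_metrics <- function(pred, ref, connectivity = 26L) {
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  stopifnot(identical(dim(pred), dim(ref)))
  lr <- label_components(ref, connectivity)
  lp <- label_components(pred, connectivity)
  nr <- max(lr); np <- max(lp)
  detected <- if (nr > 0) length(setdiff(unique(lr[pred == 1L]), 0L)) else 0L
  truepred <- if (np > 0) length(setdiff(unique(lp[ref == 1L]), 0L)) else 0L
  c(ltpr = if (nr > 0) detected / nr else 1,
    lfpr = if (np > 0) (np - truepred) / np else 0)
}

#' Cohort lesion-volume correlation
#'
#' Pearson correlation between predicted and reference total lesion volumes
#' across a cohort of prediction/reference pairs.
#'
#' @param pairs list of `list(pred, ref)` binary mask pairs.
#' @return Pearson r, or `NA` when undefined (fewer than 2 pairs or
#'   zero-variance volumes).
#' @export
volume_correlation <- function(pairs) {
  if (length(pairs) < 2L) return(NA_real_)
  pv <- vapply(pairs, function(p) sum(.as_mask(p[[1L]])), numeric(1L))
  rv <- vapply(pairs, function(p) sum(.as_mask(p[[2L]])), numeric(1L))
  if (sd(pv) == 0 || sd(rv) == 0) return(NA_real_)
  cor(pv, rv)
}

#' Metric report for one prediction/reference pair
#'
#' @param pred,ref binary 3D masks.
#' @param vc cohort volume correlation, if available (scalar or `NA`).
#' @param connectivity lesion-component connectivity.
#' @return object of class `metric_report`: a named list with `dsc`, `ppv`,
#'   `tpr`, `ltpr`, `lfpr`, `vc` and, when `vc` is defined, `score`.
#' @export
metric_report <- function(pred, ref, vc = NA_real_, connectivity = 26L) {
  vm <- voxel_metrics(pred, ref)
  lm <- lesion_metrics(pred, ref, connectivity)
  rep_ <- list(dsc = unname(vm["dsc"]), ppv = unname(vm["ppv"]),
               tpr = unname(vm["tpr"]), ltpr = unname(lm["ltpr"]),
               lfpr = unname(lm["lfpr"]), vc = vc)
  rep_$score <- if (is.na(vc)) NA_real_ else lesion_score(rep_)
  class(rep_) <- "metric_report"
  rep_
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report DSC=%.3f PPV=%.3f TPR=%.3f LTPR=%.3f LFPR=%.3f VC=%s Score=%s>\n",
    x$dsc, x$ppv, x$tpr, x$ltpr, x$lfpr,
    ifelse(is.na(x$vc), "NA", sprintf("%.3f", x$vc)),
    ifelse(is.na(x$score), "NA", sprintf("%.3f", x$score))))
  invisible(x)
}

#' Weighted composite segmentation score
#'
#' `Score = DSC/8 + PPV/8 + LTPR/4 + (1 - LFPR)/4 + VC/4`. With perfect
#' metrics (DSC = PPV = LTPR = VC = 1, LFPR = 0) the score is 1.
#'
#' @param report a [metric_report()] or a named list with fields `dsc`,
#'   `ppv`, `ltpr`, `lfpr`, `vc`.
#' @return the score (scale `[0, 1]`; multiply by 100 for the percent
#'   display convention).
#' @export
lesion_score <- function(report) {
  need <- c("dsc", "ppv", "ltpr", "lfpr", "vc")
  vals <- unlist(report[need])
  if (length(vals) != 5L || any(is.na(vals)))
    stop("score requires dsc, ppv, ltpr, lfpr and vc to be defined")
  unname(vals["dsc"] / 8 + vals["ppv"] / 8 + vals["ltpr"] / 4 +
           (1 - vals["lfpr"]) / 4 + vals["vc"] / 4)
}

#' Evaluate a prediction against one or two raters
#'
#' Computes a [metric_report()] against each reference delineation and
#' averages the components, mirroring challenge protocols that score against
#' two independent raters.
#'
#' @param pred binary prediction mask.
#' @param rater_masks list of 1 or 2 binary reference masks.
#' @param vc cohort volume correlation(s): scalar or one per rater.
#' @param connectivity lesion-component connectivity.
#' @return the averaged `metric_report`.
#' @export
evaluate_against_raters <- function(pred, rater_masks, vc = NA_real_,
                                    connectivity = 26L) {
  stopifnot(is.list(rater_masks), length(rater_masks) >= 1L)
  vc <- rep_len(vc, length(rater_masks))
  reps <- mapply(function(rm, v) metric_report(pred, rm, v, connectivity),
                 rater_masks, vc, SIMPLIFY = FALSE)
  avg <- lapply(c("dsc", "ppv", "tpr", "ltpr", "lfpr", "vc", "score"),
                function(f) mean(vapply(reps, function(r)
                  as.numeric(r[[f]]), numeric(1L))))
  names(avg) <- c("dsc", "ppv", "tpr", "ltpr", "lfpr", "vc", "score")
  class(avg) <- "metric_report"
  avg
}

#' Evaluate a cohort of predictions
#'
#' Per-subject reports against each subject's reference(s), with the cohort
#' volume correlation (against the first rater) folded into every report's
#' score.
#'
#' @param preds list of binary prediction masks.
#' @param refs list of references; each element a mask or a list of 1-2
#'   rater masks.
#' @param connectivity lesion-component connectivity.
#' @return list with `subjects` (list of `metric_report`), `vc`, and `mean`
#'   (component-wise cohort means).
#' @export
evaluate_cohort <- function(preds, refs, connectivity = 26L) {
  stopifnot(length(preds) == length(refs), length(preds) >= 1L)
  refs <- lapply(refs, function(r) if (is.list(r)) r else list(r))
  vc <- volume_correlation(mapply(function(p, r) list(p, r[[1L]]),
                                  preds, refs, SIMPLIFY = FALSE))
  subjects <- mapply(function(p, r)
    evaluate_against_raters(p, r, vc = vc, connectivity = connectivity),
    preds, refs, SIMPLIFY = FALSE)
  fields <- c("dsc", "ppv", "tpr", "ltpr", "lfpr", "score")
  mu <- lapply(fields, function(f)
    mean(vapply(subjects, function(s) as.numeric(s[[f]]), numeric(1L))))
  names(mu) <- fields
  list(subjects = subjects, vc = vc, mean = mu)
}
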