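test_that("voxel metrics match hand counts and conventions", {
  d <- c(12, 12, 12)
  # two 6-voxel cuboids overlapping in 3 voxels: DSC = PPV = TPR = 0.5
  p <- cube_mask(d, c(1, 1, 1), c(6, 1, 1))
  r <- cube_mask(d, c(4, 1, 1), c(9, 1, 1))
  expect_equal(voxel_metrics(p, r), c(dsc = 0.5, ppv = 0.5, tpr = 0.5))
  # identical nonempty masks
  expect_equal(voxel_metrics(r, r), c(dsc = 1, ppv = 1, tpr = 1))
  # disjoint nonempty masks
  q <- cube_mask(d, c(10, 10, 10), c(12, 12, 12))
  expect_equal(voxel_metrics(p, q), c(dsc = 0, ppv = 0, tpr = 0))
  # empty-mask conventions
  e <- array(0L, d)
  expect_equal(voxel_metrics(e, e), c(dsc = 1, ppv = 1, tpr = 1))
  expect_equal(voxel_metrics(e, r), c(dsc = 0, ppv = 0, tpr = 0))
  expect_error(voxel_metrics(p, random_mask(c(4, 4, 4))))
})

test_that("DSC is the harmonic mean of PPV and TPR", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_mask(c(10, 10, 10), runif(1, 0.1, 0.6))
    r <- random_mask(c(10, 10, 10), runif(1, 0.1, 0.6))
    vm <- voxel_metrics(p, r)
    if (vm["ppv"] + vm["tpr"] > 0)
      expect_equal(unname(vm["dsc"]),
                   2 * vm[["ppv"]] * vm[["tpr"]] / (vm[["ppv"]] + vm[["tpr"]]))
  }
})

test_that("lesion-wise rates count connected components with one-voxel overlap detection", {
  d <- c(20, 20, 20)
  ref <- cube_mask(d, c(1, 1, 1), c(3, 3, 3)) |
    cube_mask(d, c(10, 10, 10), c(12, 12, 12)) |
    cube_mask(d, c(17, 17, 17), c(19, 19, 19))
  ref <- array(as.integer(ref), d)
  expect_equal(lesion_metrics(ref, ref), c(ltpr = 1, lfpr = 0))
  # cover 1 of 2 lesions, plus one spurious blob: LTPR = LFPR = 0.5
  ref2 <- cube_mask(d, c(1, 1, 1), c(3, 3, 3)) |
    cube_mask(d, c(10, 10, 10), c(12, 12, 12))
  ref2 <- array(as.integer(ref2), d)
  pred <- cube_mask(d, c(1, 1, 1), c(2, 2, 2)) |    # hits lesion 1 only
    cube_mask(d, c(17, 17, 17), c(19, 19, 19))      # spurious
  pred <- array(as.integer(pred), d)
  expect_equal(lesion_metrics(pred, ref2), c(ltpr = 0.5, lfpr = 0.5))
  # empty prediction: nothing detected, nothing falsely predicted
  expect_equal(lesion_metrics(array(0L, d), ref2), c(ltpr = 0, lfpr = 0))
  # one shared voxel suffices for detection
  touch <- cube_mask(d, c(3, 3, 3), c(5, 5, 5))
  expect_equal(lesion_metrics(touch, ref2)[["ltpr"]], 0.5)
  # a diagonal-only neighbor is one lesion at 26- but two at 6-connectivity
  dm <- array(0L, d); dm[5, 5, 5] <- 1L; dm[6, 6, 6] <- 1L
  expect_equal(lesion_metrics(dm, dm)[["ltpr"]], 1)
  expect_equal(lesion_metrics(array(0L, d), dm, connectivity = 6)[["ltpr"]], 0)
})

test_that("volume correlation is Pearson r over cohort lesion volumes", {
  d <- c(8, 8, 8)
  vols <- c(5, 11, 23, 40)
  mk <- function(n) { m <- array(0L, d); m[seq_len(n)] <- 1L; m }
  pairs_id <- lapply(vols, function(v) list(mk(v), mk(v)))
  expect_equal(volume_correlation(pairs_id), 1)
  pairs_2x <- lapply(vols, function(v) list(mk(2 * v), mk(v)))
  expect_equal(volume_correlation(pairs_2x), 1)  # scale-invariance
  # hand-listed pairs against the covariance formula
  pv <- c(5, 9, 23, 31); rv <- c(7, 11, 19, 37)
  pairs <- mapply(function(a, b) list(mk(a), mk(b)), pv, rv, SIMPLIFY = FALSE)
  r_oracle <- sum((pv - mean(pv)) * (rv - mean(rv))) /
    sqrt(sum((pv - mean(pv))^2) * sum((rv - mean(rv))^2))
  expect_equal(volume_correlation(pairs), r_oracle)
  expect_true(is.na(volume_correlation(pairs[1])))
  expect_true(is.na(volume_correlation(lapply(1:3, function(i)
    list(mk(4), mk(i))))))
})

test_that("the composite score applies weights (1/8, 1/8, 1/4, 1/4, 1/4)", {
  perfect <- list(dsc = 1, ppv = 1, ltpr = 1, lfpr = 0, vc = 1)
  expect_equal(lesion_score(perfect), 1)
  expect_equal(lesion_score(list(dsc = 0.6, ppv = 0.8, ltpr = 0.5,
                                 lfpr = 0.2, vc = 0.9)), 0.725)
  set.seed(22)
  for (i in 1:25) {
    rep_ <- list(dsc = runif(1), ppv = runif(1), ltpr = runif(1),
                 lfpr = runif(1), vc = runif(1, -1, 1))
    expect_equal(lesion_score(rep_),
                 rep_$dsc / 8 + rep_$ppv / 8 + rep_$ltpr / 4 +
                   (1 - rep_$lfpr) / 4 + rep_$vc / 4)
  }
  expect_error(lesion_score(list(dsc = 1, ppv = 1, ltpr = 1, lfpr = 0)),
               "requires")
  # monotonicity: raising any positive component raises the score
  base <- list(dsc = 0.5, ppv = 0.5, ltpr = 0.5, lfpr = 0.5, vc = 0.5)
  for (f in c("dsc", "ppv", "ltpr", "vc")) {
    up <- base; up[[f]] <- 0.7
    expect_gt(lesion_score(up), lesion_score(base))
  }
  worse <- base; worse$lfpr <- 0.7
  expect_lt(lesion_score(worse), lesion_score(base))
})

test_that("two-rater evaluation averages the per-rater reports exactly", {
  set.seed(23)
  d <- c(10, 10, 10)
  pred <- random_mask(d, 0.3)
  r1 <- random_mask(d, 0.3); r2 <- random_mask(d, 0.3)
  avg <- evaluate_against_raters(pred, list(r1, r2), vc = 0.8)
  rep1 <- metric_report(pred, r1, vc = 0.8)
  rep2 <- metric_report(pred, r2, vc = 0.8)
  for (f in c("dsc", "ppv", "tpr", "ltpr", "lfpr", "score"))
    expect_equal(avg[[f]], (rep1[[f]] + rep2[[f]]) / 2)
  # identical raters: average equals the single-rater report
  same <- evaluate_against_raters(pred, list(r1, r1), vc = 0.8)
  for (f in c("dsc", "ppv", "tpr", "ltpr", "lfpr", "score"))
    expect_equal(same[[f]], rep1[[f]])
  # prediction equals rater 1, disjoint from rater 2: DSC averages to 0.5
  a <- cube_mask(d, c(1, 1, 1), c(3, 3, 3))
  b <- cube_mask(d, c(7, 7, 7), c(9, 9, 9))
  expect_equal(evaluate_against_raters(a, list(a, b))$dsc, 0.5)
})

test_that("cohort evaluation folds the cohort VC into every subject score", {
  set.seed(24)
  d <- c(8, 8, 8)
  preds <- lapply(c(0.2, 0.3, 0.4), function(p) random_mask(d, p))
  refs <- lapply(c(0.25, 0.3, 0.35), function(p) random_mask(d, p))
  ev <- evaluate_cohort(preds, refs)
  expect_length(ev$subjects, 3L)
  expect_equal(ev$vc, volume_correlation(mapply(list, preds, refs,
                                                SIMPLIFY = FALSE)))
  expect_equal(ev$subjects[[1]]$vc, ev$vc)
  expect_equal(ev$mean$dsc,
               mean(vapply(ev$subjects, function(s) s$dsc, numeric(1))))
})
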