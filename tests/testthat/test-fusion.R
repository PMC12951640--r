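test_that("the confidence map is the per-voxel vote count", {
  set.seed(11)
  d <- c(8, 8, 8)
  masks <- replicate(24, random_mask(d, 0.3), simplify = FALSE)
  cm <- confidence_map(masks)
  expect_s3_class(cm, "confidence_map")
  expect_equal(cm$n_models, 24L)
  expect_true(is.integer(cm$C))
  expect_true(all(cm$C >= 0L & cm$C <= 24L))
  # brute-force per-voxel popcount oracle
  pop <- array(0L, d)
  for (v in seq_len(prod(d)))
    pop[v] <- sum(vapply(masks, function(m) m[v], integer(1)))
  expect_identical(cm$C, pop)
  # identical and empty inputs
  M <- random_mask(d, 0.4)
  expect_identical(confidence_map(replicate(24, M, simplify = FALSE))$C, 24L * M)
  expect_true(all(confidence_map(replicate(24, M * 0L, simplify = FALSE))$C == 0L))
  # contract violations
  expect_error(confidence_map(list(M, M * 2L)), "binary")
  expect_error(confidence_map(list(M, random_mask(c(4, 4, 4)))), "grid")
})

test_that("thresholding is strict and anti-monotone in tau", {
  set.seed(12)
  cm <- confidence_map(replicate(24, random_mask(c(6, 6, 6), 0.4),
                                 simplify = FALSE))
  expect_true(all(threshold_mask(cm, 24L) == 0L))
  prev <- threshold_mask(cm, 0L)
  expect_identical(prev, array(as.integer(cm$C > 0L), dim = dim(cm$C)))
  for (tau in 1:24) {
    cur <- threshold_mask(cm, tau)
    expect_true(all(cur <= prev))  # nested masks
    expect_identical(cur, array(as.integer(cm$C > tau), dim = dim(cm$C)))
    prev <- cur
  }
  expect_error(threshold_mask(cm, 25L), "n_models")
})

test_that("connected growth equals the flood-fill oracles bit-exactly on random instances", {
  set.seed(13)
  for (i in seq_len(500)) {
    m2 <- random_mask(c(16, 16, 16), runif(1, 0.1, 0.5))
    m1 <- array(as.integer(m2 & random_mask(c(16, 16, 16), 0.15)), dim = dim(m2))
    got <- connected_growth(m1, m2)
    expect_identical(got, oracle_growth_fixpoint(m1, m2))
    if (i <= 20) expect_identical(got, oracle_growth_bfs(m1, m2))
  }
})

test_that("connected growth honors its contract and edge cases", {
  set.seed(14)
  m2 <- random_mask(c(10, 10, 10), 0.4)
  empty <- m2 * 0L
  expect_identical(connected_growth(empty, m2), empty)  # undetected never appears
  expect_identical(connected_growth(m2, m2), m2)        # tau1 == tau2 reduction
  bad <- m2 * 0L; bad[1, 1, 1] <- 1L; m2[1, 1, 1] <- 0L
  expect_error(connected_growth(bad, m2), "subset")
})

test_that("fusion satisfies the sandwich and composes from its primitives", {
  set.seed(15)
  masks <- replicate(24, random_mask(c(12, 12, 12), 0.35), simplify = FALSE)
  pars <- fusion_params(16, 7)
  fz <- fuse_masks(masks, pars, return_confidence = TRUE)
  m1 <- threshold_mask(fz$confidence, 16L)
  m2 <- threshold_mask(fz$confidence, 7L)
  expect_identical(fz$mask, connected_growth(m1, m2))  # compositional oracle
  expect_true(all(m1 <= fz$mask) && all(fz$mask <= m2))
  # anti-monotone in both thresholds
  for (p2 in list(fusion_params(17, 7), fusion_params(16, 8))) {
    expect_true(all(fuse_masks(masks, p2) <= fz$mask))
  }
  # idempotence on unanimous input
  M <- random_mask(c(12, 12, 12), 0.4)
  expect_identical(fuse_masks(replicate(24, M, simplify = FALSE), pars), M)
  # permutation invariance
  expect_identical(fuse_masks(rev(masks), pars), fz$mask)
  # all below tau2 -> empty
  lone <- c(list(random_mask(c(6, 6, 6), 0.5)),
            replicate(23, array(0L, c(6, 6, 6)), simplify = FALSE))
  expect_true(all(fuse_masks(lone, pars) == 0L))
  expect_error(fusion_params(7, 16), "tau1 >= tau2")
})

test_that("majority voting is single-threshold fusion at the majority cut", {
  set.seed(16)
  masks <- replicate(24, random_mask(c(10, 10, 10), 0.5), simplify = FALSE)
  expect_identical(majority_vote(masks),
                   fuse_masks(masks, fusion_params(12, 12)))
  # 13 of 24 votes is a strict majority under the default rule
  cm <- confidence_map(masks)
  v13 <- which(cm$C == 13L)
  if (length(v13)) expect_true(all(majority_vote(masks)[v13] == 1L))
  expect_true(all(majority_vote(replicate(5, masks[[1]], simplify = FALSE))
                  == masks[[1]]))
  # the tau1 = tau2 = 13 labeling convention is available as an override
  expect_identical(majority_vote(masks, t = 13L),
                   fuse_masks(masks, fusion_params(13, 13)))
})
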