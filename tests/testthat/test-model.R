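tiny_cfg <- backbone_config(preset = "tiny")

test_that("backbone construction follows the configuration", {
  cfg <- backbone_config()
  expect_equal(cfg$levels, 5L)
  expect_equal(cfg$channels, c(64L, 128L, 256L, 512L, 1024L))
  expect_equal(cfg$in_channels, 12L)
  expect_error(backbone_config(levels = 3, channels = c(8, 8, 16)))
  expect_error(backbone_config(levels = 1, channels = 8))
  set.seed(1)
  m <- build_backbone(tiny_cfg)
  expect_equal(dim(m$layers[["enc2.conv1"]]$w), c(3, 3, 8, 16))
  expect_equal(dim(m$layers[["head"]]$w), c(1, 1, 8, 1))
})

test_that("slice prediction returns probabilities and is deterministic", {
  set.seed(2)
  m <- build_backbone(tiny_cfg)
  slab <- array(rnorm(32 * 32 * 12), dim = c(32, 32, 12))
  p1 <- predict_slice(m, slab)
  expect_equal(dim(p1), c(32, 32))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(predict_slice(m, slab), p1)  # eval determinism
  # degenerate all-zero slab: valid map, no NaN (zero-variance path)
  p0 <- predict_slice(m, array(0, dim = c(32, 32, 12)))
  expect_true(all(is.finite(p0)) && all(p0 >= 0 & p0 <= 1))
  expect_error(predict_slice(m, array(0, dim = c(32, 32, 8))), "channel")
  expect_error(predict_slice(m, slab, combo = 0L), "non-empty")
})

test_that("probabilities stay in range over random slabs and norm modes", {
  set.seed(3)
  for (mode in c("BN", "IN", "CondIN")) {
    m <- build_backbone(backbone_config(preset = "tiny", norm_mode = mode))
    for (i in 1:12) {
      slab <- array(rnorm(16 * 16 * 12, sd = runif(1, 0.1, 30)),
                    dim = c(16, 16, 12))
      p <- predict_slice(m, slab, combo = sample(15, 1))
      expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
    }
  }
})

test_that("IN-trained models predict identically with and without TTIN", {
  set.seed(4)
  m <- build_backbone(backbone_config(preset = "tiny", norm_mode = "IN"))
  slab <- array(rnorm(16 * 16 * 12), dim = c(16, 16, 12))
  expect_equal(predict_slice(m, slab, use_ttin = TRUE),
               predict_slice(m, slab, use_ttin = FALSE))
})

test_that("constant models segment volumes to constant masks regardless of orientation", {
  set.seed(5)
  m <- build_backbone(tiny_cfg)
  vol <- mc_volume(array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4)),
                   present = rep(TRUE, 4))
  m0 <- m; m0$layers$head$w[] <- 0; m0$layers$head$b <- -50
  m1 <- m; m1$layers$head$w[] <- 0; m1$layers$head$b <- 50
  for (d in list_augmentations()[c(1, 7, 10, 16, 19, 24)]) {
    expect_true(all(segment_volume(m0, vol, d) == 0L))
    expect_true(all(segment_volume(m1, vol, d) == 1L))
  }
})

test_that("slice-stacking bookkeeping is orientation-equivariant for a voxel-wise rule", {
  # emulate a model that thresholds the FLAIR channel: applying the rule
  # slice-wise in any augmented orientation and mapping back must equal
  # applying it directly in the original space
  set.seed(6)
  vol <- array(rnorm(10 * 12 * 14), dim = c(10, 12, 14))
  direct <- array(as.integer(vol > 0.3), dim = dim(vol))
  for (d in list_augmentations()) {
    tv <- apply_transform(vol, d)
    stacked <- array(0L, dim = dim(tv))
    for (k in seq_len(dim(tv)[3]))
      stacked[, , k] <- as.integer(tv[, , k] > 0.3)
    expect_identical(invert_transform(stacked, d), direct)
  }
})

test_that("contrast dropout keeps a survivor, is seeded, and covers all 15 combinations", {
  vol <- mc_volume(array(1, dim = c(4, 4, 4, 4)),
                   present = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(contrast_dropout(vol)$present, vol$present)  # survival rule
  full <- mc_volume(array(rnorm(4^3 * 4), dim = c(4, 4, 4, 4)),
                    present = rep(TRUE, 4))
  set.seed(10); a <- contrast_dropout(full)
  set.seed(10); b <- contrast_dropout(full)
  expect_identical(a, b)
  expect_true(all(a$data[, , , !a$present] == 0))
  set.seed(11)
  seen <- integer(0)
  for (i in 1:2000)
    seen <- union(seen, combo_index(mstta:::.sample_surviving(rep(TRUE, 4))))
  expect_setequal(seen, 1:15)
})

test_that("checkpoints round-trip to bit-identical predictions", {
  set.seed(12)
  m <- build_backbone(backbone_config(preset = "tiny", norm_mode = "CondIN"))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  slab <- array(rnorm(16 * 16 * 12), dim = c(16, 16, 12))
  expect_identical(predict_slice(m2, slab, combo = 6L),
                   predict_slice(m, slab, combo = 6L))
})

test_that("backbone gradients agree with numeric differentiation in every norm mode", {
  set.seed(13)
  ns <- asNamespace("mstta")
  for (mode in c("IN", "BN", "CondIN")) {
    cfg <- backbone_config(levels = 2, channels = c(3L, 5L), norm_mode = mode,
                           in_channels = 4L)
    m <- build_backbone(cfg)
    x <- array(rnorm(8 * 8 * 4 * 2), dim = c(8, 8, 4, 2))
    y <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2))
    combos <- c(3L, 15L)
    lossfn <- function(model)
      mean((ns$.backbone_forward(model, x, combos, phase = "train")$out - y)^2)
    fw <- ns$.backbone_forward(m, x, combos, phase = "train")
    gr <- ns$.backbone_backward(m, fw$cache, 2 * (fw$out - y) / length(fw$out))
    for (ln in c("enc1.conv1", "dec1.up", "dec1.norm1", "head")) {
      g <- gr[[ln]]
      fields <- if (!is.null(g$gw)) c(w = "gw", b = "gb")
        else c(gamma = "ggamma", beta = "gbeta")
      for (f in names(fields)) {
        arr <- m$layers[[ln]][[f]]
        for (i in sample(length(arr), min(2, length(arr)))) {
          h <- 1e-5
          mp <- m; mp$layers[[ln]][[f]][i] <- arr[i] + h
          mm <- m; mm$layers[[ln]][[f]][i] <- arr[i] - h
          num <- (lossfn(mp) - lossfn(mm)) / (2 * h)
          expect_equal(g[[fields[[f]]]][i], num, tolerance = 1e-4)
        }
      }
    }
  }
})
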