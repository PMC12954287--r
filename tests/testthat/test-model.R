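# Architecture contracts: weight sharing, axial-only skip connections,
# fusion degeneracy, shape and pairing errors.

test_that("config validation enforces structural constraints", {
  expect_error(mpkb_config(encoder_depth = 1), "encoder_depth")
  expect_error(mpkb_config(folds = 1), "folds")
  expect_error(mpkb_config(lambda_contrastive = -0.1), "lambda")
  expect_error(mpkb_config(in_plane_size = 30), "divisible")
  cfg <- mpkb_config(preset = "paper")
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$folds, 5L)
})

test_that("the three encoder roles share one parameter set", {
  m <- build_model(tiny_cfg(seed = 21))
  set.seed(22)
  img <- array(rnorm(32 * 32), c(32, 32, 1))
  za <- encode_view(m, slice_batch(img, "axial"))
  zs <- encode_view(m, slice_batch(img, "sagittal"))
  zc <- encode_view(m, slice_batch(img, "coronal"))
  expect_identical(za$vectors, zs$vectors)
  expect_identical(za$vectors, zc$vectors)
  expect_equal(ncol(za$vectors), m$cfg$latent_dim)
})

test_that("initialization is deterministic under a fixed seed", {
  m1 <- build_model(tiny_cfg(seed = 33))
  m2 <- build_model(tiny_cfg(seed = 33))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_cfg(seed = 34))
  expect_false(identical(m1$params, m3$params))
})

test_that("encoder latents are finite, per-slice and deterministic", {
  m <- build_model(tiny_cfg(seed = 5))
  zero <- encode_view(m, slice_batch(array(0, c(32, 32, 1)), "axial"))
  expect_true(all(is.finite(zero$vectors)))
  set.seed(6)
  one <- array(rnorm(32 * 32), c(32, 32))
  batch <- slice_batch(array(c(one, one, 2 * one), c(32, 32, 3)), "axial")
  z <- encode_view(m, batch)
  expect_equal(nrow(z$vectors), 3)
  expect_identical(z$vectors[1, ], z$vectors[2, ])  # duplicated slice
  expect_error(encode_view(m, slice_batch(array(0, c(16, 16, 1)), "axial")),
               "in-plane")
})

test_that("fusion is the arithmetic mean with axial required", {
  za <- latent_features(matrix(1:6, 2), "axial")
  zs <- latent_features(matrix(rep(2, 6), 2), "sagittal")
  zc <- latent_features(matrix(rep(2, 6), 2), "coronal")
  expect_equal(fuse_latents(list(za)), za$vectors)          # mean of one
  same <- fuse_latents(list(za, latent_features(za$vectors, "sagittal"),
                            latent_features(za$vectors, "coronal")))
  expect_equal(same, za$vectors)                            # idempotence
  # symmetry: {ax, sag} and {ax, cor} with equal vectors fuse identically
  expect_equal(fuse_latents(list(za, zs)), fuse_latents(list(za, zc)))
  expect_error(fuse_latents(list(zs, zc)), "axial")
})

test_that("skip activations are insensitive to non-axial inputs", {
  m <- build_model(tiny_cfg(seed = 41))
  set.seed(42)
  ax <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  sag1 <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  sag2 <- sag1 + array(rnorm(32 * 32, 0, 0.5), c(32, 32, 1, 1))
  enc_a1 <- mpkbseg:::enc_forward(m$params, m$cfg, ax)
  enc_a2 <- mpkbseg:::enc_forward(m$params, m$cfg, ax)
  # the axial pass (whose a2 tensors feed the decoder skips) is a function
  # of the axial input only: finite-difference sensitivity to the sagittal
  # input is exactly zero
  for (l in seq_along(enc_a1$levels)) {
    expect_identical(enc_a1$levels[[l]]$a2, enc_a2$levels[[l]]$a2)
  }
  # while the fused latent does change with the sagittal input
  zs1 <- mpkbseg:::enc_forward(m$params, m$cfg, sag1)$z
  zs2 <- mpkbseg:::enc_forward(m$params, m$cfg, sag2)$z
  f1 <- fuse_latents(list(latent_features(enc_a1$z, "axial"),
                          latent_features(zs1, "sagittal")))
  f2 <- fuse_latents(list(latent_features(enc_a1$z, "axial"),
                          latent_features(zs2, "sagittal")))
  expect_gt(max(abs(f1 - f2)), 0)
  # and context changes the decoder output only through the bottleneck
  p1 <- mpkbseg:::dec_forward(m$params, m$cfg, enc_a1, f1)$probs
  p2 <- mpkbseg:::dec_forward(m$params, m$cfg, enc_a1, f2)$probs
  expect_gt(max(abs(p1 - p2)), 0)
})

test_that("forward_segment outputs probabilities shaped like its input", {
  m <- build_model(tiny_cfg(seed = 51))
  set.seed(52)
  ax <- slice_batch(array(rnorm(32 * 32 * 2), c(32, 32, 2)), "axial",
                    exam_ids = c("e1", "e1"))
  p <- forward_segment(m, ax)
  expect_equal(dim(p), c(32L, 32L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  # axial-only equals a full call whose context is withheld: fusion of one
  sag <- slice_batch(array(rnorm(32 * 32 * 2), c(32, 32, 2)), "sagittal",
                     exam_ids = c("e1", "e1"))
  p_full <- forward_segment(m, ax, context = list(sag))
  expect_false(identical(p, p_full))   # context does alter the bottleneck
  p_again <- forward_segment(m, ax)
  expect_identical(p, p_again)
  # pairing error when context exam ids disagree
  bad <- slice_batch(array(rnorm(32 * 32 * 2), c(32, 32, 2)), "sagittal",
                     exam_ids = c("e2", "e2"))
  expect_error(forward_segment(m, ax, context = list(bad)), "pairing")
})
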