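# Shared fixtures: a desk-scale tiny phantom protocol (32 mm field of view,
# 1 mm fine grid, 1 x 4 mm views -> 32 x 32 x 8 stacks) and cached small
# trained models so several tests can reuse one fit.

tiny_base_spec <- function() {
  phantom_spec(view_spacings = list(axial = c(1, 4), sagittal = c(1, 4),
                                    coronal = c(1, 4)),
               fine_spacing = 1.0, extent_mm = 32)
}

tiny_variability <- function() {
  list(semi_axes = c(8, 12), deform_amplitude = c(0, 0.1),
       noise_sd = c(0.03, 0.08), bias_amplitude = c(0, 0.15),
       center_offset = c(-2, 2))
}

tiny_cohort <- function(n, seed = 42, scenario = "full") {
  make_cohort(n, base_spec = tiny_base_spec(),
              variability = tiny_variability(), scenario = scenario,
              seed = seed)
}

tiny_cfg <- function(...) {
  args <- list(in_plane_size = 32L, base_channels = 4L, latent_dim = 8L,
               epochs = 2L, folds = 2L)
  override <- list(...)
  args[names(override)] <- override
  do.call(mpkb_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small trained KB ensemble on a tiny cohort, reused across test files
tiny_trained <- function() {
  cache_fixture("tiny_trained", {
    cohort <- tiny_cohort(8, seed = 42)
    fit <- mpkb_fit(lapply(cohort, `[[`, "exam"), tiny_cfg(epochs = 8L),
                    seed = 7)
    list(cohort = cohort, fit = fit)
  })
}

random_blob_mask <- function(n = 16, seed) {
  set.seed(seed)
  ctr <- runif(3, 5, n - 4)
  r <- runif(1, 3, 6)
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
  m <- array(as.numeric(d2 <= r^2), c(n, n, n))
  # sprinkle a few random voxels so surfaces are irregular
  flips <- sample(n^3, 8)
  m[flips] <- 1 - m[flips]
  m
}
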