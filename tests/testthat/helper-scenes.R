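# Shared small synthetic scenes, built once per test run.

# A small circular cell (radius 4 um in a 12 um arena) with particles held
# at fixed depths; noiseless and noisy renderings.
scene_cfg <- function(...) {
  args <- utils::modifyList(
    list(mode = "confocal2d", arena_um = c(12, 12), cell_center_um = c(6, 6),
         cell_radii_um = c(4, 4), drift_nm_per_frame = 0, n_frames = 3,
         seed = 101),
    list(...))
  do.call(simulation_config, args)
}

.static_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scene_cfg()
      depths <- c(-400, -150, 0, 150, 300, 600, 2000)
      log <- static_depth_log(cfg, depths)
      cache <<- list(cfg = cfg, depths = depths, log = log,
                     clean = render_movie(log, cfg, noise = FALSE),
                     noisy = render_movie(log, cfg))
    }
    cache
  }
})

# pixel-integrated Gaussian spot by direct Riemann integration of the
# 2-d normal density over each pixel: an oracle independent of the
# renderer's pnorm-difference formula
oracle_spot_image <- function(nr, nc, x0_px, y0_px, sigma_px, photons,
                              nsub = 40) {
  img <- matrix(0, nr, nc)
  g <- function(u, mu) stats::dnorm(u, mu, sigma_px)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    xs <- seq(c - 1 - 0.5, c - 1 + 0.5, length.out = nsub)
    ys <- seq(r - 1 - 0.5, r - 1 + 0.5, length.out = nsub)
    img[r, c] <- photons * mean(g(xs, x0_px)) * mean(g(ys, y0_px))
  }
  img
}
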