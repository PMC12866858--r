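# Fixtures built in code at test time.

# A small MSI dataset with known content; TIC per spectrum is recorded at
# generation time for the read-back check.
make_msi_fixture <- function(seed = 42, grid = c(3L, 4L)) {
  set.seed(seed)
  spectra <- list()
  tics <- numeric(0)
  i <- 0L
  for (r in 0:(grid[1] - 1L)) {
    for (c in 0:(grid[2] - 1L)) {
      i <- i + 1L
      n <- sample(2:6, 1)
      mz <- sort(runif(n, 100, 900))
      inten <- runif(n, 0, 1000)
      spectra[[i]] <- list(coord = c(r, c), mz = mz, intensity = inten)
      tics <- c(tics, sum(inten))
    }
  }
  list(ds = msi_dataset(spectra, grid_shape = grid, pixel_pitch_um = 20),
       tics = tics)
}

# A small phantom training setup shared by trainer/cli tests.
small_phantom_setup <- function(seed = 1, hr = c(32L, 32L), mag = 4L,
                                channels = c(8L, 6L, 1L)) {
  tri <- generate_phantom(phantom_spec(hr_shape = hr, magnification = mag,
                                       n_cells = 12L, seed = seed))
  pair <- validate_registration(tri$microscopy, tri$ion_lr, mag)
  net <- build_network(network_spec(block_channels = channels), seed = seed)
  list(tri = tri, pair = pair, net = net,
       truth = minmax_normalize(tri$ion_truth_hr))
}
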