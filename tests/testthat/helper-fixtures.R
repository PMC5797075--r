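# shared fixtures: cheap MC settings, reference stacks, and a lazily
# computed fast-preset simulation study reused by the acceptance tests

quick_mc <- function(n = 1e4, seed = 1L) mc_settings(n_photons = n, seed = seed)

# single clear absorbing slab, matched indices (Beer-Lambert oracle)
beer_stack <- function(mu_a = 1, d_cm = 1)
  layer_stack(list(optical_layer(1, mu_a, 0, 0, d_cm)))

# lossless glass-like slab in air (Fresnel multiple-reflection oracle)
glass_stack <- function(n = 1.5, d_cm = 0.1)
  layer_stack(list(optical_layer(n, 0, 0, 0, d_cm)))

# small multipath spectra built from an exact exponential decay
exp_spectra <- function(k = 0.5, I0 = 10, wl = c(700, 800, 900),
                        pl = c(4.2, 3.8, 3.4, 3.0)) {
  I <- outer(pl, seq_along(wl), function(l, j) I0 * exp(-k * j * l / 2))
  multipath_spectra(wl, pl, I)
}

.study_cache <- new.env(parent = emptyenv())

# fast-preset simulation study, computed once per test run
fast_study <- function() {
  if (is.null(.study_cache$report))
    .study_cache$report <- run_simulation_study(sim_study_config("fast"),
                                                seed = 20L)
  .study_cache$report
}

dc_of <- function(report, pair_, type_) {
  with(report$dc, dc[pair == pair_ & type == type_])
}
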