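## shared fixtures: built once per test run; the calibrated model is expensive
## enough to cache
default_morph <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_reduced_l5pc()
    m
  }
})

default_model <- local({
  mod <- NULL
  function() {
    if (is.null(mod)) mod <<- attach_biophysics(discretize(default_morph()))
    mod
  }
})

## tiny passive-only model for solver oracles: the trunk is the test cable
## (no taper); every appendage is a thin short stub with negligible load
passive_cable_model <- function(n_comp = 50, length_um = 1000, diam = 2,
                                g_pas = 1e-4, ra = 100, cm = 1) {
  geo <- reduced_geometry(n_basal = 1, basal_length = 5,
                          basal_diam = 0.3, trunk_length = length_um,
                          trunk_diam_base = diam, trunk_diam_tip = diam,
                          n_oblique = 0, n_tuft_primary = 1,
                          tuft_primary_length = 5, tuft_terminal_length = 5,
                          tuft_primary_diam = 0.3,
                          tuft_terminal_diam = 0.3,
                          hotspot_span = c(length_um - 5, length_um),
                          soma_diam = diam, axon_length = 5, axon_diam = 0.3,
                          node_step = length_um / n_comp)
  m <- build_reduced_l5pc(geo)
  cab <- discretize(m, max_seg = length_um / n_comp)
  chans <- lapply(default_channels(), function(ch) {
    ch$density <- c()
    ch
  })
  attach_biophysics(cab, chans,
                    passive_params(cm_soma = cm, cm_dend = cm, g_pas = g_pas,
                                   e_pas = -70, ra = ra),
                    calcium_params())
}
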