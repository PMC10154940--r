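# Synthetic re-traces of the four genital claspers used as the worked
# complexity example (species acronyms MARM, DECA, MSAUT, AIND). The
# original photographic traces are not available as coordinates, so these
# stand-ins are spectrally graded abstractions: each clasper is an ellipse
# carrying high-harmonic ornament whose energy decreases from the
# bifurcated, highly sculptured clasper (MARM) to the smooth simple one
# (AIND). Only the ordering of their scores is a testable property.
synthetic_claspers <- function(n_points = 4096) {
  mk <- function(amps, harms, id) {
    # heavy ornament intentionally exceeds the self-intersection safe bound;
    # even-odd filling handles the resulting micro-loops
    suppressWarnings(make_shape(shape_spec(axes = c(120, 70),
                          perturb = data.frame(harmonic = harms,
                                               amplitude = amps,
                                               phase = c(0.3, 1.1, 2.0)),
                          n_points = n_points),
               source_id = id))
  }
  list(
    MARM = mk(c(8.0, 5.0, 3.0), c(11, 17, 25), "MARM_synthetic"),
    DECA = mk(c(7.0, 4.0, 2.0), c(11, 17, 25), "DECA_synthetic"),
    MSAUT = mk(c(6.0, 3.0, 1.5), c(11, 17, 25), "MSAUT_synthetic"),
    AIND = mk(c(2.5, 1.2, 0.5), c(11, 17, 25), "AIND_synthetic"))
}
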