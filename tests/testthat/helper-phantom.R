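# Small, fast phantom used throughout the unit tests: 64 x 64 grid at
# 1.5 mm/px (96 mm field of view) around a 60 x 30 x 24 mm kidney.
# Any phantom_spec() argument can be overridden.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(64L, 64L), pixel_spacing_mm = 1.5,
         kidney_semi_axes_mm = c(30, 15, 12), cortex_thickness_mm = 5),
    list(...))
  do.call(phantom_spec, args)
}

# Quantified map from a spec in one call.
quantify_phantom <- function(spec, register = FALSE, params = quant_params()) {
  tr <- phantom_truth(spec)
  se <- simulate_asl_series(tr, params)
  list(truth = tr,
       map = quantify(se, tr$t1_map_truth, tr$label_map > 0, params,
                      register = register))
}
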