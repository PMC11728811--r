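# small builders shared across test files

# degenerate model: every factor a point mass, one chemical
point_mass_model <- function(c_ppm = 10, et = 8, ed = 10, ef = 250,
                             at_days = 69408, chem = "xylene") {
  exposure_factor_model(
    concentration = stats::setNames(
      list(dist_spec("point_mass", list(value = c_ppm))), chem),
    et = dist_spec("point_mass", list(value = et)),
    ed = dist_spec("point_mass", list(value = ed)),
    ef = dist_spec("point_mass", list(value = ef)),
    at_days = at_days)
}

single_chem <- function(name = "xylene", mw = 106.17, rfc = 0.1,
                        label = "nervous") {
  stats::setNames(list(chemical_spec(name, mw, rfc = stats::setNames(list(rfc), label))),
                  name)
}

single_grouping <- function(name = "xylene", label = "nervous") {
  stats::setNames(list(toxicity_grouping(label, name)), label)
}

discrete_spec <- function(values, probs = rep(1 / length(values), length(values))) {
  dist_spec("discrete", list(values = values, probs = probs))
}
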