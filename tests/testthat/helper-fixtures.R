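## shared small fixtures, all built in code

tiny_registry <- function() {
  specs <- list(
    assumption("u1", "uniform", list(minimum = 0, maximum = 1)),
    assumption("u2", "uniform", list(minimum = 0, maximum = 1)),
    assumption("t1", "triangular", list(minimum = 1, mode = 2, maximum = 4)))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  structure(specs, class = c("assumption_registry", "list"))
}

## registry of point masses (arbitrarily narrow uniforms) at the base point,
## for degenerate-distribution contracts
degenerate_registry <- function(base = registry_base(default_registry())) {
  specs <- lapply(names(base), function(nm) {
    v <- base[[nm]]
    assumption(nm, "uniform", list(minimum = v * (1 - 1e-9),
                                   maximum = v * (1 + 1e-9)))
  })
  names(specs) <- names(base)
  structure(specs, class = c("assumption_registry", "list"))
}
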