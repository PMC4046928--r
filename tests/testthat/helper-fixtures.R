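# Shared fixtures, built lazily and cached for the whole test run.  The
# "small" geometry (12 um cells, 6 um gap, 20 um gel, 3 um grid) keeps unit
# tests fast; the acceptance tests build the full-scale geometry themselves.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_fixture <- function(pattern = "contractile_pair") {
  cached(paste0("small_fx_", pattern),
         make_two_cell_fixture(diameter = 12, gap = 6, thickness = 20,
                               spacing = 3, margin = 30, pattern = pattern))
}

small_context <- function() {
  fx <- small_fixture()
  cached("small_ctx", fem_context(fx$substrate, fx$forces$grid))
}

small_disp <- function(with_z = FALSE) {
  fx <- small_fixture()
  cached(paste0("small_disp_", with_z),
         forward_surface_displacements(fx$forces, fx$substrate,
                                       with_z = with_z,
                                       context = small_context()))
}

# Full-scale two-cell geometry of the validation study (20 um cells, 10 um
# gap, E = 1 kPa, nu = 0.45, 70 um gel, 4.84 um grid).
full_fixture <- function() cached("full_fx", make_two_cell_fixture())

full_context <- function() {
  fx <- full_fixture()
  cached("full_ctx", fem_context(fx$substrate, fx$forces$grid))
}

full_roundtrip <- function() {
  cached("full_roundtrip", {
    fx <- full_fixture()
    ctx <- full_context()
    disp <- forward_surface_displacements(fx$forces, fx$substrate,
                                          with_z = TRUE, context = ctx)
    rec <- recover_mixed(disp, fx$mask, fx$substrate, context = ctx)
    list(fx = fx, ctx = ctx, disp = disp, rec = rec)
  })
}

# Write lines to a throwaway file and return its path.
writeLines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Max relative node-by-node in-plane force error over nodes carrying at
# least `floor_frac` of the peak prescribed force.
max_force_error <- function(tf, truth, mask, floor_frac = 0.05) {
  sel <- mask$labels > 0L
  dF <- sqrt((tf$fx - truth$fx)[sel]^2 + (tf$fy - truth$fy)[sel]^2)
  Ft <- sqrt(truth$fx[sel]^2 + truth$fy[sel]^2)
  big <- Ft >= floor_frac * max(Ft)
  max(dF[big] / Ft[big])
}
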