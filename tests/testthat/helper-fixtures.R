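# Shared fixtures, memoized across test files (all built in code).

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_tables <- function() memo("tables", load_constraint_tables)

# constraint tables with every half-range zeroed and per-element
# circumference/axes-ratio enforcement off: the degenerate sampler
fx_tables_degenerate <- function() memo("tables0", function() {
  tab <- unclass(load_constraint_tables())
  zero <- function(el) {
    for (f in names(el)) {
      if (is.list(el[[f]]) && !is.null(el[[f]]$hr)) el[[f]]$hr <- 0
      if (is.list(el[[f]]) && !is.null(el[[f]]$enforce))
        el[[f]]$enforce <- FALSE
    }
    el
  }
  tab$elements <- lapply(tab$elements, zero)
  tab$satellites <- lapply(tab$satellites, zero)
  tab$midline <- zero(tab$midline)
  class(tab) <- "cceit_constraints"
  tab
})

fx_sensor <- function() memo("sensor", sensor_model)

fx_phantom <- function() memo("phantom", function() {
  build_healthy_phantom(sample_geometry(fx_tables(), seed = 101),
                        assign_region_properties(seed = 101))
})

# one noiseless frame of the fixture phantom on the 64^2 solver grid
fx_frame <- function() memo("frame", function() {
  field <- permittivity_field(fx_phantom(), solver_grid(fx_sensor(), 64))
  measure_frame(field, fx_sensor())
})

# homogeneous brain-tissue reference field and its sensitivity matrix
fx_reference_field <- function(n = 64) {
  memo(paste0("ref", n), function() {
    pri <- region_priors()
    uniform_field(solver_grid(fx_sensor(), n),
                  eps_r = pri$eps_mean[pri$region == "brain"],
                  sigma_mS_m = pri$sigma_mean[pri$region == "brain"],
                  head_only = TRUE)
  })
}

fx_sensitivity <- function() memo("sens_mat", function() {
  sensitivity_matrix(fx_sensor(), fx_reference_field(), raster_grid(234, 32))
})

# small simulated dataset shared by dataset/metrics/pipeline tests
fx_dataset <- function() memo("dataset", function() {
  build_dataset(10, 6, seed = 77, snr_db = 30)
})
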