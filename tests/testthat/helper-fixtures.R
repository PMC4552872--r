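# Shared fixtures: all synthetic, generated in code.

# A smaller survey than the default study conditions, for fast unit tests
# (~120 detections).
quick_config <- function(seed, ...) {
  sim_config(n_transects = 60L, seed = seed, ...)
}

quick_sim <- function(seed, ...) {
  suppressWarnings(simulate_survey(quick_config(seed, ...)))
}

# A fitted MCDS + conditional pair on a fixed quick survey, cached per session.
fixture_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- survey_geometry(22, 350)
      sim <- quick_sim(401)
      mcds <- fit_mcds(sim$observations, geom, shared = ~ flat + cover20,
                       restarts = 1L)
      mr <- fit_mrcond(mcds$data)
      cache <<- list(geom = geom, sim = sim, mcds = mcds, mr = mr)
    }
    cache
  }
})

# Hand-written observation table for io tests.
tiny_obs <- function() {
  data.frame(
    transect = c(1L, 1L, 2L),
    distance = c(50, 120.5, 300),
    size = c(1L, 2L, 1L),
    seen_by_1 = c(1L, 0L, 1L),
    seen_by_2 = c(0L, 1L, 1L),
    cover = c(0, 40, 80),
    snow = c(0, 20, 100),
    airspeed = c(120, 150, 130),
    searchdist = c(60, 200, 500)
  )
}

write_tiny_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
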