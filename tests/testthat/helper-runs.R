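# shared, lazily-built simulation fixtures (cached across test files)

run_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- builder()
  run_cache[[key]]
}

# single-axis growth past an inclined obstacle: calibrated weights,
# zero random deviation, static hydrostatic soil field
obstacle_run_config <- function(eta = 45, t_end = 7) {
  cfg <- default_config()
  cfg$domain <- list(width = 4.8, height = 6.8, nx = 48, nz = 68,
                     thickness = 0.08)
  cfg$seed_pos <- c(2.4, 5.8)
  cfg$schedule <- data.frame(time = 0, orientation = 90)
  cfg$traits <- list(delta = 0, max_order = 1L)
  cfg$obstacles <- list(list(center = c(2.4, 3.8), length = 2,
                             width = 0.2, eta = eta))
  cfg$time <- list(t_end = t_end, dT = 0.05, output_dt = 1)
  cfg$water$coupled <- FALSE
  cfg$seed <- 1L
  cfg
}

obstacle_run <- function() {
  cached("obstacle45", function() simulate_rsa(obstacle_run_config()))
}

# calibrated six-day wheat run on the 10 x 10 cm chamber (full coupling)
wheat_run <- function() {
  cached("wheat6", function() simulate_rsa(default_config()))
}

# small, fast coupled run for structural checks
small_run <- function(t_end = 2.5) {
  cached(paste0("small", t_end), function() {
    cfg <- default_config()
    cfg$domain$nx <- 20
    cfg$domain$nz <- 20
    cfg$time$t_end <- t_end
    simulate_rsa(cfg)
  })
}
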