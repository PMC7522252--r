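#' Network-index time series of simulated root systems
#'
#' Computes the network indices at the requested times from a
#' simulation's snapshots; with several seeds, runs one replicate per
#' seed and reports the replicate mean and standard deviation.
#'
#' @param config run configuration (see [default_config()]).
#' @param times output times (day); must be snapshot times of the run.
#' @param seeds integer vector of replicate seeds.
#' @return Data frame with one row per time: columns `time`, index
#'   means, and (for > 1 replicate) `<index>_sd` columns.
#' @export
index_timeseries <- function(config, times, seeds = config$seed %||% 1L) {
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    sim <- simulate_rsa(cfg)
    snapshot_indices(sim, times)
  })
  idx_names <- setdiff(names(runs[[1]]), "time")
  out <- runs[[1]]["time"]
  for (nm in idx_names) {
    vals <- sapply(runs, function(r) r[[nm]])
    vals <- matrix(vals, nrow = length(times))
    out[[nm]] <- rowMeans(vals)
    if (length(seeds) > 1)
      out[[paste0(nm, "_sd")]] <- apply(vals, 1, stats::sd)
  }
  out
}

# indices evaluated on stored snapshots at given times
snapshot_indices <- function(sim, times) {
  snap_t <- vapply(sim$snapshots, `[[`, 0, "time")
  rows <- lapply(times, function(tt) {
    k <- which.min(abs(snap_t - tt))
    if (abs(snap_t[k] - tt) > 1e-6)
      stop("no snapshot at time ", tt, " (available: ",
           paste(signif(snap_t, 4), collapse = ", "), ")")
    sub <- sim
    sub$roots <- sim$snapshots[[k]]$roots
    sub$segments <- sim$snapshots[[k]]$segments
    sub$tips <- sim$snapshots[[k]]$tips
    cbind(time = tt, network_indices(sub))
  })
  do.call(rbind, rows)
}

#' Least-squares grid search over growth parameters
#'
#' Evaluates a simulator over the cartesian product of the parameter
#' grids and returns the point minimising the weighted mean squared
#' error between the replicate-averaged simulated index series and the
#' target series. Each index's squared error is normalized by the RMS
#' of its target series before weighting, so indices of different
#' magnitude contribute comparably.
#'
#' @param grids named list of numeric parameter grids (non-empty).
#' @param target data frame with a `time` column and one column per
#'   index.
#' @param simulator `function(params, seed)` returning a data frame
#'   time-aligned with `target` (same rows, same index columns).
#' @param seeds replicate seeds (default one replicate, seed 1).
#' @param weights named per-index weights (default all 1).
#' @return List with `best` (named list of parameters), `error` (its
#'   error), `surface` (data frame of all grid points and errors) and
#'   `ties` (row indices of equal-minimum points; the lowest-index point
#'   is returned).
#' @export
grid_search_fit <- function(grids, target, simulator, seeds = 1L,
                            weights = NULL) {
  if (length(grids) == 0 || any(!vapply(grids, length, 0L)))
    stop("parameter grids must be non-empty")
  idx_names <- setdiff(names(target), c("time", grep("_sd$",
                                                     names(target),
                                                     value = TRUE)))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(idx_names)),
                                                   idx_names)
  surf <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  rms <- vapply(idx_names, function(nm) {
    r <- sqrt(mean(target[[nm]]^2))
    if (r <= 0) 1 else r
  }, 0)
  errs <- numeric(nrow(surf))
  failures <- character(0)
  for (gi in seq_len(nrow(surf))) {
    params <- as.list(surf[gi, , drop = FALSE])
    sims <- NULL
    ok <- TRUE
    for (s in seeds) {
      r <- tryCatch(simulator(params, s), error = function(e) e)
      if (inherits(r, "error")) {
        failures <- c(failures, sprintf("grid point %d (seed %s): %s",
                                        gi, s, conditionMessage(r)))
        ok <- FALSE
        break
      }
      sims <- if (is.null(sims)) r[idx_names]
      else sims + r[idx_names]
    }
    if (!ok) {
      errs[gi] <- NA_real_
      next
    }
    sims <- sims / length(seeds)
    e <- 0
    for (nm in idx_names)
      e <- e + weights[[nm]] *
        mean(((sims[[nm]] - target[[nm]]) / rms[[nm]])^2)
    errs[gi] <- e
  }
  if (all(is.na(errs)))
    stop("all grid-point simulations failed:\n",
         paste(failures, collapse = "\n"))
  surf$error <- errs
  best_i <- which(errs == min(errs, na.rm = TRUE))
  list(best = as.list(surf[best_i[1], names(grids), drop = FALSE]),
       error = errs[best_i[1]],
       surface = surf,
       ties = best_i,
       failures = failures)
}

#' Estimate the recovery-time proportionality kappa
#'
#' Least-squares slope through the origin of the recovery duration
#' `t2 - t1` against the contact duration `t1 - t0` over the contact
#' episodes.
#'
#' @param episodes data frame with columns `t0`, `t1`, `t2`.
#' @return Estimated kappa.
#' @export
estimate_kappa <- function(episodes) {
  x <- episodes$t1 - episodes$t0
  y <- episodes$t2 - episodes$t1
  keep <- x > 0
  if (!any(keep)) stop("need at least one episode with t1 > t0")
  sum(x[keep] * y[keep]) / sum(x[keep]^2)
}

#' Calibrate the initial recovery weight W_oi
#'
#' For each obstacle inclination, simulates the growth-angle trajectory
#' for every candidate `W_oi` (several replicates), truncates the mean
#' post-contact series and the reference to their common length, and
#' returns the least-squares best `W_oi` per inclination and pooled.
#'
#' @param references named list (one entry per inclination `eta`) of
#'   data frames `time`, `beta` covering the post-contact phase
#'   (`time > t1`).
#' @param grid candidate `W_oi` values.
#' @param simulator `function(eta, W_oi, seed)` returning a data frame
#'   `time`, `beta` restricted to `time > t1`.
#' @param seeds replicate seeds (default three replicates).
#' @return List with `best` (pooled argmin), `per_eta` (named vector),
#'   and `errors` (matrix eta x grid of mean squared errors).
#' @export
fit_w_oi <- function(references, grid, simulator, seeds = 1:3) {
  stopifnot(length(grid) >= 1, length(references) >= 1)
  etas <- names(references)
  errs <- matrix(NA_real_, length(etas), length(grid),
                 dimnames = list(etas, as.character(grid)))
  for (ei in seq_along(etas)) {
    ref <- references[[ei]]
    for (wi in seq_along(grid)) {
      beta_acc <- NULL
      nmin <- Inf
      series <- lapply(seeds, function(s)
        simulator(as.numeric(etas[ei]), grid[wi], s))
      nmin <- min(nrow(ref), vapply(series, nrow, 0L))
      if (nmin < nrow(ref) || any(vapply(series, nrow, 0L) > nmin))
        warning("reference and simulated series lengths differ; ",
                "truncating to ", nmin, " samples")
      mean_beta <- rowMeans(sapply(series,
                                   function(s) s$beta[seq_len(nmin)]))
      errs[ei, wi] <- mean((mean_beta - ref$beta[seq_len(nmin)])^2)
    }
  }
  pooled <- colSums(errs)
  list(best = grid[which.min(pooled)],
       per_eta = stats::setNames(grid[apply(errs, 1, which.min)], etas),
       errors = errs)
}
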