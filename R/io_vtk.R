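#' Export soil fields as a legacy-VTK rectilinear grid
#'
#' Writes an ASCII VTK (legacy format, `RECTILINEAR_GRID`) file with the
#' nodal pressure head and water content as point data and the sink and
#' (optionally) penetration resistance as cell data. Units: cm, day,
#' kPa.
#'
#' @param grid a [soil_grid()].
#' @param state a `water_state`.
#' @param sink elemental sink (1/day); defaults to the state's sink.
#' @param path output path.
#' @param R_elem optional elemental penetration resistance (kPa).
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(grid, state, sink = NULL, path,
                             R_elem = NULL) {
  if (is.null(sink)) sink <- state$sink
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("rhizogrow soil fields (units: cm, day, kPa) t=%.6g day", state$time)
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d %d", grid$nx + 1L, grid$nz + 1L, 1L)
  wl("X_COORDINATES %d double", grid$nx + 1L)
  wl(paste(sprintf("%.9g", grid$xs), collapse = " "))
  wl("Y_COORDINATES %d double", grid$nz + 1L)
  wl(paste(sprintf("%.9g", grid$zs), collapse = " "))
  wl("Z_COORDINATES 1 double")
  wl("0")
  wl("POINT_DATA %d", grid$nnode)
  wl("SCALARS pressure_head double 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", state$h), con)
  wl("SCALARS water_content double 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", state$theta), con)
  wl("CELL_DATA %d", grid$nelem)
  wl("SCALARS sink double 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", sink), con)
  if (!is.null(R_elem)) {
    wl("SCALARS penetration_resistance double 1")
    wl("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", R_elem), con)
  }
  invisible(path)
}

#' Write the per-segment table as CSV
#'
#' Columns: segment id, root, parent segment, endpoints, length, birth
#' time, order, and (when a xylem solution is attached) xylem head,
#' radial flux density and radial flow.
#'
#' @param sim an `rsa_simulation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(sim, path) {
  segs <- sim$segments
  if (!is.null(sim$xylem) && length(sim$xylem$J_r) == nrow(segs)) {
    segs$h_x <- sim$xylem$h_x
    segs$q_r <- sim$xylem$q_r
    segs$J_r <- sim$xylem$J_r
  }
  utils::write.csv(segs, path, row.names = FALSE)
  invisible(path)
}
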