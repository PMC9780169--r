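#' G-code program with volumetric extrusion
#'
#' Ordered absolute moves; \code{e} is the cumulative extruded volume in mm^3
#' (volumetric E, RepRap dialect), \code{feed} the feed rate in mm/min and
#' \code{travel} flags non-extruding moves.
#'
#' @param moves data.frame with columns x, y, z (mm), e (cumulative mm^3),
#'   feed (mm/min), travel (logical).
#' @param settings the [print_settings()] the program was planned with.
#' @return An object of class \code{gcode_program}.
#' @export
gcode_program <- function(moves, settings = NULL) {
  need <- c("x", "y", "z", "e", "feed", "travel")
  if (!all(need %in% names(moves))) stop("moves must have columns ",
                                         paste(need, collapse = ", "))
  if (nrow(moves) && any(diff(moves$e) < -1e-9))
    stop("cumulative extrusion E must be non-decreasing")
  structure(list(moves = moves, settings = settings), class = "gcode_program")
}

#' @export
print.gcode_program <- function(x, ...) {
  m <- x$moves
  cat(sprintf("<gcode_program> %d moves (%d extruding), E total %.2f mm^3\n",
              nrow(m), sum(!m$travel), if (nrow(m)) max(m$e) else 0))
  invisible(x)
}

#' Write a G-code program to a text file
#'
#' RepRap-flavoured dialect: absolute coordinates (G90), millimetre units
#' (G21), one G1 per extruding segment with cumulative volumetric E (mm^3),
#' G0 for travels. All print settings are recorded as header comments.
#'
#' @param program a non-empty [gcode_program()].
#' @param path destination path.
#' @export
write_gcode <- function(program, path) {
  m <- program$moves
  if (nrow(m) == 0) stop("cannot write an empty G-code program")
  hdr <- c("; generated by woundpatch",
           "; volumetric extrusion: E is cumulative deposited volume in mm^3")
  s <- program$settings
  if (!is.null(s)) {
    for (k in names(s)) {
      hdr <- c(hdr, sprintf("; setting %s = %s", k,
                            paste(format(s[[k]], trim = TRUE), collapse = ",")))
    }
  }
  n <- nrow(m)
  znew <- c(TRUE, m$z[-1] != m$z[-n])
  fnew <- c(TRUE, m$feed[-1] != m$feed[-n])
  move_lines <- sprintf("%s X%.3f Y%.3f", ifelse(m$travel, "G0", "G1"),
                        m$x, m$y)
  move_lines <- ifelse(m$travel, move_lines,
                       sprintf("%s E%.5f", move_lines, m$e))
  move_lines <- ifelse(fnew, sprintf("%s F%.0f", move_lines, m$feed),
                       move_lines)
  z_lines <- sprintf("G1 Z%.3f", m$z)
  body <- character(n + sum(znew))
  pos <- seq_len(n) + cumsum(znew)
  body[pos[znew] - 1L] <- z_lines[znew]
  body[pos] <- move_lines
  writeLines(c(hdr, "G21 ; mm", "G90 ; absolute", body), path)
  invisible(path)
}
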