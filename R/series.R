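# Plain-table time series (stress-strain logs) and minimal trajectory
# frames. Tables are whitespace- or comma-separated with a header line.

#' Construct a stress-strain series
#'
#' @param strain numeric vector of engineering strains (dimensionless).
#' @param stress numeric vector of stresses, GPa.
#' @param label optional model label carried in the attributes.
#' @return a data frame of class `stress_strain` with columns `strain` and
#'   `stress`, ordered by non-decreasing strain.
#' @export
stress_strain_series <- function(strain, stress, label = NULL) {
  stopifnot(length(strain) == length(stress))
  ord <- order(strain)
  out <- data.frame(strain = strain[ord], stress = stress[ord])
  class(out) <- c("stress_strain", "data.frame")
  attr(out, "label") <- label
  out
}

#' Read an (x, y) series from a plain table
#'
#' Accepts whitespace- or comma-separated tables with a header. Rows are
#' sorted by the x column; rows with a missing value in either column are
#' dropped with a warning.
#'
#' @param path path to the table.
#' @param x_column,y_column column names to use (default `strain`,
#'   `stress`).
#' @return a [stress_strain_series()].
#' @export
read_series <- function(path, x_column = "strain", y_column = "stress") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (colname in c(x_column, y_column)) {
    if (!colname %in% names(tab))
      stop(sprintf("column '%s' not found; available: %s", colname,
                   paste(names(tab), collapse = ", ")))
  }
  x <- as.numeric(tab[[x_column]])
  y <- as.numeric(tab[[y_column]])
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep))
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
  stress_strain_series(x[keep], y[keep])
}

#' Write a stress-strain series as CSV
#' @param series a [stress_strain_series()].
#' @param path output path.
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a minimal trajectory frame
#'
#' Plain-text format: a comment header (box lengths), then one row per atom
#' `id type x y z [vx vy vz fx fy fz]`, whitespace-separated.
#'
#' @param path output path.
#' @param positions n x 3 matrix, angstrom.
#' @param type character or integer atom types (length n).
#' @param velocities,forces optional n x 3 matrices (A/fs, kcal/mol/A).
#' @param box optional numeric 3-vector of box lengths written to the
#'   header.
#' @export
write_frame <- function(path, positions, type = rep(1L, nrow(positions)),
                        velocities = NULL, forces = NULL, box = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  n <- nrow(positions)
  hdr <- if (is.null(box)) "# frame" else
    sprintf("# frame box %.10g %.10g %.10g", box[1], box[2], box[3])
  cols <- list(id = seq_len(n), type = type,
               x = positions[, 1], y = positions[, 2], z = positions[, 3])
  if (!is.null(velocities)) {
    cols$vx <- velocities[, 1]; cols$vy <- velocities[, 2]
    cols$vz <- velocities[, 3]
  }
  if (!is.null(forces)) {
    cols$fx <- forces[, 1]; cols$fy <- forces[, 2]; cols$fz <- forces[, 3]
  }
  df <- as.data.frame(cols)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, paste(names(df), collapse = " ")), con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a minimal trajectory frame written by [write_frame()]
#' @param path path to the frame file.
#' @return a list with `positions`, `type`, and (when present)
#'   `velocities`, `forces`, `box`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  box <- NULL
  if (grepl("^# frame box", lines[1]))
    box <- as.numeric(strsplit(trimws(sub("^# frame box", "", lines[1])),
                               "\\s+")[[1]])
  header <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  tab <- utils::read.table(text = lines[-(1:2)], col.names = header)
  out <- list(positions = as.matrix(tab[, c("x", "y", "z")]),
              type = tab$type, box = box)
  if (all(c("vx", "vy", "vz") %in% header))
    out$velocities <- as.matrix(tab[, c("vx", "vy", "vz")])
  if (all(c("fx", "fy", "fz") %in% header))
    out$forces <- as.matrix(tab[, c("fx", "fy", "fz")])
  out
}

#' Write coordinates in XYZ format
#' @param structure a [mol_structure()].
#' @param path output path.
#' @param comment second-line comment.
#' @export
write_xyz <- function(structure, path, comment = "") {
  a <- structure$atoms
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(a)), comment), con)
  writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                     normalize_element(a$element), a$x, a$y, a$z), con)
  invisible(path)
}
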