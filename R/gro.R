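#' Read a (possibly multi-frame) GRO coordinate file
#'
#' Parses the fixed-width GROMACS GRO format: a title line (a trailing
#' \code{t=} field is read as the frame time in ps), an atom count, one line
#' per atom (residue index, residue name, atom name, atom number, x/y/z in
#' nm), and a box line. Multiple concatenated frames are read as a
#' trajectory; the atom table is taken from the first frame and must match in
#' length across frames. Velocity columns, if present, are ignored.
#'
#' @param path file path.
#' @return list with \code{atoms} (data frame: \code{resid}, \code{resname},
#'   \code{name}) and \code{frames} (list of \code{coords} n x 3 matrix [nm],
#'   \code{box} length-3 [nm], \code{time_ns}).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stop(sprintf("%s: expected atom count on line %d", path, i + 1L))
    if (i + 1L + natoms + 1L > length(lines))
      stop(sprintf("%s: truncated frame starting at line %d", path, i))
    at <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- as.integer(substr(at, 1L, 5L))
    resname <- trimws(substr(at, 6L, 10L))
    name <- trimws(substr(at, 11L, 15L))
    x <- as.numeric(substr(at, 21L, 28L))
    y <- as.numeric(substr(at, 29L, 36L))
    z <- as.numeric(substr(at, 37L, 44L))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop(sprintf("%s: malformed coordinates in frame starting at line %d",
                   path, i))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]),
                               "\\s+")[[1L]])[1:3]
    if (anyNA(box) || any(box <= 0))
      stop(sprintf("%s: invalid box on line %d", path, i + 2L + natoms))
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time_ps <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else
      (length(frames)) * 1.0
    if (is.null(atoms)) {
      atoms <- data.frame(resid = resid, resname = resname, name = name,
                          stringsAsFactors = FALSE)
    } else if (natoms != nrow(atoms)) {
      stop(sprintf("%s: frame %d has %d atoms, expected %d", path,
                   length(frames) + 1L, natoms, nrow(atoms)))
    }
    frames[[length(frames) + 1L]] <-
      list(coords = cbind(x = x, y = y, z = z), box = box,
           time_ns = time_ps / 1000)
    i <- i + natoms + 3L
  }
  if (!length(frames)) stop(path, ": no frames found")
  list(atoms = atoms, frames = frames)
}

#' Write coordinates to a GRO file
#'
#' @param atoms data frame with \code{resid}, \code{resname}, \code{name}.
#' @param frames list of frames as returned by \code{\link{read_gro}}.
#' @param path output path.
#' @param title title-line prefix; the frame time is appended as
#'   \code{t= <ps>}.
#' @export
write_gro <- function(atoms, frames, path, title = "memprobe system") {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("%s t= %.3f", title, fr$time_ns * 1000), con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resid %% 100000L, atoms$resname, atoms$name,
                       seq_len(nrow(atoms)) %% 100000L,
                       fr$coords[, 1L], fr$coords[, 2L], fr$coords[, 3L]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1L], fr$box[2L],
                       fr$box[3L]), con)
  }
  invisible(path)
}
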