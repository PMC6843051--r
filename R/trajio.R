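#' Write a trajectory to disk
#'
#' Writes a list of coordinate frames as an XYZ trajectory (element column
#' `CA`, 6-decimal coordinates) or a multi-model PDB (MODEL/ENDMDL blocks,
#' standard fixed-width ATOM records, 3-decimal coordinates).
#'
#' @param frames a list of N x 3 matrices, or an `mcg_trajectory`.
#' @param path output file path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the file extension.
#' @param times optional frame times in ps (taken from the trajectory object
#'   when available), written to the comment line / MODEL remark.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, format = NULL, times = NULL) {
  if (inherits(frames, "mcg_trajectory")) {
    if (is.null(times)) times <- frames$times
    frames <- frames$frames
  }
  if (!is.list(frames)) frames <- list(coords_of(frames))
  if (length(frames) == 0L) stop("empty frame list")
  frames <- lapply(frames, coords_of)
  if (is.null(format))
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  format <- match.arg(format, c("xyz", "pdb"))
  if (is.null(times)) times <- seq_along(frames) - 1
  n <- nrow(frames[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (f in seq_along(frames)) {
      x <- frames[[f]]
      writeLines(c(as.character(n),
                   sprintf("frame %d time_ps %.6f", f, times[f]),
                   sprintf("CA %14.6f %14.6f %14.6f", x[, 1], x[, 2], x[, 3])),
                 con)
    }
  } else {
    for (f in seq_along(frames)) {
      x <- frames[[f]]
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), seq_len(n), x[, 1], x[, 2], x[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Reads an XYZ or multi-model PDB trajectory written by
#' [write_trajectory()] (or any file in those standard formats).
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the extension.
#' @return A list of N x 3 coordinate matrices.
#' @export
read_trajectory <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else
      if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else
        stop("cannot guess trajectory format from extension of ", path)
  format <- match.arg(format, c("xyz", "pdb"))
  lines <- readLines(path)
  if (format == "xyz") {
    frames <- list()
    i <- 1L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- as.integer(trimws(lines[i]))
      if (is.na(n)) stop("malformed XYZ atom-count line at line ", i)
      block <- lines[(i + 2L):(i + 1L + n)]
      parts <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(p)
        as.numeric(p[2:4])))
      frames[[length(frames) + 1L]] <- parts
      i <- i + 2L + n
    }
    frames
  } else {
    at <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA "
    model_of <- cumsum(grepl("^MODEL", lines))
    if (max(model_of) == 0L) model_of <- rep(1L, length(lines))
    xs <- as.numeric(substr(lines[at], 31, 38))
    ys <- as.numeric(substr(lines[at], 39, 46))
    zs <- as.numeric(substr(lines[at], 47, 54))
    lapply(split(seq_along(xs), model_of[at]), function(ix)
      cbind(xs[ix], ys[ix], zs[ix]))
  }
}

#' Write a C-alpha trace as a single-model PDB file
#'
#' @param trace a [ca_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(trace, path) {
  x <- trace$coords
  chain <- if (nzchar(trace$label) && nchar(trace$label) == 1L) trace$label else "A"
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(x)), trace$residue_names, chain, trace$residue_ids,
    x[, 1], x[, 2], x[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
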