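#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect of the TPS landmark format: each specimen is
#' a block starting `LM=<p>`, followed by `p` whitespace-separated
#' coordinate lines, then `ID=<specimen>` and optionally `SCALE=<v>`
#' (coordinates are multiplied by the scale to yield image units). CRLF
#' line endings and trailing blank lines are tolerated.
#'
#' @param path Path to a `.tps` / `.TPS` file.
#' @return A landmark tibble: `specimen_id`, `landmark` (1-based), `x`,
#'   `y`, `scale`.
#' @export
read_tps <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  i <- 1L
  specimens <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      abort(paste0("line ", i, ": expected 'LM=<count>', got '", ln, "'"))
    }
    p <- as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE))
    if (is.na(p) || p < 1) abort(paste0("line ", i, ": bad landmark count"))
    coords <- matrix(NA_real_, p, 2)
    for (k in seq_len(p)) {
      i <- i + 1L
      if (i > length(lines)) abort("truncated TPS file: missing coordinates")
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2 || any(is.na(xy))) {
        abort(paste0("line ", i, ": expected two coordinates"))
      }
      coords[k, ] <- xy
    }
    id <- NA_character_
    scale <- 1
    i <- i + 1L
    while (i <= length(lines) && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      kv <- lines[i]
      if (grepl("^ID\\s*=", kv, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", kv, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", kv, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", kv,
                                ignore.case = TRUE))
      } # other tpsDig keys (IMAGE=, COMMENT=) are ignored
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("spec", length(specimens) + 1L)
    specimens[[length(specimens) + 1L]] <- tibble::tibble(
      specimen_id = id, landmark = seq_len(p),
      x = coords[, 1] * scale, y = coords[, 2] * scale, scale = scale
    )
  }
  if (length(specimens) == 0) abort("no specimens in TPS file")
  dplyr::bind_rows(specimens)
}

#' Write landmarks as a TPS file
#'
#' Emits the tpsDig dialect with LF line endings: `LM=`, coordinate
#' lines, `ID=`, and `SCALE=` when a scale column is present (coordinates
#' are divided back by the scale so read/write round-trips).
#'
#' @param landmarks A landmark tibble (`specimen_id`, `landmark`, `x`,
#'   `y`, optional `scale`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  lm <- tibble::as_tibble(landmarks)
  ids <- unique(lm$specimen_id)
  out <- character(0)
  for (id in ids) {
    s <- lm[lm$specimen_id == id, , drop = FALSE]
    s <- s[order(s$landmark), , drop = FALSE]
    scale <- if ("scale" %in% names(s)) s$scale[1] else 1
    out <- c(out,
             paste0("LM=", nrow(s)),
             sprintf("%.6f %.6f", s$x / scale, s$y / scale),
             paste0("ID=", id),
             if (scale != 1) paste0("SCALE=", format(scale)) else NULL)
  }
  readr::write_lines(out, path)
  invisible(path)
}
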