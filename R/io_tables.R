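#' Read a particle table (RELION STAR dialect or plain delimited)
#'
#' Ingests subtomogram-averaging particle tables into a [particle_set],
#' normalising units and column names. STAR input expects a single data
#' block with a loop containing at least the RELION-3 coordinate columns
#' (`rlnCoordinateX/Y/Z`); angles map `rlnAngleRot` -> `phi`,
#' `rlnAngleTilt` -> `theta`, `rlnAnglePsi` -> `psi`, and the tomogram
#' identifier is taken from `rlnTomoName` or `rlnMicrographName`. Delimited
#' input expects a header with `x`/`y`/`z` (optionally suffixed `_nm`) plus
#' `phi`, `theta`, `psi`.
#'
#' Positions are converted to nanometres exactly once: if `pixel_size` is
#' given, coordinates are taken to be in voxels and multiplied by it;
#' otherwise they are taken to be nanometres already. A missing state
#' column yields `state = "unknown"`.
#'
#' @param path file to read.
#' @param dialect `"star"` or `"delimited"` (TSV/CSV, sniffed from the
#'   header line).
#' @param pixel_size nanometres per voxel, or `NULL` when coordinates are
#'   already in nanometres.
#' @return a [particle_set] with positions in nanometres.
#' @seealso [write_particle_table()]
#' @export
read_particle_table <- function(path, dialect = c("star", "delimited"),
                                pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (dialect == "star") read_star_loop(path) else read_delim_table(path)
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), pixel_size > 0)
    df$x <- df$x * pixel_size
    df$y <- df$y * pixel_size
    df$z <- df$z * pixel_size
  }
  as_particle_set(df, provenance = sprintf(
    "read %s (%s dialect%s)", path, dialect,
    if (is.null(pixel_size)) "" else sprintf(", voxel->nm x%g", pixel_size)
  ))
}

# Column aliases recognised on ingest, in lookup order.
star_aliases <- list(
  x = c("rlnCoordinateX"),
  y = c("rlnCoordinateY"),
  z = c("rlnCoordinateZ"),
  phi = c("rlnAngleRot"),
  theta = c("rlnAngleTilt"),
  psi = c("rlnAnglePsi"),
  tomogram_id = c("rlnTomoName", "rlnMicrographName"),
  particle_id = c("rlnImageName"),
  state = c("rlnClassNumber", "tsState")
)

delim_aliases <- list(
  x = c("x_nm", "x"), y = c("y_nm", "y"), z = c("z_nm", "z"),
  phi = c("phi"), theta = c("theta"), psi = c("psi"),
  tomogram_id = c("tomogram_id", "tomo"),
  particle_id = c("particle_id", "id"),
  state = c("state")
)

map_columns <- function(raw, aliases, where) {
  out <- list()
  for (field in names(aliases)) {
    hit <- intersect(aliases[[field]], names(raw))
    if (length(hit) > 0) out[[field]] <- raw[[hit[1]]]
  }
  for (coord in c("x", "y", "z")) {
    if (is.null(out[[coord]])) {
      stop(sprintf(
        "%s: missing coordinate column (expected one of: %s)",
        where, paste(aliases[[coord]], collapse = ", ")
      ))
    }
  }
  n <- length(out$x)
  for (coord in c("x", "y", "z", "phi", "theta", "psi")) {
    if (is.null(out[[coord]])) {
      out[[coord]] <- rep(0, n)
      next
    }
    v <- suppressWarnings(as.numeric(out[[coord]]))
    bad <- which(is.na(v) & !is.na(out[[coord]]))
    if (length(bad) > 0) {
      stop(sprintf(
        "%s: non-numeric value in column '%s' at row %d",
        where, coord, bad[1]
      ))
    }
    out[[coord]] <- v
  }
  if (is.null(out$tomogram_id)) out$tomogram_id <- "tomo1"
  if (is.null(out$particle_id)) {
    out$particle_id <- paste0("p", seq_len(n))
  }
  if (is.null(out$state)) out$state <- "unknown"
  out$state <- as.character(out$state)
  out$tomogram_id <- as.character(out$tomogram_id)
  out$particle_id <- as.character(out$particle_id)
  extras <- setdiff(names(raw), unlist(aliases))
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (e in extras) df[[e]] <- raw[[e]]
  df
}

# Minimal STAR reader: first data_ block, first loop_. Enough for the
# RELION-3 particle dialect; not a general STAR implementation.
read_star_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stop(path, ": no loop_ block found")
  i <- loop_at[1] + 1
  labels <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    lab <- sub("^_", "", strsplit(lines[i], "\\s+")[[1]][1])
    labels <- c(labels, lab)
    i <- i + 1
  }
  if (length(labels) == 0) stop(path, ": loop_ block declares no columns")
  rows <- character(0)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "data_") || ln == "loop_" ||
        startsWith(ln, "#")) {
      if (ln == "" && length(rows) == 0) { i <- i + 1; next }
      break
    }
    rows <- c(rows, ln)
    i <- i + 1
  }
  if (length(rows) == 0) stop(path, ": loop_ block has no data rows")
  fields <- strsplit(rows, "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(labels))) {
    stop(sprintf(
      "%s: row %d has %d fields, expected %d",
      path, which(nf != length(labels))[1], nf[nf != length(labels)][1],
      length(labels)
    ))
  }
  raw <- as.data.frame(
    do.call(rbind, fields), stringsAsFactors = FALSE
  )
  names(raw) <- labels
  map_columns(raw, star_aliases, path)
}

read_delim_table <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", header) && !grepl("\t", header)) "," else "\t"
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE, comment.char = ""
  )
  map_columns(raw, delim_aliases, path)
}

#' Write a particle table
#'
#' Inverse of [read_particle_table()]: emits either a single-loop STAR file
#' with RELION-3 column names (positions stay in nanometres; no voxel
#' conversion is applied on output) or a TSV with the package's canonical
#' header. Round-tripping through either dialect preserves positions,
#' angles and state labels to better than 1e-6.
#'
#' @param ps a non-empty [particle_set].
#' @param path output file.
#' @param dialect `"star"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(ps, path, dialect = c("star", "delimited")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ps, "particle_set"))
  if (nrow(ps) == 0) stop("refusing to write an empty particle set")
  df <- as.data.frame(ps)
  num <- function(v) formatC(v, format = "f", digits = 8)
  if (dialect == "delimited") {
    out <- data.frame(
      particle_id = df$particle_id, tomogram_id = df$tomogram_id,
      x_nm = num(df$x), y_nm = num(df$y), z_nm = num(df$z),
      phi = num(df$phi), theta = num(df$theta), psi = num(df$psi),
      state = df$state, stringsAsFactors = FALSE
    )
    utils::write.table(out, path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    labels <- c(
      "rlnImageName", "rlnTomoName",
      "rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
      "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi", "tsState"
    )
    body <- paste(
      df$particle_id, df$tomogram_id,
      num(df$x), num(df$y), num(df$z),
      num(df$phi), num(df$theta), num(df$psi), df$state,
      sep = "  "
    )
    writeLines(c(
      "", "data_particles", "", "loop_",
      sprintf("_%s #%d", labels, seq_along(labels)),
      body, ""
    ), path)
  }
  invisible(path)
}
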