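#' Construct a particle set
#'
#' A particle set is the package's universal currency: one row per detected
#' macromolecule with its tomogram of origin, centre position in nanometres,
#' orientation as a ZYZ Euler triplet in degrees, and a categorical state
#' label. It is a plain `data.frame` carrying `unit` and `provenance`
#' attributes, so every base-R table verb keeps working.
#'
#' @param particle_id character vector of unique particle identifiers.
#'   Defaults to `"p1" ... "pn"`.
#' @param tomogram_id character vector naming the tomogram each particle
#'   belongs to.
#' @param x,y,z numeric centre coordinates, nanometres.
#' @param phi,theta,psi Euler angles in degrees (intrinsic ZYZ; the RELION
#'   rot/tilt/psi composition). `theta` must lie in `[0, 180]`; `phi` and
#'   `psi` are wrapped to `[-180, 180)`.
#' @param state character state labels (e.g. `"closed"`, `"open_noPFD"`,
#'   `"ribosome"`); defaults to `"unknown"`.
#' @param provenance free-text note on where the records came from.
#'
#' @return An object of class `particle_set` (a `data.frame` with columns
#'   `particle_id`, `tomogram_id`, `x`, `y`, `z`, `phi`, `theta`, `psi`,
#'   `state` and attributes `unit = "nm"`, `provenance`).
#'
#' @examples
#' ps <- particle_set(
#'   tomogram_id = "tomo1",
#'   x = c(0, 17), y = 0, z = 0,
#'   phi = 0, theta = 0, psi = 0,
#'   state = "closed"
#' )
#' nrow(ps)
#' @export
particle_set <- function(particle_id = NULL, tomogram_id, x, y, z,
                         phi = 0, theta = 0, psi = 0,
                         state = "unknown", provenance = "constructed") {
  n <- max(length(tomogram_id), length(x), length(y), length(z))
  if (is.null(particle_id)) particle_id <- paste0("p", seq_len(n))
  df <- data.frame(
    particle_id = as.character(particle_id),
    tomogram_id = rep_len(as.character(tomogram_id), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    z = rep_len(as.numeric(z), n),
    phi = rep_len(as.numeric(phi), n),
    theta = rep_len(as.numeric(theta), n),
    psi = rep_len(as.numeric(psi), n),
    state = rep_len(as.character(state), n),
    stringsAsFactors = FALSE
  )
  as_particle_set(df, provenance = provenance)
}

#' Coerce a data frame to a particle set
#'
#' Validates invariants (finite positions, unique ids, `theta` in
#' `[0, 180]`), wraps `phi`/`psi` into `[-180, 180)` and stamps the
#' nanometre unit attribute.
#'
#' @param df a data.frame with at least the columns named in
#'   [particle_set()].
#' @param provenance free-text provenance string.
#' @return a `particle_set`.
#' @export
as_particle_set <- function(df, provenance = "coerced") {
  req <- c("particle_id", "tomogram_id", "x", "y", "z",
           "phi", "theta", "psi", "state")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("missing particle columns: ", paste(missing_cols, collapse = ", "))
  }
  pos <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite particle positions")
  if (anyDuplicated(df$particle_id)) stop("particle_id values must be unique")
  ang <- c("phi", "theta", "psi")
  if (!all(vapply(df[ang], is.numeric, logical(1)))) {
    stop("Euler angle columns must be numeric")
  }
  if (!all(is.finite(as.matrix(df[ang])))) stop("non-finite Euler angles")
  if (any(df$theta < -1e-9 | df$theta > 180 + 1e-9)) {
    stop("theta outside [0, 180] degrees")
  }
  df$theta <- pmin(pmax(df$theta, 0), 180)
  df$phi <- wrap_angle(df$phi)
  df$psi <- wrap_angle(df$psi)
  df <- df[, union(req, names(df))]
  structure(df,
    class = c("particle_set", "data.frame"),
    unit = "nm", provenance = provenance
  )
}

# wrap degrees into [-180, 180)
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf(
    "particle_set: %d particles, %d tomogram(s), unit %s\n",
    nrow(x), length(unique(x$tomogram_id)), attr(x, "unit")
  ))
  tab <- table(x$state)
  cat("states:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Subset a particle set by state label
#'
#' @param ps a `particle_set`.
#' @param states character vector of state labels to keep; `NULL` keeps all.
#' @return a `particle_set` with only matching records.
#' @export
filter_state <- function(ps, states) {
  stopifnot(inherits(ps, "particle_set"))
  if (is.null(states)) return(ps)
  out <- ps[ps$state %in% states, , drop = FALSE]
  as_particle_set(as.data.frame(out), provenance = attr(ps, "provenance"))
}

# split row indices by tomogram, preserving input order within each
split_by_tomogram <- function(ps) {
  split(seq_len(nrow(ps)), ps$tomogram_id)
}

position_matrix <- function(ps) {
  m <- as.matrix(ps[, c("x", "y", "z")])
  rownames(m) <- ps$particle_id
  m
}
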