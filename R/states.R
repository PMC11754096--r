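#' Per-class particle counts
#'
#' Container for the duty-cycle accounting: integer particle tallies per
#' conformational/cofactor state. The canonical vocabulary is
#' `open_noPFD`, `open_1PFD`, `open_2PFD` (the three open-conformation
#' prefoldin classes) and `closed`; arbitrary extra labels are allowed.
#' Counts may also be tallied directly from a [particle_set]'s state
#' labels via [count_states()].
#'
#' @param counts named integer vector of per-state counts, all `>= 0`.
#' @param label dataset label, e.g. `"untreated"` or `"treated"`.
#' @return list of class `state_counts`.
#' @examples
#' state_counts(c(open_noPFD = 2395, open_1PFD = 875, open_2PFD = 83,
#'                closed = 4054), label = "untreated")
#' @export
state_counts <- function(counts, label = "custom") {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0), all(counts == round(counts)))
  structure(
    list(counts = stats::setNames(as.integer(counts), names(counts)),
         label = label),
    class = "state_counts"
  )
}

#' Tally state counts from a particle set
#'
#' @param ps a [particle_set].
#' @param label dataset label.
#' @return a [state_counts()] object.
#' @export
count_states <- function(ps, label = "custom") {
  stopifnot(inherits(ps, "particle_set"))
  tab <- table(ps$state)
  state_counts(stats::setNames(as.integer(tab), names(tab)), label = label)
}

open_classes <- c("open_noPFD", "open_1PFD", "open_2PFD", "open")

#' Convert state counts to a percentage distribution
#'
#' Percentages are taken over ALL particles in the tally (open classes
#' plus closed together), so a prefoldin class percentage reads "of all
#' chaperonin particles", not "of open particles" — e.g. untreated counts
#' 875/7,407 give 1-PFD at about 12% of all particles. The open/closed
#' split is reported at one decimal; per-class percentages additionally
#' carry a nearest-integer rounding column.
#'
#' @param sc a [state_counts()] object.
#' @return data.frame (class `state_distribution`) with `state`, `count`,
#'   `percent` (1 decimal), `percent_int`; attributes `total`, `label`,
#'   `open_percent`, `closed_percent` (each 1 decimal, over the same
#'   total).
#' @examples
#' sd <- state_distribution(state_counts(c(open = 3353, closed = 4054)))
#' attr(sd, "open_percent")   # 45.3
#' attr(sd, "closed_percent") # 54.7
#' @export
state_distribution <- function(sc) {
  stopifnot(inherits(sc, "state_counts"))
  total <- sum(sc$counts)
  if (total == 0) stop("total particle count is zero")
  pct <- 100 * sc$counts / total
  out <- data.frame(
    state = names(sc$counts),
    count = as.integer(sc$counts),
    percent = round(pct, 1),
    percent_int = round(pct),
    stringsAsFactors = FALSE
  )
  is_open <- out$state %in% open_classes | grepl("^open", out$state)
  attr(out, "total") <- total
  attr(out, "label") <- sc$label
  attr(out, "open_percent") <- round(100 * sum(sc$counts[is_open]) / total, 1)
  attr(out, "closed_percent") <-
    round(100 * sum(sc$counts[!is_open]) / total, 1)
  class(out) <- c("state_distribution", "data.frame")
  out
}

#' Compare two state distributions
#'
#' Per-state percentage-point deltas (`b - a`) plus a pooled two-proportion
#' z statistic and two-sided p-value per state. No multiple-testing
#' correction is applied — the comparison covers a handful of pre-defined
#' states, and readers can apply their own correction.
#'
#' @param a,b `state_distribution` objects with identical state
#'   vocabularies.
#' @return data.frame: `state`, `percent_a`, `percent_b`, `delta`
#'   (points, exact not re-rounded), `z`, `p_value`.
#' @export
compare_distributions <- function(a, b) {
  stopifnot(inherits(a, "state_distribution"),
            inherits(b, "state_distribution"))
  if (!setequal(a$state, b$state)) {
    stop("state vocabularies differ: ",
         paste(symdiff_chr(a$state, b$state), collapse = ", "))
  }
  b <- b[match(a$state, b$state), , drop = FALSE]
  na <- attr(a, "total"); nb <- attr(b, "total")
  pa <- a$count / na; pb <- b$count / nb
  pool <- (a$count + b$count) / (na + nb)
  se <- sqrt(pool * (1 - pool) * (1 / na + 1 / nb))
  z <- ifelse(se > 0, (pb - pa) / se, 0)
  data.frame(
    state = a$state,
    percent_a = a$percent, percent_b = b$percent,
    delta = 100 * (pb - pa),
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
}

symdiff_chr <- function(x, y) union(setdiff(x, y), setdiff(y, x))

#' Duty-cycle summary table
#'
#' Side-by-side state percentages for two datasets, one row per step of
#' the folding cycle (open without PFD, open with one PFD, open with two
#' PFD, closed), zero-count classes retained as 0.0% rows.
#'
#' @param untreated,treated [state_counts()] objects.
#' @return data.frame: `state`, per-dataset `count_*` and `percent_*`
#'   columns (suffixed by the dataset labels).
#' @export
duty_cycle_table <- function(untreated, treated) {
  da <- state_distribution(untreated)
  db <- state_distribution(treated)
  states <- union(da$state, db$state)
  pref <- intersect(c("open_noPFD", "open_1PFD", "open_2PFD", "closed"),
                    states)
  states <- c(pref, setdiff(states, pref))
  pick <- function(d, col) {
    v <- d[[col]][match(states, d$state)]
    v[is.na(v)] <- 0
    v
  }
  out <- data.frame(
    state = states,
    count_a = as.integer(pick(da, "count")),
    percent_a = pick(da, "percent"),
    count_b = as.integer(pick(db, "count")),
    percent_b = pick(db, "percent"),
    stringsAsFactors = FALSE
  )
  names(out)[2:5] <- c(
    paste0("count_", attr(da, "label")), paste0("percent_", attr(da, "label")),
    paste0("count_", attr(db, "label")), paste0("percent_", attr(db, "label"))
  )
  out
}

#' Published particle tallies
#'
#' The per-class chaperonin particle counts for the two datasets analysed
#' in the source study: 360 tomograms of untreated cells (3,353 open +
#' 4,054 closed particles, open split 2,395/875/83 by prefoldin
#' occupancy) and 352 tomograms of translation-inhibited cells (3,785
#' open + 3,418 closed, open split 2,334/1,287/164).
#'
#' @param dataset `"untreated"` or `"treated"`.
#' @return a [state_counts()] object.
#' @export
reference_counts <- function(dataset = c("untreated", "treated")) {
  dataset <- match.arg(dataset)
  if (dataset == "untreated") {
    state_counts(c(open_noPFD = 2395, open_1PFD = 875, open_2PFD = 83,
                   closed = 4054), label = "untreated")
  } else {
    state_counts(c(open_noPFD = 2334, open_1PFD = 1287, open_2PFD = 164,
                   closed = 3418), label = "treated")
  }
}
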