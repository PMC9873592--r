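#' Cover-board study design
#'
#' Describes the sampling geometry and calendar of a robust-design
#' cover-board survey: board coordinates, the number of open "primary"
#' sessions (sampling seasons), the number of closed "secondary" occasions
#' nested in each primary, day-of-study stamps for the primaries (used to
#' scale annual survival to between-season intervals), and the rectangular
#' state space over which latent activity centers live.
#'
#' The default mirrors a 5 x 10 grid of 50 cover boards spaced 1 m apart,
#' sampled in spring and fall over three years (6 primaries, 3 secondary
#' occasions each). The state space is the board bounding box plus a buffer
#' wide enough that truncation of activity centers is negligible.
#'
#' @param boards data frame with columns `x`, `y` (meters). Default: 5 x 10
#'   grid at 1-m spacing with origin at the southwest board.
#' @param n_primary number of primary sessions.
#' @param secondaries integer vector of secondary-occasion counts per
#'   primary (recycled if length 1).
#' @param primary_dates `Date` vector or numeric day stamps, one per
#'   primary; consecutive differences give the between-primary intervals in
#'   days.
#' @param buffer state-space buffer beyond the board bounding box, meters.
#'   Must be at least 2.5 times the largest space-use scale \eqn{\sigma}
#'   used with the design (checked where \eqn{\sigma} is known).
#' @return object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$area
#' @export
study_design <- function(boards = default_board_grid(),
                         n_primary = 6,
                         secondaries = 3,
                         primary_dates = default_primary_dates(),
                         buffer = 10.5) {
  boards <- tibble::as_tibble(boards)
  stopifnot(all(c("x", "y") %in% names(boards)))
  if (anyDuplicated(boards[c("x", "y")]) > 0) {
    abort("board positions must be unique")
  }
  if (!"board_id" %in% names(boards)) {
    boards$board_id <- seq_len(nrow(boards))
  }
  secondaries <- rep_len(as.integer(secondaries), n_primary)
  if (any(secondaries < 1)) abort("each primary needs at least one secondary occasion")
  dates <- as.numeric(primary_dates)
  if (length(dates) != n_primary) {
    abort("`primary_dates` must supply one date per primary session")
  }
  intervals <- diff(dates)
  if (n_primary > 1 && any(intervals <= 0)) {
    abort("primary dates must be strictly increasing")
  }
  if (buffer <= 0) abort("`buffer` must be positive")
  xlim <- range(boards$x) + c(-buffer, buffer)
  ylim <- range(boards$y) + c(-buffer, buffer)
  structure(
    list(
      boards = boards[c("board_id", "x", "y")],
      n_primary = as.integer(n_primary),
      secondaries = secondaries,
      primary_dates = dates,
      intervals = intervals,
      buffer = buffer,
      xlim = xlim,
      ylim = ylim,
      area = diff(xlim) * diff(ylim)
    ),
    class = "study_design"
  )
}

#' @rdname study_design
#' @export
default_board_grid <- function() {
  tidyr::expand_grid(x = 0:4, y = 0:9) |>
    dplyr::arrange(.data$y, .data$x) |>
    dplyr::mutate(board_id = dplyr::row_number(), .before = 1)
}

#' @rdname study_design
#' @export
default_primary_dates <- function() {
  as.Date(c(
    "2017-04-15", "2017-10-01",
    "2018-04-15", "2018-10-01",
    "2019-04-15", "2019-10-01"
  ))
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat(sprintf("  boards: %d  primaries: %d  secondaries: %s\n",
              nrow(x$boards), x$n_primary, paste(x$secondaries, collapse = "/")))
  cat(sprintf("  state space: [%.1f, %.1f] x [%.1f, %.1f] m (%.0f m2, buffer %.1f m)\n",
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$area, x$buffer))
  invisible(x)
}

check_buffer <- function(design, sigma) {
  if (design$buffer < 2.5 * sigma) {
    abort(sprintf(
      "state-space buffer (%.2f m) must be at least 2.5 x sigma (sigma = %.2f m) to avoid edge bias",
      design$buffer, sigma
    ))
  }
  invisible(TRUE)
}
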