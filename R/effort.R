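#' Read searcher GPS tracks
#'
#' Tracks are timestamped fixes in projected planar coordinates. Columns:
#' `searcher_id`, `timestamp` (ISO-8601), `x_km`, `y_km`. Timestamps must be
#' strictly increasing within each searcher's track.
#'
#' @param path CSV file path.
#' @param tz time zone for parsing timestamps (default `"UTC"`).
#' @return a data frame with `searcher_id` (character), `timestamp`
#'   (POSIXct), `x_km`, `y_km`.
#' @export
read_tracks <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("searcher_id", "timestamp", "x_km", "y_km")
  if (!all(need %in% names(df)))
    stop("tracks CSV must have columns: ", paste(need, collapse = ", "))
  df$searcher_id <- as.character(df$searcher_id)
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  df$timestamp <- ts
  validate_tracks(df)
  df
}

validate_tracks <- function(tracks) {
  for (id in unique(tracks$searcher_id)) {
    ts <- tracks$timestamp[tracks$searcher_id == id]
    if (any(diff(as.numeric(ts)) <= 0))
      stop("timestamps not strictly increasing for searcher ", id)
  }
  invisible(tracks)
}

#' Write tracks to CSV
#' @param tracks data frame as returned by [read_tracks()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- data.frame(
    searcher_id = tracks$searcher_id,
    timestamp = format(tracks$timestamp, "%Y-%m-%dT%H:%M:%S"),
    x_km = tracks$x_km, y_km = tracks$y_km)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rasterize GPS tracks into a per-trap, per-occasion effort covariate
#'
#' Each inter-fix segment's Euclidean length (km) is credited to the trap
#' pixel containing the segment midpoint, on the occasion (calendar day) of
#' the segment's start. Segments spanning midnight are split at the day
#' boundary by linear interpolation. Fixes outside the trap-grid extent are
#' dropped with a warning; total assigned length equals the summed length of
#' segments between retained consecutive fixes.
#'
#' @param tracks data frame of fixes (see [read_tracks()]).
#' @param traps a `trap_grid`.
#' @param occasions ordered `Date` vector defining the sampling occasions;
#'   default spans the dates present in `tracks`. Track days outside
#'   `occasions` are an error.
#' @param max_gap_s consecutive fixes more than this many seconds apart are
#'   treated as separate recording sessions (device switched off between
#'   patrols) and no effort is credited to the gap. Default 3600.
#' @return an `effort_grid`: list with `effort` (J x K matrix, km),
#'   `occasions` (Date vector) and the `traps` grid. The activity mask is
#'   `effort > 0`.
#' @export
rasterize_effort <- function(tracks, traps, occasions = NULL,
                             max_gap_s = 3600) {
  stopifnot(inherits(traps, "trap_grid"))
  validate_tracks(tracks)
  # keep fixes inside the trap grid
  idx <- trap_index(traps, tracks$x_km, tracks$y_km)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " fixes outside the trap grid were dropped")
    tracks <- tracks[!is.na(idx), , drop = FALSE]
  }
  dates <- as.Date(tracks$timestamp, tz = attr(tracks$timestamp, "tzone") %||% "UTC")
  if (is.null(occasions)) {
    occasions <- if (nrow(tracks)) seq(min(dates), max(dates), by = "day")
                 else as.Date(character())
  }
  occasions <- sort(as.Date(occasions))
  K <- length(occasions)
  eff <- matrix(0, nrow = traps$J, ncol = K)
  if (nrow(tracks) >= 2) {
    sid <- tracks$searcher_id
    gap <- diff(as.numeric(tracks$timestamp))
    same <- sid[-length(sid)] == sid[-1] & gap <= max_gap_s
    t0 <- tracks$timestamp[-nrow(tracks)][same]
    t1 <- tracks$timestamp[-1][same]
    x0 <- tracks$x_km[-nrow(tracks)][same]; x1 <- tracks$x_km[-1][same]
    y0 <- tracks$y_km[-nrow(tracks)][same]; y1 <- tracks$y_km[-1][same]
    segs <- split_at_midnight(t0, t1, x0, y0, x1, y1)
    len <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
    mx <- (segs$x0 + segs$x1) / 2
    my <- (segs$y0 + segs$y1) / 2
    day <- as.Date(segs$t0, tz = "UTC")
    k <- match(day, occasions)
    if (anyNA(k))
      stop("track dates outside the occasion calendar: ",
           paste(unique(day[is.na(k)]), collapse = ", "))
    j <- trap_index(traps, mx, my)
    keep <- len > 0
    cell <- (k[keep] - 1L) * traps$J + j[keep]
    add <- tapply(len[keep], cell, sum)
    eff[as.integer(names(add))] <- eff[as.integer(names(add))] + as.numeric(add)
  }
  structure(list(effort = eff, occasions = occasions, traps = traps),
            class = "effort_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split segments crossing midnight at the day boundary (linear interpolation
# in time). Returns vectors t0, x0, y0, x1, y1 of sub-segments.
split_at_midnight <- function(t0, t1, x0, y0, x1, y1) {
  d0 <- as.Date(t0, tz = "UTC"); d1 <- as.Date(t1, tz = "UTC")
  cross <- which(d1 > d0)
  if (!length(cross))
    return(list(t0 = t0, x0 = x0, y0 = y0, x1 = x1, y1 = y1))
  out <- list(t0 = t0[-cross], x0 = x0[-cross], y0 = y0[-cross],
              x1 = x1[-cross], y1 = y1[-cross])
  for (i in cross) {
    # walk day by day through the segment
    a <- as.numeric(t0[i]); b <- as.numeric(t1[i])
    cuts <- as.numeric(as.POSIXct(seq(d0[i] + 1, d1[i], by = "day"),
                                  tz = "UTC"))
    pts <- c(a, cuts, b)
    for (p in seq_len(length(pts) - 1)) {
      fa <- (pts[p] - a) / (b - a); fb <- (pts[p + 1] - a) / (b - a)
      out$t0 <- c(out$t0, as.POSIXct(pts[p], origin = "1970-01-01", tz = "UTC"))
      out$x0 <- c(out$x0, x0[i] + fa * (x1[i] - x0[i]))
      out$y0 <- c(out$y0, y0[i] + fa * (y1[i] - y0[i]))
      out$x1 <- c(out$x1, x0[i] + fb * (x1[i] - x0[i]))
      out$y1 <- c(out$y1, y0[i] + fb * (y1[i] - y0[i]))
    }
  }
  out
}

#' @export
print.effort_grid <- function(x, ...) {
  cat(sprintf(
    "effort_grid: %d traps x %d occasions; %.1f km total effort; %d active trap-days\n",
    nrow(x$effort), ncol(x$effort), sum(x$effort), sum(x$effort > 0)))
  invisible(x)
}

#' Serialize an effort grid as long-format CSV
#'
#' Writes one row per active trap-day: `trap_id`, `occasion`, `effort_km`.
#' Zero cells are implicit.
#'
#' @param effort an `effort_grid`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_effort <- function(effort, path) {
  act <- which(effort$effort > 0, arr.ind = TRUE)
  df <- data.frame(
    trap_id = act[, 1],
    occasion = format(effort$occasions[act[, 2]]),
    effort_km = effort$effort[act])
  df <- df[order(df$occasion, df$trap_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format effort CSV
#'
#' @param path file path.
#' @param traps the `trap_grid` the effort refers to.
#' @param occasions `Date` vector of occasions; default spans the dates in
#'   the file (trailing all-zero occasions are then unrecoverable, so pass
#'   the calendar explicitly when it matters).
#' @return an `effort_grid`.
#' @export
read_effort <- function(path, traps, occasions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trap_id", "occasion", "effort_km")
  if (!all(need %in% names(df)))
    stop("effort CSV must have columns: ", paste(need, collapse = ", "))
  dates <- as.Date(df$occasion)
  if (is.null(occasions)) {
    occasions <- if (nrow(df)) seq(min(dates), max(dates), by = "day")
                 else as.Date(character())
  }
  occasions <- sort(as.Date(occasions))
  k <- match(dates, occasions)
  if (anyNA(k)) stop("effort occasions outside the supplied calendar")
  eff <- matrix(0, nrow = traps$J, ncol = length(occasions))
  eff[cbind(df$trap_id, k)] <- df$effort_km
  structure(list(effort = eff, occasions = occasions, traps = traps),
            class = "effort_grid")
}
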