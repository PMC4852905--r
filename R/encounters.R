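#' Read a sightings CSV
#'
#' Columns: `individual_id`, `sex` (`F`/`M`), `x_km`, `y_km`, `date`
#' (ISO-8601), `time` (optional, `HH:MM:SS`).
#'
#' @param path file path.
#' @return data frame with `individual_id` (character), `sex` (character),
#'   `x_km`, `y_km`, `date` (Date), `time` (character, possibly `NA`).
#' @export
read_sightings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "x_km", "y_km", "date")
  if (!all(need %in% names(df)))
    stop("sightings CSV must have columns: ", paste(need, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$sex <- toupper(as.character(df$sex))
  df$date <- as.Date(df$date)
  if (is.null(df$time)) df$time <- NA_character_
  df
}

#' Write sightings to CSV
#' @param sightings data frame (see [read_sightings()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(sightings, path) {
  out <- sightings[, c("individual_id", "sex", "x_km", "y_km", "date", "time")]
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the binary encounter array from sighting records
#'
#' Converts sightings into the standard SCR individuals x traps x occasions
#' binary structure. Repeated sightings of an individual in the same trap
#' pixel on the same occasion collapse to a single 1 (the observation model
#' is Bernoulli per cell). A detection in a trap-day with zero recorded
#' effort keeps the detection: the searcher was demonstrably there, so a
#' configurable minimum effort (`effort_floor`, km) is imputed in that cell
#' and a warning lists the affected cells.
#'
#' @param sightings data frame (see [read_sightings()]); sex must be `F` or
#'   `M` for every record and constant within individual.
#' @param effort an `effort_grid` (carries its `trap_grid` and occasion
#'   calendar).
#' @param effort_floor km of effort imputed where a detection occurred with
#'   no recorded effort (default 0.1).
#' @return an `encounter_data` object: `det` (data frame `ind`, `trap`,
#'   `occ` of 1-cells), `n`, `ids`, `sex` (0 = female, 1 = male, per
#'   individual), the possibly floored `effort` grid, and `floored` (data
#'   frame of imputed cells).
#' @export
build_encounter_array <- function(sightings, effort, effort_floor = 0.1) {
  stopifnot(inherits(effort, "effort_grid"))
  if (nrow(sightings) == 0) stop("no detected individuals: empty sighting list")
  if (!all(sightings$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M' for all detected individuals (unsexed records rejected)")
  traps <- effort$traps
  j <- trap_index(traps, sightings$x_km, sightings$y_km)
  if (anyNA(j)) {
    bad <- which(is.na(j))
    stop("sightings outside the trap grid: records ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  k <- match(as.Date(sightings$date), effort$occasions)
  if (anyNA(k))
    stop("sighting dates outside the occasion calendar: records ",
         paste(utils::head(which(is.na(k)), 10), collapse = ", "))
  ids <- sort(unique(sightings$individual_id))
  sexm <- integer(length(ids))
  for (a in seq_along(ids)) {
    sx <- unique(sightings$sex[sightings$individual_id == ids[a]])
    if (length(sx) > 1)
      stop("conflicting sex labels for individual ", ids[a])
    sexm[a] <- as.integer(sx == "M")
  }
  i <- match(sightings$individual_id, ids)
  det <- unique(data.frame(ind = i, trap = j, occ = k))
  det <- det[order(det$ind, det$occ, det$trap), ]
  rownames(det) <- NULL
  # effort floor for detections in cells with no recorded effort
  cell <- cbind(det$trap, det$occ)
  noeff <- effort$effort[cell] == 0
  floored <- data.frame(trap = integer(), occ = integer())
  if (any(noeff)) {
    floored <- unique(data.frame(trap = det$trap[noeff], occ = det$occ[noeff]))
    effort$effort[as.matrix(floored)] <- effort_floor
    warning(nrow(floored), " trap-days had detections but no recorded ",
            "effort; floored to ", effort_floor, " km")
  }
  structure(
    list(det = det, n = length(ids), ids = ids, sex = sexm,
         effort = effort, floored = floored),
    class = "encounter_data")
}

#' @export
print.encounter_data <- function(x, ...) {
  cat(sprintf(
    "encounter_data: %d individuals (%d F, %d M), %d detection cells over %d traps x %d occasions\n",
    x$n, sum(x$sex == 0), sum(x$sex == 1), nrow(x$det),
    nrow(x$effort$effort), ncol(x$effort$effort)))
  invisible(x)
}

#' Expand encounter data to a dense 3-D array
#'
#' @param enc an `encounter_data`.
#' @return binary array of dimension `n x J x K`.
#' @export
encounter_array <- function(enc) {
  stopifnot(inherits(enc, "encounter_data"))
  J <- nrow(enc$effort$effort); K <- ncol(enc$effort$effort)
  y <- array(0L, dim = c(enc$n, J, K))
  y[as.matrix(enc$det)] <- 1L
  y
}

#' Serialize encounter data as long-format CSV
#'
#' One row per 1-cell (`individual_id`, `trap_id`, `occasion`) plus a
#' companion sex table written alongside (`<path>` with suffix `_sex.csv`
#' unless `sex_path` is given).
#'
#' @param enc an `encounter_data`.
#' @param path file path for the 1-cell table.
#' @param sex_path file path for the sex table.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(enc, path,
                             sex_path = sub("\\.csv$", "_sex.csv", path)) {
  df <- data.frame(
    individual_id = enc$ids[enc$det$ind],
    trap_id = enc$det$trap,
    occasion = format(enc$effort$occasions[enc$det$occ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(individual_id = enc$ids, sex = c("F", "M")[enc$sex + 1]),
    sex_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read encounter data written by [write_encounters()]
#'
#' @param path 1-cell table path.
#' @param effort the `effort_grid` the encounters refer to (defines traps
#'   and the occasion calendar).
#' @param sex_path sex table path.
#' @return an `encounter_data`.
#' @export
read_encounters <- function(path, effort,
                            sex_path = sub("\\.csv$", "_sex.csv", path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sx <- utils::read.csv(sex_path, stringsAsFactors = FALSE)
  ids <- sort(unique(sx$individual_id))
  det <- data.frame(
    ind = match(df$individual_id, ids),
    trap = df$trap_id,
    occ = match(as.Date(df$occasion), effort$occasions))
  if (anyNA(det$ind) || anyNA(det$occ))
    stop("encounter table inconsistent with the sex table or calendar")
  det <- det[order(det$ind, det$occ, det$trap), ]
  rownames(det) <- NULL
  structure(
    list(det = det, n = length(ids), ids = ids,
         sex = as.integer(sx$sex[match(ids, sx$individual_id)] == "M"),
         effort = effort,
         floored = data.frame(trap = integer(), occ = integer())),
    class = "encounter_data")
}

#' Mean maximum distance moved (MMDM)
#'
#' The per-individual statistic is the maximum pairwise Euclidean distance
#' among that individual's sighting locations (0 for a single sighting); the
#' group value is the arithmetic mean over individuals. A coarse index of
#' movement range used to set the state-space buffer and to compare male and
#' female ranging behaviour.
#'
#' @param sightings data frame (see [read_sightings()]).
#' @param group `"all"` for a single pooled mean, `"sex"` for per-sex means.
#' @return list with `mmdm` (named numeric) and `individual` (data frame
#'   `individual_id`, `sex`, `max_dist_km`).
#' @export
mmdm <- function(sightings, group = c("all", "sex")) {
  group <- match.arg(group)
  if (nrow(sightings) == 0) stop("no sightings")
  ids <- unique(sightings$individual_id)
  per <- vapply(ids, function(id) {
    p <- sightings[sightings$individual_id == id, c("x_km", "y_km")]
    if (nrow(p) < 2) return(0)
    max(stats::dist(p))
  }, numeric(1))
  sex <- sightings$sex[match(ids, sightings$individual_id)]
  ind <- data.frame(individual_id = ids, sex = sex, max_dist_km = as.numeric(per))
  m <- if (group == "all") c(all = mean(per))
       else tapply(per, sex, mean)
  list(mmdm = m, individual = ind)
}
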