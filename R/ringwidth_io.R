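#' A single tree's ring-width series
#'
#' Annual ring widths (mm) with calendar alignment and optional pith
#' geometry. Widths must be positive; missing rings may be encoded as
#' exactly 0 only when `allow_missing_rings = TRUE`.
#'
#' @param tree_id series identifier (max 8 characters for .rwl export).
#' @param species `"black_spruce"` or `"trembling_aspen"`.
#' @param stand_type `"PBS"`, `"M"` or `"PTA"`.
#' @param first_year calendar year of the innermost measured ring.
#' @param widths numeric vector of ring widths in mm, one per consecutive
#'   year.
#' @param has_pith TRUE if the innermost ring is at the pith.
#' @param arc_chord_mm,arc_height_mm optional chord and height of the
#'   innermost ring's visible arc (mm), used for distance-to-pith
#'   estimation.
#' @param est_pith_offset_mm optional externally estimated pith offset.
#' @param allow_missing_rings permit zero widths (flagged missing rings).
#' @return object of class `ring_width_series`.
#' @export
ring_width_series <- function(tree_id, species, stand_type, first_year,
                              widths, has_pith = FALSE,
                              arc_chord_mm = NA_real_,
                              arc_height_mm = NA_real_,
                              est_pith_offset_mm = NA_real_,
                              allow_missing_rings = FALSE) {
  stopifnot(is.character(tree_id), length(tree_id) == 1L, nzchar(tree_id))
  species <- match.arg(species, c("black_spruce", "trembling_aspen"))
  stand_type <- match.arg(stand_type, stand_types())
  widths <- as.numeric(widths)
  if (length(widths) == 0L) stop("widths must be nonempty")
  if (any(!is.finite(widths))) stop("widths must be finite")
  if (allow_missing_rings) {
    if (any(widths < 0)) stop("widths must be >= 0")
  } else if (any(widths <= 0)) {
    stop("widths must be > 0 (set allow_missing_rings for zero-width rings)")
  }
  if (!is.na(arc_height_mm) && arc_height_mm <= 0)
    stop("arc height must be > 0")
  if (!is.na(arc_chord_mm) && arc_chord_mm <= 0)
    stop("arc chord must be > 0")
  structure(list(tree_id = tree_id, species = species,
                 stand_type = stand_type,
                 first_year = as.integer(first_year), widths = widths,
                 has_pith = isTRUE(has_pith),
                 arc_chord_mm = arc_chord_mm, arc_height_mm = arc_height_mm,
                 est_pith_offset_mm = est_pith_offset_mm),
            class = "ring_width_series")
}

#' @export
print.ring_width_series <- function(x, ...) {
  cat(sprintf("<ring_width_series %s: %s/%s, %d rings %d-%d, pith %s>\n",
              x$tree_id, x$species, x$stand_type, length(x$widths),
              x$first_year, x$first_year + length(x$widths) - 1L,
              if (x$has_pith) "present" else "absent"))
  invisible(x)
}

series_years <- function(s) s$first_year + seq_along(s$widths) - 1L

#' Write ring-width series in Tucson (.rwl) decadal format
#'
#' Default dialect stores widths as integers in 0.01 mm units with series
#' terminator 999; `precision = 0.001` uses 0.001 mm units with terminator
#' -9999 (the two dominant dialects in circulation).
#'
#' @param series list of [ring_width_series()] objects.
#' @param path output file.
#' @param precision storage unit in mm: 0.01 (default) or 0.001.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path, precision = 0.01) {
  if (!precision %in% c(0.01, 0.001))
    stop("precision must be 0.01 or 0.001")
  terminator <- if (precision == 0.01) 999L else -9999L
  lines <- character(0)
  for (s in series) {
    if (nchar(s$tree_id) > 8L)
      stop("tree_id longer than 8 characters: ", s$tree_id)
    vals <- as.integer(round(s$widths / precision))
    yrs <- series_years(s)
    payload <- c(vals, terminator)
    pyrs <- c(yrs, max(yrs) + 1L)
    decade <- pyrs %/% 10L
    for (d in unique(decade)) {
      sel <- decade == d
      line <- sprintf("%-8s%4d%s", s$tree_id, pyrs[sel][1],
                      paste0(sprintf("%6d", payload[sel]), collapse = ""))
      lines <- c(lines, line)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ring-width series from a Tucson (.rwl) file
#'
#' The storage dialect is auto-detected from the series terminator: 999
#' means 0.01 mm integer units, -9999 means 0.001 mm units. Malformed
#' decade lines or non-monotone year runs raise an error naming the line.
#'
#' @param path .rwl file path.
#' @param metadata optional data.frame (tree_id, species, stand_type) to
#'   attach; otherwise species/stand default to black_spruce/PBS.
#' @param allow_missing_rings passed through to [ring_width_series()].
#' @return list of [ring_width_series()] objects.
#' @export
read_rwl <- function(path, metadata = NULL, allow_missing_rings = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  order_seen <- character(0)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 3L)
      stop("malformed decade line ", i, " in ", path)
    id <- toks[1]
    year <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.integer(toks[-(1:2)]))
    if (is.na(year) || any(is.na(vals)))
      stop("malformed decade line ", i, " in ", path)
    if (is.null(recs[[id]])) {
      recs[[id]] <- list(years = integer(0), vals = integer(0))
      order_seen <- c(order_seen, id)
    } else {
      expected <- recs[[id]]$years[length(recs[[id]]$years)] + 1L
      if (year != expected)
        stop("non-monotone years for series ", id, " at line ", i,
             " (expected ", expected, ", got ", year, ")")
    }
    recs[[id]]$years <- c(recs[[id]]$years, year + seq_along(vals) - 1L)
    recs[[id]]$vals <- c(recs[[id]]$vals, vals)
  }
  out <- vector("list", length(order_seen))
  names(out) <- order_seen
  for (id in order_seen) {
    vals <- recs[[id]]$vals
    yrs <- recs[[id]]$years
    term <- vals[length(vals)]
    if (term == 999L) precision <- 0.01
    else if (term == -9999L) precision <- 0.001
    else stop("series ", id, " lacks a recognized terminator (999/-9999)")
    vals <- vals[-length(vals)]
    yrs <- yrs[-length(yrs)]
    meta <- lookup_meta(metadata, id)
    out[[id]] <- ring_width_series(
      tree_id = id, species = meta$species, stand_type = meta$stand_type,
      first_year = yrs[1], widths = vals * precision,
      has_pith = meta$has_pith, arc_chord_mm = meta$arc_chord_mm,
      arc_height_mm = meta$arc_height_mm,
      allow_missing_rings = allow_missing_rings)
  }
  unname(out)
}

lookup_meta <- function(metadata, id) {
  out <- list(species = "black_spruce", stand_type = "PBS",
              has_pith = FALSE, arc_chord_mm = NA_real_,
              arc_height_mm = NA_real_)
  if (!is.null(metadata) && id %in% metadata$tree_id) {
    row <- metadata[metadata$tree_id == id, , drop = FALSE][1, ]
    out$species <- row$species
    out$stand_type <- row$stand_type
    for (f in c("has_pith", "arc_chord_mm", "arc_height_mm"))
      if (!is.null(row[[f]])) out[[f]] <- row[[f]]
  }
  out
}

#' Write/read ring widths as a long-form CSV
#'
#' Lossless round trip of (tree_id, year, width_mm); the reader rejects
#' duplicate (tree_id, year) rows and non-consecutive year runs rather than
#' silently repairing them.
#'
#' @param series list of [ring_width_series()] objects.
#' @param path CSV path.
#' @return `path` (write) or list of series (read).
#' @export
write_long_csv <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(tree_id = s$tree_id, year = series_years(s),
               width_mm = s$widths))
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(tree_id = character(0), year = integer(0),
                  width_mm = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_long_csv
#' @param metadata optional metadata data.frame to join on tree_id.
#' @param allow_missing_rings permit zero widths.
#' @export
read_long_csv <- function(path, metadata = NULL,
                          allow_missing_rings = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "year", "width_mm")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns tree_id, year, width_mm")
  if (nrow(df) == 0L) return(list())
  if (anyDuplicated(df[, c("tree_id", "year")]))
    stop("duplicate (tree_id, year) rows in ", path)
  out <- list()
  for (id in unique(df$tree_id)) {
    sub <- df[df$tree_id == id, ]
    sub <- sub[order(sub$year), ]
    if (!all(diff(sub$year) == 1L))
      stop("non-consecutive years for series ", id, " in ", path)
    meta <- lookup_meta(metadata, id)
    out[[length(out) + 1L]] <- ring_width_series(
      tree_id = id, species = meta$species, stand_type = meta$stand_type,
      first_year = sub$year[1], widths = sub$width_mm,
      has_pith = meta$has_pith, arc_chord_mm = meta$arc_chord_mm,
      arc_height_mm = meta$arc_height_mm,
      allow_missing_rings = allow_missing_rings)
  }
  out
}

#' Read/write the tree metadata table
#'
#' Columns: tree_id (unique), species, stand_type, optional dbh_cm.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tree_id", "species", "stand_type") %in% names(df)))
    stop("metadata CSV must have tree_id, species, stand_type")
  if (anyDuplicated(df$tree_id)) stop("tree_id must be unique")
  if (!all(df$stand_type %in% stand_types()))
    stop("stand_type must be one of PBS, M, PTA")
  df
}

#' @rdname read_metadata_csv
#' @param metadata data.frame to write.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Metadata table of a series collection
#'
#' Carries species, stand type, and the pith information (pith flag and
#' innermost-ring arc geometry) that the width formats themselves cannot
#' store, so that file round trips preserve distance-to-pith estimation.
#'
#' @param series list of [ring_width_series()].
#' @return data.frame(tree_id, species, stand_type, has_pith,
#'   arc_chord_mm, arc_height_mm).
#' @export
series_metadata <- function(series) {
  do.call(rbind, lapply(series, function(s)
    data.frame(tree_id = s$tree_id, species = s$species,
               stand_type = s$stand_type, has_pith = s$has_pith,
               arc_chord_mm = s$arc_chord_mm,
               arc_height_mm = s$arc_height_mm)))
}
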