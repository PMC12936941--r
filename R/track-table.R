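# Track-table data model: one row per cell per frame, the interchange
# format consumed by every downstream stage.

#' Track-table column schema
#'
#' Column order of the track CSV interchange format. Coordinates are
#' chamber-local micrometers with the origin at the chamber corner adjacent
#' to the main feeding channel; frames are 0-based and
#' `time_h = frame * frame_interval_min / 60`.
#'
#' @format A character vector of the ten required column names.
#' @export
track_columns <- c(
  "replicate_id", "chamber_id", "frame", "time_h", "track_id",
  "cell_type", "x_um", "y_um", "length_um", "area_um2"
)

.track_numeric_cols <- c("frame", "time_h", "track_id", "x_um", "y_um",
                         "length_um", "area_um2")

#' Construct a validated track table
#'
#' Coerces a data frame to the track-table schema, sorts rows by
#' (replicate, chamber, track, frame) and optionally validates every
#' schema invariant (see [validate_tracks()]).
#'
#' @param df data frame with the columns listed in [track_columns]
#'   (case-insensitive names; extra columns are dropped).
#' @param chamber_side_um chamber side length in micrometers used for the
#'   coordinate-bounds check (default 40).
#' @param validate if `TRUE` (default) stop on any invariant violation.
#' @return a `data.frame` with class `track_table`, columns in schema order.
#' @export
track_table <- function(df, chamber_side_um = 40, validate = TRUE) {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(track_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste0("'", missing_cols, "'", collapse = ", ")),
         call. = FALSE)
  }
  df <- df[track_columns]
  df$replicate_id <- as.character(df$replicate_id)
  df$chamber_id <- as.character(df$chamber_id)
  df$cell_type <- as.character(df$cell_type)
  for (col in .track_numeric_cols) {
    if (!is.numeric(df[[col]])) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad) > 0L) {
        stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                     col, bad[1L]), call. = FALSE)
      }
      df[[col]] <- v
    }
  }
  df$frame <- as.integer(df$frame)
  df$track_id <- as.integer(df$track_id)
  ord <- order(df$replicate_id, df$chamber_id, df$track_id, df$frame)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("track_table", "data.frame")
  if (validate) {
    rep <- validate_tracks(df, chamber_side_um = chamber_side_um)
    if (nrow(rep) > 0L) {
      stop(sprintf("validation error: %d invariant violation(s); first: [%s] %s",
                   nrow(rep), rep$rule[1L], rep$detail[1L]), call. = FALSE)
    }
  }
  df
}

.track_key <- function(table) {
  paste(table$replicate_id, table$chamber_id, table$track_id, sep = "\r")
}

#' Validate a track table
#'
#' Checks every schema invariant and reports each violation instead of
#' stopping: key uniqueness, consecutive frames within tracks, constant
#' cell type within tracks, the `{WT, AUX}` type vocabulary, positive
#' lengths/areas, non-negative frames and chamber-bounded coordinates.
#'
#' @param table data frame in the track schema.
#' @param chamber_side_um chamber side length in micrometers (default 40).
#' @return a data frame with columns `rule`, `detail`, `rows` (a row-index
#'   reference into `table`); zero rows if and only if the table is valid.
#' @export
validate_tracks <- function(table, chamber_side_um = 40) {
  check_number(chamber_side_um, "chamber_side_um", positive = TRUE)
  report <- list()
  add <- function(rule, detail, rows) {
    report[[length(report) + 1L]] <<- data.frame(
      rule = rule, detail = detail,
      rows = paste(utils::head(rows, 10L), collapse = ","),
      stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(track_columns, names(table))
  if (length(missing_cols) > 0L) {
    add("schema", sprintf("missing column(s) %s",
                          paste(missing_cols, collapse = ", ")), integer(0))
    return(do.call(rbind, report))
  }
  n <- nrow(table)
  if (n == 0L) {
    return(data.frame(rule = character(0), detail = character(0),
                      rows = character(0), stringsAsFactors = FALSE))
  }

  bad_type <- which(!(table$cell_type %in% c("WT", "AUX")))
  if (length(bad_type) > 0L) {
    add("cell_type_vocabulary", "cell_type outside {WT, AUX}", bad_type)
  }
  bad_frame <- which(!is.finite(table$frame) | table$frame < 0)
  if (length(bad_frame) > 0L) {
    add("frame_nonnegative", "negative or missing frame", bad_frame)
  }
  bad_len <- which(!is.finite(table$length_um) | table$length_um <= 0)
  if (length(bad_len) > 0L) {
    add("length_positive", "length_um must be > 0", bad_len)
  }
  bad_area <- which(!is.finite(table$area_um2) | table$area_um2 <= 0)
  if (length(bad_area) > 0L) {
    add("area_positive", "area_um2 must be > 0", bad_area)
  }
  bad_xy <- which(table$x_um < 0 | table$x_um > chamber_side_um |
                    table$y_um < 0 | table$y_um > chamber_side_um)
  if (length(bad_xy) > 0L) {
    add("coordinates_in_chamber",
        sprintf("x_um/y_um outside [0, %g]", chamber_side_um), bad_xy)
  }

  key <- paste(.track_key(table), table$frame, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    add("key_unique", "duplicate (replicate, chamber, track, frame)", dup)
  }

  trk <- .track_key(table)
  ord <- order(trk, table$frame)
  fr <- table$frame[ord]
  same <- trk[ord][-1L] == trk[ord][-n]
  if (n > 1L) {
    gap <- which(same & (fr[-1L] - fr[-n]) != 1L & (fr[-1L] - fr[-n]) != 0L)
    if (length(gap) > 0L) {
      add("frames_consecutive", "frame gap within track (split with split_track_gaps)",
          ord[gap + 1L])
    }
    flip <- which(same & table$cell_type[ord][-1L] != table$cell_type[ord][-n])
    if (length(flip) > 0L) {
      add("cell_type_constant", "cell_type changes within track", ord[flip + 1L])
    }
  }
  if (length(report) == 0L) {
    return(data.frame(rule = character(0), detail = character(0),
                      rows = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}

#' Split tracks at frame gaps
#'
#' A track whose frames are not consecutive is split into maximal runs of
#' consecutive frames, each run becoming its own track. The first run keeps
#' the original `track_id`; later runs get fresh ids above the current
#' maximum within their (replicate, chamber). The growth fit and the
#' minimum-frames filter are defined on consecutive frames, so gapped
#' observations must never be fit as one lifetime.
#'
#' @param table data frame in the track schema.
#' @return the table with gap-free tracks, sorted in key order.
#' @export
split_track_gaps <- function(table) {
  stopifnot(is.data.frame(table))
  trk <- .track_key(table)
  ord <- order(trk, table$frame)
  table <- table[ord, , drop = FALSE]
  trk <- trk[ord]
  n <- nrow(table)
  if (n == 0L) return(table)
  new_track <- c(TRUE, trk[-1L] != trk[-n])
  # only true gaps (missing frames) split; duplicated frames are left for
  # validation to reject
  gap <- c(FALSE, (table$frame[-1L] - table$frame[-n]) > 1L) & !new_track
  seg <- cumsum(new_track | gap)           # global segment id
  # segments that start a new (sub)track beyond the first run need fresh ids
  chamber <- paste(table$replicate_id, table$chamber_id, sep = "\r")
  needs_id <- gap
  if (any(needs_id)) {
    for (ch in unique(chamber[needs_id])) {
      in_ch <- chamber == ch
      next_id <- max(table$track_id[in_ch]) + 1L
      seg_ids <- unique(seg[needs_id & in_ch])
      new_ids <- seq.int(next_id, length.out = length(seg_ids))
      idx <- in_ch & seg %in% seg_ids
      table$track_id[idx] <- new_ids[match(seg[idx], seg_ids)]
    }
  }
  ord <- order(table$replicate_id, table$chamber_id, table$track_id, table$frame)
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  table
}

#' Read a track table from delimited text
#'
#' Reads a comma-separated (by default) track file with a mandatory header,
#' checks the schema, optionally splits tracks at frame gaps, and validates
#' all invariants.
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter (default `","`).
#' @param split_gaps split tracks with missing frames into consecutive runs
#'   (default `TRUE`).
#' @param chamber_side_um chamber side length for coordinate validation.
#' @return a validated [track_table()].
#' @export
read_tracks <- function(path, sep = ",", split_gaps = TRUE,
                        chamber_side_um = 40) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(track_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste0("'", missing_cols, "'", collapse = ", ")),
         call. = FALSE)
  }
  if (split_gaps && nrow(df) > 0L) {
    df <- track_table(df, chamber_side_um = chamber_side_um, validate = FALSE)
    df <- split_track_gaps(df)
  }
  track_table(df, chamber_side_um = chamber_side_um, validate = TRUE)
}

#' Write a track table to delimited text
#'
#' Writes CSV with full double precision (17 significant digits) so that
#' `read_tracks(write_tracks(t))` reproduces `t` exactly.
#'
#' @param table a track table (validated before writing).
#' @param path output file path.
#' @param sep field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(table, path, sep = ",") {
  rep <- validate_tracks(table)
  if (nrow(rep) > 0L) {
    stop(sprintf("refusing to write invalid table: [%s] %s",
                 rep$rule[1L], rep$detail[1L]), call. = FALSE)
  }
  out <- table[track_columns]
  for (col in c("time_h", "x_um", "y_um", "length_um", "area_um2")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
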