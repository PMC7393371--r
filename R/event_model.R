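#' Read a frame-scored behavioural event log
#'
#' Reads copulation and suck events scored from 2-h mating movies filmed at
#' 1 frame per second, so times are integer seconds. Candidate copulations
#' shorter than 5 s are not copulations under the scoring definition (the
#' pair must stay interlinked for at least 5 s) and are rejected at ingest
#' with a warning, never silently kept.
#'
#' @param path Path to a CSV or TSV event log. Expected columns:
#'   `record_id`, `record_kind` (`"pair"` or `"drop"`), `pairing_type`
#'   (blank for drops), `event_kind` (`"copulation"` or `"suck"`),
#'   `actor_a`, `actor_b`, `start_s`, `end_s`, `copulation_type`
#'   (`LL`/`LJ`/`JJ`/`NA`), `preceding_copulation_index` (optional).
#' @param schema Either `"pair"` (within-pair observations; copulation type
#'   is unknown under transmitted light and must be `NA`) or `"drop"`
#'   (mate-choice arenas with dyed worms; every copulation must be typed).
#' @param window_s Length of the observation window in seconds. Events must
#'   end inside it. Default 7200 (2 h).
#'
#' @return A tibble of validated events, sorted by `record_id` then
#'   `start_s`, one row per event, with the columns listed above.
#' @export
#'
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_event_log(sim_pair_logs(sim_params(n_pairs = 2))[1:8, ], path)
#' read_event_log(path, schema = "pair")
read_event_log <- function(path, schema = c("pair", "drop"), window_s = 7200) {
  schema <- match.arg(schema)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      record_id = readr::col_character(),
      record_kind = readr::col_character(),
      pairing_type = readr::col_character(),
      event_kind = readr::col_character(),
      actor_a = readr::col_character(),
      actor_b = readr::col_character(),
      start_s = readr::col_integer(),
      end_s = readr::col_integer(),
      copulation_type = readr::col_character(),
      preceding_copulation_index = readr::col_integer()
    )
  )
  required <- c("record_id", "record_kind", "event_kind",
                "start_s", "end_s", "copulation_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("event log is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"pairing_type" %in% names(raw)) raw$pairing_type <- NA_character_
  if (!"actor_a" %in% names(raw)) raw$actor_a <- NA_character_
  if (!"actor_b" %in% names(raw)) raw$actor_b <- NA_character_
  if (!"preceding_copulation_index" %in% names(raw)) {
    raw$preceding_copulation_index <- NA_integer_
  }
  validate_event_log(raw, schema = schema, window_s = window_s)
}

#' Validate an in-memory event table
#'
#' Applies the same checks as [read_event_log()]: integer-second times
#' inside the observation window, `end_s > start_s`, the 5-s minimum
#' copulation duration (sub-5-s rows are dropped with a warning), no
#' overlapping copulations within a record, and schema-dependent typing of
#' copulations.
#'
#' @param events A data frame of events (see [read_event_log()] for
#'   columns).
#' @inheritParams read_event_log
#' @return A validated, sorted tibble of events.
#' @export
validate_event_log <- function(events, schema = c("pair", "drop"),
                               window_s = 7200) {
  schema <- match.arg(schema)
  ev <- tibble::as_tibble(events)

  bad_row <- which(is.na(ev$start_s) | is.na(ev$end_s) |
                     is.na(ev$record_id) | is.na(ev$event_kind))
  if (length(bad_row) > 0) {
    abort(paste0("malformed event row(s): ",
                 paste(head(bad_row, 5L), collapse = ", "),
                 " (missing record_id, event_kind, start_s or end_s)"))
  }
  bad_kind <- !ev$event_kind %in% c("copulation", "suck")
  if (any(bad_kind)) {
    abort(paste0("unknown event_kind in row(s): ",
                 paste(head(which(bad_kind), 5L), collapse = ", ")))
  }
  rev_time <- ev$end_s < ev$start_s
  if (any(rev_time)) {
    abort(paste0("end_s < start_s in row(s): ",
                 paste(head(which(rev_time), 5L), collapse = ", ")))
  }
  if (any(ev$start_s < 0)) {
    abort("negative start_s: events must start inside the observation window")
  }
  if (any(ev$end_s > window_s)) {
    abort(paste0("event end_s exceeds the ", window_s, " s observation window"))
  }

  # 5-s rule: an interlinked posture shorter than 5 s is not a copulation.
  is_cop <- ev$event_kind == "copulation"
  short <- is_cop & (ev$end_s - ev$start_s) < 5L
  if (any(short)) {
    warn(paste0(sum(short), " candidate copulation(s) below 5 s minimum ",
                "duration rejected (row(s) ",
                paste(head(which(short), 5L), collapse = ", "), ")"))
    ev <- ev[!short, , drop = FALSE]
    is_cop <- ev$event_kind == "copulation"
  }

  if (schema == "drop") {
    untyped <- is_cop & (is.na(ev$copulation_type) |
                           !ev$copulation_type %in% COPULATION_TYPES)
    if (any(untyped)) {
      abort(paste0("drop logs require every copulation typed LL/LJ/JJ; ",
                   sum(untyped), " untyped row(s)"))
    }
  } else {
    typed <- is_cop & ev$copulation_type %in% COPULATION_TYPES
    if (any(typed)) {
      abort(paste0("pair logs cannot carry copulation types (species are ",
                   "indistinguishable under transmitted light); found ",
                   sum(typed), " typed row(s)"))
    }
    bad_pt <- !is.na(ev$pairing_type) & !ev$pairing_type %in% PAIRING_TYPES
    if (any(bad_pt)) {
      abort(paste0("unknown pairing_type: ",
                   paste(unique(ev$pairing_type[bad_pt]), collapse = ", ")))
    }
  }

  ev <- dplyr::arrange(ev, .data$record_id, .data$start_s, .data$end_s)

  # Overlapping copulations are physically impossible for one pair. In a
  # pair log the record is the pair; in a drop, disjoint pairs may mate
  # simultaneously, so the check is per individual.
  cops <- ev[ev$event_kind == "copulation", , drop = FALSE]
  if (nrow(cops) > 1) {
    if (schema == "pair") {
      overlap <- cops |>
        dplyr::group_by(.data$record_id) |>
        dplyr::summarise(
          bad = dplyr::n() > 1 &&
            any(.data$start_s[-1] < head(.data$end_s, -1)),
          .groups = "drop"
        )
      if (any(overlap$bad)) {
        abort(paste0("overlapping copulations within record(s): ",
                     paste(overlap$record_id[overlap$bad], collapse = ", ")))
      }
    } else {
      long <- dplyr::bind_rows(
        dplyr::transmute(cops, .data$record_id, actor = .data$actor_a,
                         .data$start_s, .data$end_s),
        dplyr::transmute(cops, .data$record_id, actor = .data$actor_b,
                         .data$start_s, .data$end_s)
      ) |>
        dplyr::filter(!is.na(.data$actor)) |>
        dplyr::arrange(.data$record_id, .data$actor, .data$start_s)
      overlap <- long |>
        dplyr::group_by(.data$record_id, .data$actor) |>
        dplyr::summarise(
          bad = dplyr::n() > 1 &&
            any(.data$start_s[-1] < head(.data$end_s, -1)),
          .groups = "drop"
        )
      if (any(overlap$bad)) {
        abort(paste0("individual in overlapping copulations in record(s): ",
                     paste(unique(overlap$record_id[overlap$bad]),
                           collapse = ", ")))
      }
    }
  }
  ev
}

#' Write an event log to CSV
#'
#' Inverse of [read_event_log()]: writing and re-reading reproduces the
#' event table field for field.
#'
#' @param events An event tibble as returned by [read_event_log()] or the
#'   simulators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path, progress = FALSE)
  invisible(path)
}

#' Filter mate-choice drops on their exclusion flags
#'
#' Drops flagged as excluded (injured worm, dim lighting, other) are
#' removed; the tally of exclusions by reason is reported as a message. In
#' the original experiment 9 of 68 filmed drops were excluded (5 injured,
#' 4 dim lighting), leaving 59 analysable drops.
#'
#' @param drop_meta A data frame with columns `drop_id`, `excluded`
#'   (0/1 or logical) and `exclusion_reason` (required non-missing for
#'   excluded drops), plus any other metadata columns.
#' @param quiet Suppress the exclusion tally message.
#' @return The retained rows as a tibble. Idempotent: filtering an already
#'   filtered table is the identity.
#' @export
filter_drops <- function(drop_meta, quiet = FALSE) {
  dm <- tibble::as_tibble(drop_meta)
  if (!all(c("drop_id", "excluded") %in% names(dm))) {
    abort("drop metadata needs columns drop_id and excluded")
  }
  excl <- as.logical(dm$excluded)
  excl[is.na(excl)] <- FALSE
  if (any(excl)) {
    if (!"exclusion_reason" %in% names(dm) ||
        any(is.na(dm$exclusion_reason[excl]) |
              dm$exclusion_reason[excl] == "")) {
      abort("excluded drops must carry an exclusion_reason")
    }
    if (!quiet) {
      tally <- table(dm$exclusion_reason[excl])
      inform(paste0("excluded ", sum(excl), " of ", nrow(dm), " drops (",
                    paste(names(tally), tally, sep = ": ", collapse = ", "),
                    ")"))
    }
  }
  dm[!excl, , drop = FALSE]
}
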