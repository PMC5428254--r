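#' Write a table as commented CSV
#'
#' All tables are CSV with ISO-8601 dates; per-mil values for deltas and
#' mol O/d for fluxes. Comment lines starting with `#` record the config
#' hash and seed so every file can be traced to the run that produced it.
#'
#' @param x data.frame.
#' @param path output file.
#' @param config optional `isocow_config`; its hash and seed go into the
#'   header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# written by isocow ",
                    as.character(utils::packageVersion("isocow"))), con)
  if (!is.null(config)) {
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
    writeLines(paste0("# seed: ", config$seed), con)
  }
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a commented CSV written by [write_table()]
#'
#' @param path file path.
#' @return data.frame; a `date` column, if present, is parsed to `Date`.
#' @export
read_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#")
  if ("date" %in% names(x)) {
    x$date <- as.Date(x$date)
  }
  if ("keeping" %in% names(x)) {
    x$keeping <- as.character(x$keeping)
  }
  x
}

#' Write a driver bundle to a directory
#'
#' Writes `weather.csv`, `isotopes.csv`, `calendar.csv` and
#' `leaf_diurnal.csv` (long format: date, hour 0-23, delta).
#'
#' @param drivers bundle from [gen_drivers()].
#' @param dir output directory (created if missing).
#' @param config optional config recorded in the headers.
#' @return `dir`, invisibly.
#' @export
write_driver_tables <- function(drivers, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(drivers$weather, file.path(dir, "weather.csv"), config)
  write_table(drivers$isotopes, file.path(dir, "isotopes.csv"), config)
  write_table(drivers$calendar, file.path(dir, "calendar.csv"), config)
  write_table(drivers$leaf_diurnal, file.path(dir, "leaf_diurnal.csv"),
              config)
  invisible(dir)
}

#' Read a driver bundle from a directory
#'
#' Counterpart of [write_driver_tables()]; user-supplied tables with the
#' same headers are accepted. The leaf diurnal table is re-ordered by date
#' and hour.
#'
#' @param dir directory holding the four CSVs.
#' @return driver bundle list.
#' @export
read_driver_tables <- function(dir) {
  need <- c("weather", "isotopes", "calendar", "leaf_diurnal")
  paths <- file.path(dir, paste0(need, ".csv"))
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("missing driver table(s): ", paste(missing, collapse = ", "))
  }
  b <- lapply(paths, read_table)
  names(b) <- need
  b$calendar$lactating <- as.logical(b$calendar$lactating)
  b$calendar$calf_age <- as.numeric(b$calendar$calf_age)
  b$leaf_diurnal <- b$leaf_diurnal[order(b$leaf_diurnal$date,
                                         b$leaf_diurnal$hour), ]
  rownames(b$leaf_diurnal) <- NULL
  b
}
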