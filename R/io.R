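#' Read a formulation design/response table
#'
#' CSV with a header row naming every configured factor and response
#' (comma separator, dot decimal, UTF-8). An optional `run` column
#' supplies run labels; otherwise rows are numbered. Row order is
#' preserved. Response values are validated against the bounds declared
#' in each [response_def()].
#'
#' @param path CSV file path.
#' @param config A [study_config()].
#' @return Data frame with columns `run`, the factors (actual units) and
#'   the responses; zero rows for a header-only file.
#' @examples
#' runs <- read_design_table(
#'   system.file("extdata", "nlc_formulation_runs.csv",
#'               package = "nose2brain"),
#'   berberine_config()
#' )
#' nrow(runs) # 17
#' @export
read_design_table <- function(path, config) {
  stopifnot(inherits(config, "study_config"))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  needed <- c(names(config$factors), names(config$responses))
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("design table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    run = if ("run" %in% names(raw)) raw[["run"]] else
      as.character(seq_len(nrow(raw))),
    stringsAsFactors = FALSE
  )
  for (col in needed) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("non-numeric value in column '", col, "' at data row ", row,
           call. = FALSE)
    }
    out[[col]] <- v
  }
  for (r in config$responses) {
    v <- out[[r$name]]
    lo_bad <- !is.na(r$min_valid) & v < r$min_valid
    hi_bad <- !is.na(r$max_valid) & v > r$max_valid
    if (any(lo_bad | hi_bad)) {
      stop("response '", r$name, "' out of valid range [",
           r$min_valid, ", ", r$max_valid, "] at data row ",
           which(lo_bad | hi_bad)[1], call. = FALSE)
    }
  }
  out
}

# full-precision numeric formatting for round-trip-safe CSV output
format_full <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  vapply(x, function(v) {
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    sub("(\\.\\d*?)0+$", "\\1", sub("\\.$", "", s))
  }, character(1))
}

#' Write a design/response table
#'
#' Numeric columns are written with enough digits that re-reading
#' restores them to full double precision.
#'
#' @param runs Data frame as returned by [read_design_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(runs, path) {
  out <- as.data.frame(lapply(runs, format_full),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(runs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read concentration-time profiles
#'
#' CSV with columns `time` (min), `concentration` (ng/mL), `tissue`
#' (`brain`/`blood`), `route` (`IV`/`IN`) and `group`. One profile is
#' returned per (tissue, route, group) combination; unsorted times are
#' sorted with a warning, duplicated times or negative concentrations
#' are errors.
#'
#' @param path CSV file path.
#' @return Named list of [concentration_profile()]s (names
#'   `tissue_route_group`).
#' @export
read_profile_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  needed <- c("time", "concentration", "tissue", "route", "group")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("profile table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$time) || !is.numeric(raw$concentration)) {
    stop("'time' and 'concentration' must be numeric", call. = FALSE)
  }
  if (any(raw$concentration < 0)) {
    stop("negative concentration at data row ",
         which(raw$concentration < 0)[1], call. = FALSE)
  }
  key <- paste(raw$tissue, raw$route, raw$group, sep = "_")
  profiles <- lapply(split(raw, factor(key, levels = unique(key))),
                     function(d) {
    if (anyDuplicated(d$time)) {
      stop("duplicate time ", d$time[duplicated(d$time)][1],
           " in profile ", d$tissue[1], "/", d$route[1], "/", d$group[1],
           call. = FALSE)
    }
    if (is.unsorted(d$time)) {
      warning("unsorted times in profile ", d$tissue[1], "/", d$route[1],
              "/", d$group[1], "; sorting", call. = FALSE)
      d <- d[order(d$time), ]
    }
    concentration_profile(d$time, d$concentration,
                          tissue = d$tissue[1], route = d$route[1],
                          group = d$group[1])
  })
  profiles
}

#' Write concentration-time profiles
#'
#' Inverse of [read_profile_table()]: stacks the profiles into the long
#' CSV schema at full precision.
#'
#' @param profiles List of [concentration_profile()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(time = format_full(p$time),
               concentration = format_full(p$concentration),
               tissue = p$tissue, route = p$route, group = p$group,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
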