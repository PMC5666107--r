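#' Discrete character matrices
#'
#' A `char_matrix` holds one discrete morphological character: an ordered
#' state alphabet, a missing-data marker (`"?"` by default, as in NEXUS
#' usage), and one state per taxon. Internally it is a tibble
#' (`taxon`, `state`) with the alphabet and marker kept as attributes.
#'
#' @param data A data frame with columns `taxon` and `state` (character).
#' @param alphabet Ordered character vector of allowed states (length >= 2).
#' @param missing Missing-data marker.
#' @param name Character name, e.g. `"trunk_plates"`.
#' @return A `char_matrix` object.
#' @examples
#' char_matrix(tibble::tibble(taxon = c("A", "B"), state = c("0", "1")),
#'             alphabet = c("0", "1"), name = "plates")
#' @export
char_matrix <- function(data, alphabet, missing = "?", name = "character") {
  stopifnot(is.data.frame(data), all(c("taxon", "state") %in% names(data)))
  data <- tibble::tibble(taxon = as.character(data$taxon),
                         state = as.character(data$state))
  if (anyDuplicated(data$taxon)) {
    stop(sprintf("duplicated taxon label '%s'", data$taxon[duplicated(data$taxon)][1]),
         call. = FALSE)
  }
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2) stop("alphabet must have >= 2 states", call. = FALSE)
  bad <- !(data$state %in% c(alphabet, missing))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("taxon '%s' has unknown state symbol '%s'",
                 data$taxon[i], data$state[i]), call. = FALSE)
  }
  structure(list(data = data, alphabet = alphabet, missing = missing, name = name),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("Character '%s': %d taxa, states {%s}, missing '%s'\n",
              x$name, nrow(x$data), paste(x$alphabet, collapse = ","), x$missing))
  print(x$data, ...)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.char_matrix <- function(x, ...) x$data

#' States of a character matrix as a named vector
#'
#' @param x A [char_matrix].
#' @return Named character vector of states (missing marker retained).
#' @export
char_states <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  stats::setNames(x$data$state, x$data$taxon)
}

#' Encode the four-state odontode location character
#'
#' Combines two presence flags into the standard coding: 0 = no odontodes,
#' 1 = odontodes on the head only, 2 = odontodes on the trunk only,
#' 3 = odontodes on both head and trunk. If either flag is unknown the
#' missing marker is returned (not an error).
#'
#' @param head,trunk Presence flags; `TRUE`/`FALSE`, `"present"`/`"absent"`,
#'   or `NA`/`"unknown"` for unknown. Vectorised.
#' @param missing Marker returned when a flag is unknown.
#' @return Character vector over `{"0","1","2","3"}` plus the missing marker.
#' @examples
#' encode_odontode_state("present", "absent")  # "1"
#' encode_odontode_state(c(TRUE, NA), c(TRUE, TRUE))
#' @export
encode_odontode_state <- function(head, trunk, missing = "?") {
  h <- .as_flag(head)
  t <- .as_flag(trunk)
  out <- as.character(ifelse(t & h, "3", ifelse(t, "2", ifelse(h, "1", "0"))))
  out[is.na(h) | is.na(t)] <- missing
  out
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("present", "1", "true", "yes")] <- TRUE
  out[x %in% c("absent", "0", "false", "no")] <- FALSE
  out
}

#' Read a character matrix from CSV or NEXUS
#'
#' CSV files need a header `taxon,state`. NEXUS files must contain a DATA or
#' CHARACTERS block with a single character per taxon.
#'
#' @param path File path.
#' @param format `"csv"` or `"nexus"`; guessed from the extension by default.
#' @param alphabet State alphabet; for CSV it defaults to the sorted set of
#'   observed non-missing states.
#' @inheritParams char_matrix
#' @return A [char_matrix].
#' @export
read_char_matrix <- function(path, format = c("auto", "csv", "nexus"),
                             alphabet = NULL, missing = "?",
                             name = "character") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  }
  if (format == "csv") {
    d <- utils::read.csv(path, colClasses = "character")
    stopifnot(all(c("taxon", "state") %in% names(d)))
  } else {
    raw <- ape::read.nexus.data(path)
    d <- data.frame(taxon = names(raw),
                    state = vapply(raw, function(s) paste(s, collapse = ""), character(1)))
  }
  if (is.null(alphabet)) alphabet <- sort(setdiff(unique(d$state), missing))
  char_matrix(d, alphabet = alphabet, missing = missing, name = name)
}

#' Write a character matrix to CSV or NEXUS
#'
#' The NEXUS writer emits a CHARACTERS block with `FORMAT DATATYPE=STANDARD`,
#' the alphabet as `SYMBOLS`, and the missing marker.
#'
#' @param x A [char_matrix].
#' @param path Output path.
#' @param format `"csv"` or `"nexus"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_char_matrix <- function(x, path, format = c("auto", "csv", "nexus")) {
  stopifnot(inherits(x, "char_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  pad <- max(nchar(x$data$taxon)) + 2
  lines <- c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=1;", nrow(x$data)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=%s;",
            paste(x$alphabet, collapse = " "), x$missing),
    "  MATRIX",
    sprintf("    %-*s %s", pad, x$data$taxon, x$data$state),
    "  ;",
    "END;")
  writeLines(lines, path)
  invisible(path)
}
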