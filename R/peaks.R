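# 2D (1H-15N) peak lists: construction, validation, TSV and Sparky-dialect
# readers/writers.  A peak list is a plain data frame with columns
# id, assignment (NA allowed), shift_h (ppm), shift_n (ppm), height.

#' Build a 2D peak list
#'
#' @param shift_h,shift_n Chemical shifts in ppm (amide 1H and 15N).
#' @param height Peak intensities (arbitrary units, >= 0).
#' @param id Peak labels; defaults to `P1..Pn`.
#' @param assignment Optional residue assignments, written as mature
#'   position plus one-letter code (e.g. `"F112"`); `NA` when unassigned.
#' @return Data frame with class `"peak_list"`.
#' @export
peak_list <- function(shift_h, shift_n, height = 1,
                      id = NULL, assignment = NA_character_) {
  n <- length(shift_h)
  stopifnot(length(shift_n) == n)
  height <- rep_len(height, n)
  assignment <- rep_len(as.character(assignment), n)
  if (is.null(id)) id <- paste0("P", seq_len(n))
  stopifnot(!anyDuplicated(id))
  x <- data.frame(id = as.character(id), assignment = assignment,
                  shift_h = as.numeric(shift_h),
                  shift_n = as.numeric(shift_n),
                  height = as.numeric(height), stringsAsFactors = FALSE)
  validate_peak_list(x)
}

#' @rdname peak_list
#' @param x Data frame to validate.
#' @export
validate_peak_list <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("id", "assignment", "shift_h", "shift_n", "height") %in%
                  names(x)))
  if (!all(is.finite(x$shift_h)) || !all(is.finite(x$shift_n))) {
    stop("peak shifts must be finite", call. = FALSE)
  }
  if (any(x$height < 0)) stop("peak heights must be >= 0", call. = FALSE)
  if (anyDuplicated(x$id)) stop("duplicate peak ids", call. = FALSE)
  class(x) <- unique(c("peak_list", class(x)))
  x
}

#' Residue number parsed from an assignment label
#'
#' Accepts `"F112"`, `"112"`, and Sparky-style `"F112N-H"`.
#'
#' @param assignment Character vector of labels.
#' @return Integer vector (NA where unparseable).
#' @export
assignment_residue <- function(assignment) {
  has <- !is.na(assignment) & grepl("[0-9]+", assignment)
  out <- rep(NA_integer_, length(assignment))
  out[has] <- as.integer(regmatches(assignment[has],
                                    regexpr("[0-9]+", assignment[has])))
  out
}

#' Read / write peak lists as TSV
#'
#' Columns: `id`, `assignment` (may be empty), `shift_h`, `shift_n`,
#' `height`.
#'
#' @param path File path.
#' @return A `peak_list` data frame.
#' @export
read_peaks_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character",
                                        assignment = "character"),
                         comment.char = "#")
  x$assignment[x$assignment == ""] <- NA_character_
  validate_peak_list(x)
}

#' @rdname read_peaks_tsv
#' @param peaks A `peak_list`.
#' @export
write_peaks_tsv <- function(peaks, path) {
  peaks <- validate_peak_list(peaks)
  out <- peaks
  out$assignment[is.na(out$assignment)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Sparky-style peak list
#'
#' Parses the common Sparky amide list dialect:
#' `Assignment  w1  w2  [Data] Height`, where w1 is the 15N shift and w2
#' the 1H shift and the assignment is e.g. `F112N-H` (`?-?` when
#' unassigned).
#'
#' @param path File path.
#' @return A `peak_list` data frame; assignments normalised to `"F112"`
#'   style, `NA` when unassigned.
#' @export
read_sparky_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !grepl("^(Assignment|#)", lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  n_col <- lengths(fields)
  stopifnot(all(n_col >= 3L))
  asg <- vapply(fields, `[[`, character(1), 1L)
  w1 <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  w2 <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  height <- vapply(fields, function(f)
    if (length(f) >= 4L) as.numeric(f[[length(f)]]) else 1, numeric(1))
  norm <- sub("^([A-Z])([0-9]+).*$", "\\1\\2", asg)
  norm[!grepl("^[A-Z][0-9]+", asg)] <- NA_character_
  peak_list(shift_h = w2, shift_n = w1, height = height,
            id = paste0("S", seq_along(asg)), assignment = norm)
}
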