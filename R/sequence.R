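# Expression-construct bookkeeping: tag cleavage, mature numbering,
# truncation, and sequence-feature scans (N-glycosylation sequons,
# cysteines, pairwise differences).

.aa_canonical <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_sequence <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .aa_canonical)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-canonical residue letters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Define an expression construct
#'
#' Describes a raw expressed sequence together with the cleavable tag
#' region, any post-cleavage extension residues (e.g. the "GP" scar left by
#' 3C protease), and an optional stop-codon truncation expressed in mature
#' numbering.
#'
#' @param raw_sequence One-letter amino-acid string as expressed.
#' @param tag_region Integer length-2 vector, 1-based inclusive interval of
#'   the cleavable N-terminal tag within `raw_sequence`; `NULL` for no tag.
#' @param extension Residues left after cleavage but preceding mature
#'   position 1 (reported at non-positive mature positions); `""` for none.
#' @param stop_position Optional mature position at which a stop codon
#'   truncates the product (that residue and all beyond are absent).
#' @return An object of class `"construct"`.
#' @examples
#' con <- construct("MHHHHHHGPQIPLC", tag_region = c(1, 7), extension = "GP")
#' cleave_construct(con)$mature
#' @export
construct <- function(raw_sequence, tag_region = NULL, extension = "",
                      stop_position = NULL) {
  .check_sequence(raw_sequence, "raw_sequence")
  n <- nchar(raw_sequence)
  if (!is.null(tag_region)) {
    tag_region <- as.integer(tag_region)
    stopifnot(length(tag_region) == 2L)
    if (tag_region[1] != 1L || tag_region[2] < tag_region[1] ||
        tag_region[2] > n) {
      stop(sprintf("tag_region [%d, %d] outside raw sequence of length %d",
                   tag_region[1], tag_region[2], n), call. = FALSE)
    }
  }
  if (nchar(extension) > 0L) .check_sequence(extension, "extension")
  tag_len <- if (is.null(tag_region)) 0L else tag_region[2]
  mature_offset <- tag_len + nchar(extension) + 1L
  if (mature_offset > n) {
    stop("tag and extension leave no mature residues", call. = FALSE)
  }
  # the declared extension must actually be present in the raw sequence
  if (nchar(extension) > 0L) {
    found <- substr(raw_sequence, tag_len + 1L, tag_len + nchar(extension))
    if (found != extension) {
      stop(sprintf("extension '%s' not found after tag (raw has '%s')",
                   extension, found), call. = FALSE)
    }
  }
  if (!is.null(stop_position)) {
    stop_position <- as.integer(stop_position)
    mature_len <- n - mature_offset + 1L
    if (stop_position < 1L || stop_position > mature_len + 1L) {
      stop(sprintf("stop_position %d out of range 1..%d",
                   stop_position, mature_len + 1L), call. = FALSE)
    }
  }
  structure(list(raw_sequence = raw_sequence, tag_region = tag_region,
                 extension = extension, mature_offset = mature_offset,
                 stop_position = stop_position),
            class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat(sprintf("construct: raw %d aa; tag %s; extension '%s'; mature offset %d%s\n",
              nchar(x$raw_sequence),
              if (is.null(x$tag_region)) "none"
              else sprintf("%d-%d", x$tag_region[1], x$tag_region[2]),
              x$extension, x$mature_offset,
              if (is.null(x$stop_position)) ""
              else sprintf("; stop at mature %d", x$stop_position)))
  invisible(x)
}

#' Cleave a construct to its mature sequence
#'
#' Removes the tag region and reports the mature sequence in mature
#' numbering (position 1 = first residue after the extension).  Extension
#' residues are reported separately at non-positive mature positions
#' (e.g. a "GP" scar at -1, 0) so that mature numbering matches the
#' literature.  If the construct carries a `stop_position` the truncation
#' is applied after cleavage.
#'
#' @param con A [construct()].
#' @return List with `mature` (string), `extension` (data frame of
#'   position/residue at non-positive positions), and `numbering`
#'   (data frame mapping mature position to raw index; a bijection over
#'   retained residues, extension included).
#' @export
cleave_construct <- function(con) {
  stopifnot(inherits(con, "construct"))
  raw <- strsplit(con$raw_sequence, "")[[1]]
  ext_len <- nchar(con$extension)
  ext_raw_idx <- if (ext_len > 0L) {
    (con$mature_offset - ext_len):(con$mature_offset - 1L)
  } else integer(0)
  mat_raw_idx <- con$mature_offset:length(raw)
  if (!is.null(con$stop_position)) {
    keep <- seq_len(con$stop_position - 1L)
    mat_raw_idx <- mat_raw_idx[keep]
  }
  mature <- paste(raw[mat_raw_idx], collapse = "")
  numbering <- data.frame(
    mature_position = c(if (ext_len > 0L) (1L - ext_len):0L else integer(0),
                        seq_along(mat_raw_idx)),
    raw_index = c(ext_raw_idx, mat_raw_idx),
    residue = raw[c(ext_raw_idx, mat_raw_idx)],
    stringsAsFactors = FALSE)
  extension <- numbering[numbering$mature_position <= 0L,
                         c("mature_position", "residue")]
  rownames(extension) <- NULL
  list(mature = mature, extension = extension, numbering = numbering)
}

#' Truncate a mature sequence at a stop position
#'
#' Mimics introduction of a stop codon: the residue at `stop_position` and
#' everything C-terminal of it are removed.
#'
#' @param mature_seq Mature one-letter sequence.
#' @param stop_position Mature 1-based position of the stop (1..len+1).
#' @return List with `sequence` (length `stop_position - 1`) and `removed`
#'   (count of residues removed).
#' @export
apply_truncation <- function(mature_seq, stop_position) {
  .check_sequence(mature_seq, "mature_seq")
  n <- nchar(mature_seq)
  stop_position <- as.integer(stop_position)
  if (stop_position < 1L || stop_position > n + 1L) {
    stop(sprintf("stop_position %d out of range 1..%d", stop_position, n + 1L),
         call. = FALSE)
  }
  list(sequence = substr(mature_seq, 1L, stop_position - 1L),
       removed = n - (stop_position - 1L))
}

#' Scan for N-glycosylation sequons
#'
#' Finds every N-X-\[S/T\] motif with X != P, the consensus acceptor site
#' for N-linked glycosylation.
#'
#' @param mature_seq One-letter sequence in mature numbering.
#' @return Data frame with `position` (1-based index of the Asn, ascending)
#'   and `triplet` (the three-residue window); zero rows when no sequon.
#' @examples
#' scan_sequons("ANGTXXNPSXXNIS")  # NGT and NIS hit, NPS is excluded
#' @export
scan_sequons <- function(mature_seq) {
  .check_sequence(mature_seq, "mature_seq")
  s <- strsplit(mature_seq, "")[[1]]
  n <- length(s)
  if (n < 3L) {
    return(data.frame(position = integer(0), triplet = character(0),
                      stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 2L)
  hit <- s[i] == "N" & s[i + 1L] != "P" & s[i + 2L] %in% c("S", "T")
  pos <- i[hit]
  data.frame(position = pos,
             triplet = vapply(pos, function(p)
               paste(s[p:(p + 2L)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

#' Positions of a residue type
#'
#' @param mature_seq One-letter sequence.
#' @param residue_letter Single canonical one-letter code.
#' @return Sorted integer vector of 1-based positions (possibly empty).
#' @export
find_residue_positions <- function(mature_seq, residue_letter) {
  .check_sequence(mature_seq, "mature_seq")
  stopifnot(nchar(residue_letter) == 1L, residue_letter %in% .aa_canonical)
  which(strsplit(mature_seq, "")[[1]] == residue_letter)
}

#' Hamming distance between equal-length sequences
#'
#' Counts positionwise substitutions between two pre-aligned sequences.
#' No alignment is performed; unequal lengths are an error.
#'
#' @param seq_a,seq_b One-letter sequences of equal length.
#' @return Integer substitution count.
#' @export
count_differences <- function(seq_a, seq_b) {
  .check_sequence(seq_a, "seq_a")
  .check_sequence(seq_b, "seq_b")
  if (nchar(seq_a) != nchar(seq_b)) {
    stop(sprintf("sequences differ in length (%d vs %d); inputs must be pre-aligned",
                 nchar(seq_a), nchar(seq_b)), call. = FALSE)
  }
  sum(strsplit(seq_a, "")[[1]] != strsplit(seq_b, "")[[1]])
}

#' Read / write single sequences as FASTA
#'
#' Thin wrappers: reading uses Biostrings when available and falls back to
#' a plain-text parse otherwise; writing emits 60-column wrapped FASTA.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stopifnot(length(hdr) > 0L)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  names(out) <- sub("^>\\s*", "", lines[hdr])
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Sequence feature report for a construct
#'
#' Convenience wrapper running cleavage, truncation, sequon and cysteine
#' scans, as a construct-level summary.
#'
#' @param con A [construct()].
#' @return List with the mature sequence, its length, sequon table,
#'   cysteine positions, and (when a stop is set) the truncation summary.
#' @export
sequence_report <- function(con) {
  full <- cleave_construct(construct(con$raw_sequence, con$tag_region,
                                     con$extension))
  trunc <- if (!is.null(con$stop_position)) {
    apply_truncation(full$mature, con$stop_position)
  } else NULL
  mature <- if (is.null(trunc)) full$mature else trunc$sequence
  list(mature = mature,
       mature_length = nchar(full$mature),
       product_length = nchar(mature),
       sequons = scan_sequons(mature),
       cysteines = find_residue_positions(mature, "C"),
       truncation = trunc)
}
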