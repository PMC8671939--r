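# Reverse minimal chemical-shift mapping: assign an unassigned free-state
# HSQC peak list by nearest-neighbour matching onto an assigned bound-state
# list, under per-dimension gates, a weighted combined-shift distance, and
# a relative-height floor.

#' Dimension weighting from assigned shift ranges
#'
#' The 15N dimension is scaled into 1H ppm units by the ratio of the
#' assigned-shift ranges of the two dimensions, so that a combined shift
#' can be expressed on a single ppm scale.  For the AGP2--UCN-01 bound
#' spectrum the ranges 4.504 ppm (1H) and 30.616 ppm (15N) give a
#' weighting of 0.147.
#'
#' @param range_h,range_n Assigned chemical-shift ranges (ppm), > 0.
#' @return Object of class `"weight_spec"` with fields `range_h`,
#'   `range_n`, `weight` (= `range_h / range_n`, 1H ppm per 15N ppm).
#' @export
compute_weight <- function(range_h, range_n) {
  if (!is.finite(range_h) || !is.finite(range_n) ||
      range_h <= 0 || range_n <= 0) {
    stop("shift ranges must be positive and finite", call. = FALSE)
  }
  structure(list(range_h = range_h, range_n = range_n,
                 weight = range_h / range_n),
            class = "weight_spec")
}

.as_weight <- function(weight) {
  if (inherits(weight, "weight_spec")) weight$weight else as.numeric(weight)
}

#' Weighted combined chemical-shift distance
#'
#' `d = sqrt(dH^2 + (w * dN)^2)` in 1H ppm, the standard combined-shift
#' form with the 15N difference scaled by the dimension weighting.
#'
#' @param peak_a,peak_b Single-row peak lists (or any objects with
#'   `shift_h`/`shift_n` fields).
#' @param weight A [compute_weight()] result or a bare numeric weighting.
#' @return Distance in ppm.
#' @export
weighted_distance <- function(peak_a, peak_b, weight) {
  w <- .as_weight(weight)
  dh <- peak_a$shift_h - peak_b$shift_h
  dn <- peak_a$shift_n - peak_b$shift_n
  sqrt(dh^2 + (w * dn)^2)
}

#' Per-dimension matching gates and height floor
#'
#' @param max_dh Maximum 1H shift difference (ppm) for a candidate match.
#' @param max_dn Maximum 15N shift difference (ppm).
#' @param height_floor_fraction Minimum peak height as a fraction of the
#'   tallest peak in the same spectrum (strictly greater than).
#' @return Object of class `"gate_spec"`.
#' @export
gate_spec <- function(max_dh = 0.1, max_dn = 0.68,
                      height_floor_fraction = 0.05) {
  stopifnot(max_dh > 0, max_dn > 0,
            height_floor_fraction >= 0, height_floor_fraction < 1)
  structure(list(max_dh = max_dh, max_dn = max_dn,
                 height_floor_fraction = height_floor_fraction),
            class = "gate_spec")
}

#' Drop peaks below a relative-height floor
#'
#' Retains peaks strictly taller than `floor_fraction` times the tallest
#' peak of the same list (the "more than 5% of the largest resonance"
#' counting rule).  The reference peak id is recorded as attribute
#' `"reference_id"`.
#'
#' @param peaks A `peak_list`.
#' @param floor_fraction Fraction in \[0, 1).
#' @return Filtered `peak_list`.
#' @export
filter_by_height <- function(peaks, floor_fraction = 0.05) {
  peaks <- validate_peak_list(peaks)
  stopifnot(nrow(peaks) > 0)
  hmax <- max(peaks$height)
  if (hmax <= 0) {
    stop("all peak heights are zero: no reference peak for the height floor",
         call. = FALSE)
  }
  ref <- peaks$id[which.max(peaks$height)]
  out <- peaks[peaks$height > floor_fraction * hmax, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_id") <- ref
  out
}

#' Reverse-assign a free-state peak list against a bound-state list
#'
#' Implements the reverse minimal-shift matching: every cross-list pair
#' whose 1H and 15N differences both fall inside the per-dimension gates is
#' a candidate; candidates are ranked by weighted combined-shift distance
#' and accepted greedily, each acceptance consuming its bound and free
#' peak, so the closest free/bound pairs are assigned first and more
#' distant free peaks fall to the closest remaining bound peak.  Ties in
#' distance break lexicographically on (bound id, free id) for
#' determinism.
#'
#' `method = "sequential"` instead iterates over free peaks in order of
#' their own best gated distance, assigning each to its closest remaining
#' bound peak; this is the free-peak-sequential reading of the same
#' two-phase description and is provided for comparison.
#'
#' @param free_list Unassigned free-state `peak_list`.
#' @param bound_list Assigned bound-state `peak_list` (assignments
#'   required on at least one peak).
#' @param weight A [compute_weight()] result or numeric weighting.
#' @param gates A [gate_spec()].
#' @param method `"global"` (default) or `"sequential"`.
#' @param apply_height_floor If `TRUE`, [filter_by_height()] is applied to
#'   each list (separately, each against its own tallest peak) before
#'   matching.
#' @return Object of class `"csp_mapping"`: `pairs` (data frame: bound_id,
#'   free_id, distance, dh, dn), `unmatched_bound`, `unmatched_free`
#'   (character vectors of ids), plus the parameters used.
#' @export
reverse_assign <- function(free_list, bound_list, weight, gates = gate_spec(),
                           method = c("global", "sequential"),
                           apply_height_floor = FALSE) {
  method <- match.arg(method)
  free_list <- validate_peak_list(free_list)
  bound_list <- validate_peak_list(bound_list)
  if (nrow(bound_list) == 0L) {
    stop("bound peak list is empty", call. = FALSE)
  }
  if (apply_height_floor) {
    free_list <- filter_by_height(free_list, gates$height_floor_fraction)
    bound_list <- filter_by_height(bound_list, gates$height_floor_fraction)
  }
  w <- .as_weight(weight)

  cand <- .gated_candidates(free_list, bound_list, w, gates)
  if (nrow(cand) == 0L) {
    pairs <- data.frame(bound_id = character(0), free_id = character(0),
                        distance = numeric(0), dh = numeric(0),
                        dn = numeric(0), stringsAsFactors = FALSE)
  } else if (method == "global") {
    ord <- order(cand$distance, cand$bound_id, cand$free_id)
    cand <- cand[ord, , drop = FALSE]
    used_b <- character(0); used_f <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!(cand$bound_id[i] %in% used_b) && !(cand$free_id[i] %in% used_f)) {
        keep[i] <- TRUE
        used_b <- c(used_b, cand$bound_id[i])
        used_f <- c(used_f, cand$free_id[i])
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  } else {
    # free-peak-sequential: order free peaks by their best gated distance,
    # then give each its closest remaining bound peak
    best <- tapply(cand$distance, cand$free_id, min)
    free_order <- names(sort(best))
    used_b <- character(0)
    rows <- list()
    for (f in free_order) {
      sub <- cand[cand$free_id == f & !(cand$bound_id %in% used_b), ,
                  drop = FALSE]
      if (nrow(sub) == 0L) next
      sub <- sub[order(sub$distance, sub$bound_id), , drop = FALSE]
      rows[[f]] <- sub[1L, , drop = FALSE]
      used_b <- c(used_b, sub$bound_id[1L])
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      cand[0L, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  out <- structure(list(
    pairs = pairs,
    unmatched_bound = setdiff(bound_list$id, pairs$bound_id),
    unmatched_free = setdiff(free_list$id, pairs$free_id),
    weight = w, gates = gates, method = method), class = "csp_mapping")
  .assert_mapping(out)
  out
}

.gated_candidates <- function(free_list, bound_list, w, gates) {
  nb <- nrow(bound_list); nf <- nrow(free_list)
  if (nf == 0L) {
    return(data.frame(bound_id = character(0), free_id = character(0),
                      distance = numeric(0), dh = numeric(0),
                      dn = numeric(0), stringsAsFactors = FALSE))
  }
  dh <- outer(bound_list$shift_h, free_list$shift_h, "-")
  dn <- outer(bound_list$shift_n, free_list$shift_n, "-")
  ok <- abs(dh) <= gates$max_dh & abs(dn) <= gates$max_dn
  idx <- which(ok, arr.ind = TRUE)
  data.frame(bound_id = bound_list$id[idx[, 1L]],
             free_id = free_list$id[idx[, 2L]],
             distance = sqrt(dh[idx]^2 + (w * dn[idx])^2),
             dh = dh[idx], dn = dn[idx], stringsAsFactors = FALSE)
}

.assert_mapping <- function(m) {
  stopifnot(!anyDuplicated(m$pairs$bound_id), !anyDuplicated(m$pairs$free_id),
            all(abs(m$pairs$dh) <= m$gates$max_dh),
            all(abs(m$pairs$dn) <= m$gates$max_dn))
  invisible(m)
}

#' @export
print.csp_mapping <- function(x, ...) {
  cat(sprintf("csp_mapping (%s greedy): %d pairs, %d bound-only, %d free-only\n",
              x$method, nrow(x$pairs), length(x$unmatched_bound),
              length(x$unmatched_free)))
  invisible(x)
}

#' Per-residue minimal-shift profile
#'
#' For each assigned bound-state peak, reports the minimal weighted shift
#' `delta_min` (its matched pair's distance) when a free-state partner was
#' found, or status `"bound-only"` when none was (candidate large-shift or
#' exchange-broadened residue).  Residues in `residues` with no bound peak
#' at all are reported `"unobserved"`.
#'
#' @param mapping A [reverse_assign()] result.
#' @param bound_list The assigned bound-state `peak_list` the mapping was
#'   computed against.
#' @param residues Integer vector of residue positions to report; default
#'   is the span of the bound assignments.
#' @return Data frame: `residue`, `status` (`matched` / `bound-only` /
#'   `unobserved`), `delta_min` (ppm, NA unless matched), `bound_id`,
#'   `free_id`.
#' @export
minimal_shift_profile <- function(mapping, bound_list, residues = NULL) {
  stopifnot(inherits(mapping, "csp_mapping"))
  bound_list <- validate_peak_list(bound_list)
  res_of <- assignment_residue(bound_list$assignment)
  assigned <- !is.na(res_of)
  if (is.null(residues)) {
    residues <- seq(min(res_of[assigned]), max(res_of[assigned]))
  }
  lut <- match(bound_list$id, mapping$pairs$bound_id)
  out <- data.frame(residue = residues, status = "unobserved",
                    delta_min = NA_real_, bound_id = NA_character_,
                    free_id = NA_character_, stringsAsFactors = FALSE)
  for (i in which(assigned)) {
    r <- res_of[i]
    j <- match(r, out$residue)
    if (is.na(j)) next
    out$bound_id[j] <- bound_list$id[i]
    if (!is.na(lut[i])) {
      out$status[j] <- "matched"
      out$delta_min[j] <- mapping$pairs$distance[lut[i]]
      out$free_id[j] <- mapping$pairs$free_id[lut[i]]
    } else {
      out$status[j] <- "bound-only"
    }
  }
  stopifnot(all(is.na(out$delta_min) | out$delta_min >= 0))
  out
}
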