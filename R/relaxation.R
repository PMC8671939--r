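# Backbone 15N relaxation: mono-exponential T1/T2 decay fitting,
# heteronuclear NOE ratios, and mobility profiling from T1/T2 and NOE.

#' Fit a mono-exponential relaxation decay
#'
#' Nonlinear least squares of `I(t) = I0 * exp(-t / T)` (two parameters,
#' no offset), the standard model for 15N T1/T2 peak-height decays.
#' Delays are taken in milliseconds and converted to seconds internally;
#' `T` is reported in seconds.  Initial guesses are deterministic:
#' `I0 = max(intensity)`, `T` = the delay at which the intensity is
#' closest to `I0/e`.  Parameter uncertainties come from the
#' residual-scaled covariance of the least-squares solution; Monte-Carlo
#' errors are available via `mc_errors`.
#'
#' A fit that fails to converge, or whose time constant falls outside
#' (1 ms, 100 s), is returned as a flagged failure (`converged = FALSE`)
#' rather than an error, so that whole-protein tables survive individual
#' bad residues.
#'
#' @param delays_ms Relaxation delays (ms), >= 3 distinct values.
#' @param intensities Peak heights, same length as `delays_ms`.
#' @param mc_errors Integer; when > 0, parameter errors are instead taken
#'   as the SD over this many residual-resampled Monte-Carlo refits
#'   (deterministic given the RNG state).
#' @return List of class `"relax_fit"`: `i0`, `t_s`, `i0_err`, `t_err`,
#'   `converged`, `message`.
#' @export
fit_exponential <- function(delays_ms, intensities, mc_errors = 0) {
  stopifnot(length(delays_ms) == length(intensities))
  if (length(unique(delays_ms)) < 3L) {
    stop("at least 3 distinct delays are required for a two-parameter fit",
         call. = FALSE)
  }
  if (any(delays_ms <= 0)) {
    stop("relaxation delays must be strictly positive", call. = FALSE)
  }
  if (length(unique(intensities)) == 1L) {
    stop("intensities are all equal; no decay to fit", call. = FALSE)
  }
  t_s <- delays_ms / 1000
  i0_start <- max(intensities)
  target <- i0_start / exp(1)
  t_start <- t_s[which.min(abs(intensities - target))]
  if (t_start <= 0) t_start <- stats::median(t_s)

  dat <- data.frame(t = t_s, y = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-t / tc), data = dat,
                      start = list(i0 = i0_start, tc = t_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  fail <- function(msg) {
    structure(list(i0 = NA_real_, t_s = NA_real_, i0_err = NA_real_,
                   t_err = NA_real_, converged = FALSE, message = msg),
              class = "relax_fit")
  }
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  co <- stats::coef(fit)
  if (!is.finite(co[["tc"]]) || co[["tc"]] <= 0.001 || co[["tc"]] > 100) {
    return(fail(sprintf("time constant %.4g s outside (1 ms, 100 s)",
                        co[["tc"]])))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(i0 = NA_real_, tc = NA_real_))
  if (mc_errors > 0) {
    res <- stats::resid(fit)
    sims <- vapply(seq_len(mc_errors), function(i) {
      y2 <- stats::fitted(fit) + sample(res, replace = TRUE)
      f2 <- tryCatch(minpack.lm::nlsLM(
        y ~ i0 * exp(-t / tc), data = data.frame(t = t_s, y = y2),
        start = list(i0 = co[["i0"]], tc = co[["tc"]])),
        error = function(e) NULL)
      if (is.null(f2)) c(NA_real_, NA_real_) else stats::coef(f2)
    }, numeric(2))
    se <- c(i0 = stats::sd(sims[1, ], na.rm = TRUE),
            tc = stats::sd(sims[2, ], na.rm = TRUE))
  }
  structure(list(i0 = unname(co[["i0"]]), t_s = unname(co[["tc"]]),
                 i0_err = unname(se[["i0"]]), t_err = unname(se[["tc"]]),
                 converged = TRUE, message = "ok"),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("relax_fit: T = %.4f +/- %.4f s, I0 = %.4g\n",
                x$t_s, x$t_err, x$i0))
  } else {
    cat("relax_fit: FAILED --", x$message, "\n")
  }
  invisible(x)
}

#' Heteronuclear NOE ratio with propagated error
#'
#' `NOE = I_sat / I_ref` from the saturated and reference interleaved
#' spectra; the first-order propagated uncertainty is
#' `sqrt((s_sat/I_ref)^2 + (I_sat * s_ref / I_ref^2)^2)`.  Negative
#' ratios are valid (highly flexible residues).
#'
#' @param i_sat,i_ref Peak heights in the saturated and reference spectra.
#' @param sigma_sat,sigma_ref Intensity uncertainties (default 0).
#' @return List with `noe` and `noe_err`.
#' @export
compute_hetnoe <- function(i_sat, i_ref, sigma_sat = 0, sigma_ref = 0) {
  if (any(i_ref == 0)) stop("reference intensity is zero", call. = FALSE)
  noe <- i_sat / i_ref
  err <- sqrt((sigma_sat / i_ref)^2 + (i_sat * sigma_ref / i_ref^2)^2)
  list(noe = noe, noe_err = err)
}

#' Fit a full relaxation table
#'
#' Takes long-format decay data (`residue`, `experiment` in `"T1"`/`"T2"`,
#' `delay_ms`, `intensity`) plus NOE pairs (`residue`, `i_sat`, `i_ref`,
#' optional `sigma_sat`, `sigma_ref`), fits every residue's T1 and T2
#' decay and assembles the per-residue result table.
#'
#' @param decays Long-format decay data frame.
#' @param noe Data frame of NOE intensities, or `NULL`.
#' @return Data frame: `residue`, `t1_s`, `t1_err`, `t2_s`, `t2_err`,
#'   `noe`, `noe_err`, `ratio` (T1/T2), `ok` (both fits converged).
#' @export
fit_relaxation_table <- function(decays, noe = NULL) {
  stopifnot(all(c("residue", "experiment", "delay_ms", "intensity") %in%
                  names(decays)))
  residues <- sort(unique(decays$residue))
  one <- function(res, expt) {
    d <- decays[decays$residue == res & decays$experiment == expt, ]
    if (nrow(d) < 3L) return(NULL)
    fit_exponential(d$delay_ms, d$intensity)
  }
  rows <- lapply(residues, function(res) {
    f1 <- one(res, "T1"); f2 <- one(res, "T2")
    out <- data.frame(residue = res, t1_s = NA_real_, t1_err = NA_real_,
                      t2_s = NA_real_, t2_err = NA_real_, noe = NA_real_,
                      noe_err = NA_real_, ratio = NA_real_, ok = FALSE)
    if (!is.null(f1) && f1$converged) {
      out$t1_s <- f1$t_s; out$t1_err <- f1$t_err
    }
    if (!is.null(f2) && f2$converged) {
      out$t2_s <- f2$t_s; out$t2_err <- f2$t_err
    }
    if (is.finite(out$t1_s) && is.finite(out$t2_s)) {
      out$ratio <- out$t1_s / out$t2_s
      out$ok <- TRUE
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (!is.null(noe)) {
    stopifnot(all(c("residue", "i_sat", "i_ref") %in% names(noe)))
    s_sat <- if ("sigma_sat" %in% names(noe)) noe$sigma_sat else 0
    s_ref <- if ("sigma_ref" %in% names(noe)) noe$sigma_ref else 0
    hn <- compute_hetnoe(noe$i_sat, noe$i_ref, s_sat, s_ref)
    j <- match(tab$residue, noe$residue)
    tab$noe <- hn$noe[j]
    tab$noe_err <- hn$noe_err[j]
  }
  tab
}

#' Mobility profile from relaxation results
#'
#' Flags fast-motion residues and scans for contiguous patches of
#' depressed T2.  A residue is flagged `fast_motion` when both its T1/T2
#' ratio and its NOE fall below configured fractions of the core values,
#' where "core" is the trimmed mean over all residues (trimming removes
#' genuinely mobile termini from the reference).  Reduced T1/T2 together
#' with reduced NOE is the signature of fast (sub-nanosecond) internal
#' motion; a contiguous run of depressed T2 values is instead the
#' signature of intermediate (microsecond--millisecond) exchange, and is
#' reported separately.
#'
#' @param results A [fit_relaxation_table()] data frame (>= 5 complete
#'   residues required).
#' @param ratio_fraction,noe_fraction Flag when ratio (resp. NOE) is below
#'   this fraction of the core trimmed mean (defaults 0.75).
#' @param t2_fraction A residue contributes to a low-T2 patch when its T2
#'   is below this fraction of the core trimmed-mean T2 (default 0.75).
#' @param patch_min Minimum run length (in consecutive residues) for a
#'   reported low-T2 patch (default 4).
#' @param trim Trimming fraction for the core means (default 0.2).
#' @return List of class `"mobility_profile"`: `table` (per-residue flags),
#'   `core` (reference values), `fast_motion` (flagged residues),
#'   `t2_patches` (data frame of start/end/length, zero rows when none).
#' @export
mobility_profile <- function(results, ratio_fraction = 0.75,
                             noe_fraction = 0.75, t2_fraction = 0.75,
                             patch_min = 4L, trim = 0.2) {
  ok <- results[results$ok & is.finite(results$noe), , drop = FALSE]
  if (nrow(ok) < 5L) {
    stop("need >= 5 residues with complete T1, T2 and NOE results",
         call. = FALSE)
  }
  ok <- ok[order(ok$residue), , drop = FALSE]
  core <- list(ratio = mean(ok$ratio, trim = trim),
               noe = mean(ok$noe, trim = trim),
               t2 = mean(ok$t2_s, trim = trim))
  fast <- ok$ratio < ratio_fraction * core$ratio &
    ok$noe < noe_fraction * core$noe
  low_t2 <- ok$t2_s < t2_fraction * core$t2

  # contiguous (in residue numbering) runs of depressed T2
  patches <- data.frame(start = integer(0), end = integer(0),
                        length = integer(0))
  r <- ok$residue
  run_start <- NA_integer_; prev <- NA_integer_
  close_run <- function(patches, s, e) {
    len <- sum(r >= s & r <= e & low_t2)
    if (len >= patch_min) rbind(patches, data.frame(start = s, end = e,
                                                    length = len))
    else patches
  }
  for (i in seq_along(r)) {
    if (low_t2[i] && (is.na(run_start))) {
      run_start <- r[i]
    } else if (!is.na(run_start) && (!low_t2[i] || r[i] != prev + 1L)) {
      patches <- close_run(patches, run_start, prev)
      run_start <- if (low_t2[i]) r[i] else NA_integer_
    }
    prev <- r[i]
  }
  if (!is.na(run_start)) patches <- close_run(patches, run_start, prev)

  tab <- data.frame(residue = ok$residue, ratio = ok$ratio, noe = ok$noe,
                    t2_s = ok$t2_s, fast_motion = fast, low_t2 = low_t2)
  structure(list(table = tab, core = core,
                 fast_motion = ok$residue[fast], t2_patches = patches),
            class = "mobility_profile")
}

#' @export
print.mobility_profile <- function(x, ...) {
  cat(sprintf("mobility_profile: %d residues; core T1/T2 = %.2f, NOE = %.2f\n",
              nrow(x$table), x$core$ratio, x$core$noe))
  cat(sprintf("  fast-motion residues: %s\n",
              if (length(x$fast_motion)) paste(x$fast_motion, collapse = ", ")
              else "none"))
  cat(sprintf("  low-T2 patches (>= configured length): %d\n",
              nrow(x$t2_patches)))
  invisible(x)
}
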