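# Least-squares rigid-body superposition (Kabsch) and RMSD over
# residue-range backbone selections.

#' Kabsch optimal rotation between paired coordinate sets
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum(|| R p_i + t - q_i ||^2)` over paired points `P -> Q`, by SVD of
#' the covariance of the centred sets with the usual sign correction so
#' that `det(R) = +1` (no reflection).
#'
#' @param p,q Numeric n-by-3 matrices of paired coordinates (`p` is
#'   moved onto `q`).
#' @return List with `rotation` (3x3, proper), `translation` (length 3),
#'   `rmsd` (Angstrom, after the fit), `n` (number of points).
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3L, ncol(q) == 3L, nrow(p) == nrow(q))
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 paired points", call. = FALSE)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- crossprod(pc, qc)           # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cq - as.numeric(rot %*% cp)
  moved <- sweep(pc %*% t(rot), 2, cq, "+")  # = R p + t
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  stopifnot(abs(det(rot) - 1) < 1e-8)
  list(rotation = rot, translation = trans, rmsd = rmsd, n = n)
}

#' Superpose two structure models over a residue range
#'
#' Pairs atoms by (chain, residue number, insertion code, atom name) over
#' the requested residue interval and atom-name set, then applies
#' [kabsch()].  Residues present in only one model are dropped from the
#' fit and reported.
#'
#' @param model_a Reference `structure_model` (the fit moves `model_b`
#'   onto `model_a`).
#' @param model_b Mobile `structure_model`.
#' @param residue_range Length-2 integer vector (inclusive), e.g.
#'   `c(11, 167)`; `NULL` uses every shared residue.
#' @param atom_names Atom-name set for the fit; the default is the
#'   backbone heavy atoms `N, CA, C, O`; use `"CA"` for a CA-only fit.
#' @param chain Restrict to these chains (default: all).
#' @return Object of class `"superposition"`: `rotation`, `translation`,
#'   `rmsd`, `n_atoms`, `selection`, `unpaired` (data frame of residues
#'   present in only one model over the range).
#' @export
superpose <- function(model_a, model_b, residue_range = NULL,
                      atom_names = c("N", "CA", "C", "O"), chain = NULL) {
  sel <- function(m) {
    a <- get_atoms(m, chain = chain, elety = atom_names, het = FALSE)
    if (!is.null(residue_range)) {
      a <- a[a$resno >= residue_range[1] & a$resno <= residue_range[2], ,
             drop = FALSE]
    }
    a$key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    a[!duplicated(a$key), , drop = FALSE]
  }
  aa <- sel(model_a); ab <- sel(model_b)
  shared <- intersect(aa$key, ab$key)
  only_a <- unique(aa[!(aa$key %in% shared), c("chain", "resno")])
  only_b <- unique(ab[!(ab$key %in% shared), c("chain", "resno")])
  unpaired <- unique(rbind(
    if (nrow(only_a)) cbind(only_a, model = model_a$identifier),
    if (nrow(only_b)) cbind(only_b, model = model_b$identifier)))
  if (length(shared) < 3L) {
    stop(sprintf("only %d paired atoms between '%s' and '%s' over the selection; need >= 3%s",
                 length(shared), model_a$identifier, model_b$identifier,
                 if (!is.null(unpaired) && nrow(unpaired))
                   paste0(" (unpaired residues: ",
                          paste(unique(unpaired$resno), collapse = ", "), ")")
                 else ""), call. = FALSE)
  }
  ia <- match(shared, aa$key); ib <- match(shared, ab$key)
  q <- as.matrix(aa[ia, c("x", "y", "z")])   # reference
  p <- as.matrix(ab[ib, c("x", "y", "z")])   # mobile
  k <- kabsch(p, q)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, n_atoms = k$n,
                 selection = list(residue_range = residue_range,
                                  atom_names = atom_names, chain = chain),
                 unpaired = if (is.null(unpaired))
                   data.frame(chain = character(0), resno = integer(0),
                              model = character(0)) else unpaired),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  rr <- x$selection$residue_range
  cat(sprintf("superposition: RMSD %.3f A over %d atoms (%s%s)\n",
              x$rmsd, x$n_atoms,
              paste(x$selection$atom_names, collapse = ","),
              if (is.null(rr)) "" else sprintf("; residues %d-%d",
                                               rr[1], rr[2])))
  if (nrow(x$unpaired)) {
    cat(sprintf("  %d unpaired residue entries dropped from the fit\n",
                nrow(x$unpaired)))
  }
  invisible(x)
}

#' Apply a superposition to a model
#'
#' @param model A `structure_model`.
#' @param sup A [superpose()] result (or any list with `rotation` and
#'   `translation`).
#' @return The transformed `structure_model`.
#' @export
transform_model <- function(model, sup) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(sup$rotation), 2, sup$translation, "+")
  model$atoms$x <- moved[, 1]; model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}
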