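# Independent oracles used to cross-check the package implementations.
# Each is deliberately written with a different algorithm or primitive
# than the code it checks.

# Horn's quaternion method for optimal rigid superposition (eigenvector of
# the 4x4 profile matrix) -- independent of the SVD-based Kabsch code.
horn_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  s <- crossprod(pc, qc)  # s[a, b] = sum p_a q_b
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  nmat <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  ev <- eigen(nmat, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- sweep(pc %*% t(rot), 2, cq, "+")
  list(rotation = rot, rmsd = sqrt(mean(rowSums((moved - q)^2))))
}

# Brute-force greedy matcher: explicit loops, repeated global-minimum
# extraction, per-dimension gate checks on every candidate.
brute_force_greedy <- function(free, bound, weight, max_dh, max_dn) {
  cands <- list()
  for (i in seq_len(nrow(bound))) {
    for (j in seq_len(nrow(free))) {
      dh <- bound$shift_h[i] - free$shift_h[j]
      dn <- bound$shift_n[i] - free$shift_n[j]
      if (abs(dh) <= max_dh && abs(dn) <= max_dn) {
        cands[[length(cands) + 1L]] <- data.frame(
          bound_id = bound$id[i], free_id = free$id[j],
          distance = sqrt(dh^2 + (weight * dn)^2),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- data.frame(bound_id = character(0), free_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (length(cands) == 0L) return(pairs)
  cands <- do.call(rbind, cands)
  while (nrow(cands) > 0L) {
    best <- which(cands$distance == min(cands$distance))
    if (length(best) > 1L) {
      sub <- cands[best, ]
      best <- best[order(sub$bound_id, sub$free_id)][1L]
    }
    pairs <- rbind(pairs, cands[best, ])
    cands <- cands[cands$bound_id != cands$bound_id[best] &
                     cands$free_id != cands$free_id[best], , drop = FALSE]
  }
  pairs[order(pairs$distance, pairs$bound_id, pairs$free_id), ]
}

# regex-with-lookahead sequon oracle
regex_sequons <- function(seq) {
  m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

random_aa <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# minimal hand-written PDB fixture: three residues (SER, GLU, ARG) plus a
# benzene-like het ring, a water, used across the interaction tests
write_fixture_pdb <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"), i,
            ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
            a$altloc, a$resid, a$chain, a$resno, a$x, a$y, a$z, a$occ, 0,
            a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

fixture_atoms <- function(chain = "A", resno, resid, elety, element,
                          x, y, z, occ = 1, altloc = "", het = FALSE) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = element, x = x, y = y, z = z,
             occ = occ, altloc = altloc, het = het, stringsAsFactors = FALSE)
}

# regular hexagon "benzene" ring in the z = 0 plane centred on origin
benzene_atoms <- function(resno = 900, resid = "BNZ", radius = 1.39,
                          z = 0) {
  ang <- (0:5) * pi / 3
  fixture_atoms(resno = resno, resid = resid,
                elety = paste0("C", 1:6), element = "C",
                x = radius * cos(ang), y = radius * sin(ang), z = z,
                het = TRUE)
}
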