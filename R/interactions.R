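# Geometric protein-ligand interaction detection: hydrogen bonds, salt
# bridges, cation-pi (with stacked / T-shaped classification), CH-pi,
# bridging waters and pocket contacts.  All criteria are distance/angle
# cutoffs on heavy atoms; hydrogens are used for donor angles only when
# present (crystal structures at typical resolution lack them).

# --- chemistry tables for the 20 standard residues (heavy atoms) --------

.protein_donors <- list(
  backbone = "N",  # all residues except PRO
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")

.protein_acceptors <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

.protein_cations <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.protein_anions <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

.protein_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.flag_atoms <- function(atoms, table) {
  hit <- atoms$resid %in% .protein_residues & !atoms$het &
    ((atoms$elety %in% table$backbone & atoms$resid != "PRO") | FALSE)
  for (res in setdiff(names(table), "backbone")) {
    hit <- hit | (atoms$resid == res & atoms$elety %in% table[[res]] &
                    !atoms$het)
  }
  hit
}

# --- ligand chemistry configuration -------------------------------------

#' Read a ligand chemistry table
#'
#' Plain-text (tab-separated) declaration of per-het-code ligand
#' chemistry: ring atom sets, hydrogen-bond donors/acceptors,
#' cationic/anionic groups and named reference atoms.  Columns:
#' `het`, `category` (one of ring/donor/acceptor/cation/anion/named),
#' `label`, `atoms` (comma-separated atom names).  The packaged default
#' (`system.file("extdata", "ligand_chemistry.tsv", package = "ligmap")`)
#' carries a synthetic-naming entry for the UCN het code; per-entry
#' overrides are expected whenever deposited files use different atom
#' nomenclature.
#'
#' @param path File path; default is the packaged table.
#' @return Data frame with one row per (het, category, label) and a list
#'   column `atoms`.
#' @export
read_ligand_chemistry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ligand_chemistry.tsv", package = "ligmap")
  }
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("het", "category", "label", "atoms") %in% names(x)))
  x$atoms <- strsplit(x$atoms, ",")
  x
}

.ligand_chem_atoms <- function(chem, het, category) {
  rows <- chem[chem$het == het & chem$category == category, , drop = FALSE]
  unique(unlist(rows$atoms))
}

# --- rings ---------------------------------------------------------------

#' Define an aromatic ring from model atoms
#'
#' Extracts the named ring atoms of one residue, verifies near-planarity,
#' and derives the centroid and unit normal (least-squares plane via SVD).
#'
#' @param model A `structure_model`.
#' @param resid Residue name carrying the ring (e.g. the ligand het code).
#' @param atom_names Ordered ring atom names (>= 5).
#' @param resno,chain Optional residue number / chain to disambiguate.
#' @param label Ring label.
#' @param max_dev Maximum out-of-plane deviation (Angstrom) accepted as
#'   planar (default 0.35).
#' @return Object of class `"ring_definition"`: `label`, `resid`, `resno`,
#'   `atoms`, `coords`, `centroid`, `normal` (unit), `max_dev`.
#' @export
ring_definition <- function(model, resid, atom_names, resno = NULL,
                            chain = NULL, label = resid, max_dev = 0.35) {
  if (length(atom_names) < 5L) {
    stop("a ring definition needs at least 5 atoms", call. = FALSE)
  }
  a <- get_atoms(model, chain = chain, resno = resno, resid = resid,
                 elety = atom_names)
  if (nrow(a) != length(atom_names)) {
    stop(sprintf("ring '%s': found %d of %d atoms (%s) in residue %s",
                 label, nrow(a), length(atom_names),
                 paste(setdiff(atom_names, a$elety), collapse = ","), resid),
         call. = FALSE)
  }
  xyz <- as.matrix(a[match(atom_names, a$elety), c("x", "y", "z")])
  centroid <- unname(colMeans(xyz))
  centred <- sweep(xyz, 2, centroid)
  sv <- svd(centred)
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  dev <- max(abs(centred %*% normal))
  if (dev > max_dev) {
    warning(sprintf("ring '%s' fails planarity (max deviation %.2f A > %.2f A); skipping",
                    label, dev, max_dev))
    return(NULL)
  }
  structure(list(label = label, resid = resid, resno = a$resno[1],
                 atoms = atom_names, coords = xyz, centroid = centroid,
                 normal = normal, max_dev = dev),
            class = "ring_definition")
}

#' Rings of a ligand from a chemistry table
#'
#' @param model A `structure_model`.
#' @param het Het code.
#' @param chem A [read_ligand_chemistry()] table.
#' @return List of `ring_definition` objects (planarity failures dropped
#'   with a warning).
#' @export
ligand_rings <- function(model, het, chem = read_ligand_chemistry()) {
  rows <- chem[chem$het == het & chem$category == "ring", , drop = FALSE]
  rings <- lapply(seq_len(nrow(rows)), function(i)
    ring_definition(model, resid = het, atom_names = rows$atoms[[i]],
                    label = rows$label[i]))
  Filter(Negate(is.null), rings)
}

# --- shared helpers ------------------------------------------------------

.interaction_row <- function(kind, partner_a, partner_b, metrics,
                             geometry_class = NA_character_) {
  data.frame(kind = kind, partner_a = partner_a, partner_b = partner_b,
             distance = metrics[["distance"]],
             angle = if ("angle" %in% names(metrics)) metrics[["angle"]]
             else NA_real_,
             geometry_class = geometry_class, stringsAsFactors = FALSE)
}

.atom_label <- function(a) {
  sprintf("%s%s%d%s:%s", a$chain, a$resid, a$resno,
          ifelse(a$insert == "", "", a$insert), a$elety)
}

.pair_distances <- function(a, b) {
  # n_a x n_b matrix of distances between two atom tables
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

.empty_interactions <- function() {
  data.frame(kind = character(0), partner_a = character(0),
             partner_b = character(0), distance = numeric(0),
             angle = numeric(0), geometry_class = character(0),
             stringsAsFactors = FALSE)
}

# --- detectors -----------------------------------------------------------

#' Detect hydrogen bonds
#'
#' Heavy-atom criterion: donor--acceptor distance <= `max_dist`.  When the
#' model contains hydrogens, the D-H...A angle must additionally be
#' >= `min_angle` for some hydrogen covalently bound to the donor.
#' Donors/acceptors for the standard residues come from built-in tables;
#' ligand donors/acceptors from the chemistry table.  Waters are both
#' donor and acceptor.
#'
#' @param model A `structure_model`.
#' @param max_dist Donor-acceptor heavy-atom cutoff (Angstrom, default 3.5).
#' @param min_angle D-H...A angle cutoff in degrees (default 120), applied
#'   only when hydrogens are present.
#' @param chem Ligand chemistry table.
#' @param include_waters Treat water oxygens as donors and acceptors
#'   (default TRUE).
#' @return Interaction data frame (`kind == "hbond"`), symmetric in
#'   partner order and sorted by distance.
#' @export
detect_hbonds <- function(model, max_dist = 3.5, min_angle = 120,
                          chem = read_ligand_chemistry(),
                          include_waters = TRUE) {
  atoms <- model$atoms
  don <- .flag_atoms(atoms, .protein_donors)
  acc <- .flag_atoms(atoms, .protein_acceptors)
  for (het in unique(atoms$resid[atoms$het])) {
    don <- don | (atoms$resid == het &
                    atoms$elety %in% .ligand_chem_atoms(chem, het, "donor"))
    acc <- acc | (atoms$resid == het &
                    atoms$elety %in% .ligand_chem_atoms(chem, het, "acceptor"))
  }
  if (include_waters) {
    wat <- atoms$resid %in% c("HOH", "WAT") & atoms$element == "O"
    don <- don | wat; acc <- acc | wat
  }
  d_at <- atoms[don, , drop = FALSE]; a_at <- atoms[acc, , drop = FALSE]
  if (nrow(d_at) == 0L || nrow(a_at) == 0L) return(.empty_interactions())
  dm <- .pair_distances(d_at, a_at)
  idx <- which(dm <= max_dist & dm > 0.5, arr.ind = TRUE)  # >0.5 excludes self
  if (nrow(idx) == 0L) return(.empty_interactions())
  hyd <- atoms[atoms$element == "H", , drop = FALSE]
  out <- lapply(seq_len(nrow(idx)), function(k) {
    di <- d_at[idx[k, 1], ]; ai <- a_at[idx[k, 2], ]
    same_res <- di$chain == ai$chain && di$resno == ai$resno &&
      di$insert == ai$insert && di$resid == ai$resid
    if (same_res) return(NULL)
    ang <- NA_real_
    if (nrow(hyd) > 0L) {
      hd <- .pair_distances(hyd, di)[, 1]
      mine <- hyd[hd < 1.25, , drop = FALSE]
      if (nrow(mine) > 0L) {
        angs <- vapply(seq_len(nrow(mine)), function(j) {
          v1 <- c(di$x, di$y, di$z) - c(mine$x[j], mine$y[j], mine$z[j])
          v2 <- c(ai$x, ai$y, ai$z) - c(mine$x[j], mine$y[j], mine$z[j])
          acos(pmin(pmax(sum(v1 * v2) /
                           sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < min_angle) return(NULL)
      }
    }
    .interaction_row("hbond", .atom_label(di), .atom_label(ai),
                     c(distance = dm[idx[k, 1], idx[k, 2]], angle = ang))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) return(.empty_interactions())
  # one row per unordered atom pair
  key <- apply(cbind(out$partner_a, out$partner_b), 1,
               function(r) paste(sort(r), collapse = "~"))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect salt bridges
#'
#' Any cationic nitrogen (Arg NE/NH1/NH2, Lys NZ, plus ligand cations from
#' the chemistry table) within `max_dist` of an anionic oxygen (Glu
#' OE1/OE2, Asp OD1/OD2, ligand anions) counts; one interaction is
#' reported per residue pair at the minimum atom distance.
#'
#' @inheritParams detect_hbonds
#' @param max_dist Cutoff in Angstrom (default 4.0).
#' @return Interaction data frame (`kind == "salt_bridge"`).
#' @export
detect_salt_bridges <- function(model, max_dist = 4.0,
                                chem = read_ligand_chemistry()) {
  atoms <- model$atoms
  cat_f <- .flag_atoms(atoms, c(list(backbone = character(0)),
                                .protein_cations))
  ani_f <- .flag_atoms(atoms, c(list(backbone = character(0)),
                                .protein_anions))
  for (het in unique(atoms$resid[atoms$het])) {
    cat_f <- cat_f | (atoms$resid == het &
                        atoms$elety %in% .ligand_chem_atoms(chem, het,
                                                            "cation"))
    ani_f <- ani_f | (atoms$resid == het &
                        atoms$elety %in% .ligand_chem_atoms(chem, het,
                                                            "anion"))
  }
  ca <- atoms[cat_f, , drop = FALSE]; an <- atoms[ani_f, , drop = FALSE]
  if (nrow(ca) == 0L || nrow(an) == 0L) return(.empty_interactions())
  dm <- .pair_distances(ca, an)
  idx <- which(dm <= max_dist, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(.empty_interactions())
  hits <- data.frame(i = idx[, 1], j = idx[, 2],
                     d = dm[idx],
                     res_a = paste0(ca$chain[idx[, 1]], ca$resid[idx[, 1]],
                                    ca$resno[idx[, 1]]),
                     res_b = paste0(an$chain[idx[, 2]], an$resid[idx[, 2]],
                                    an$resno[idx[, 2]]),
                     stringsAsFactors = FALSE)
  hits$pair <- paste(hits$res_a, hits$res_b, sep = "~")
  hits <- hits[order(hits$d), , drop = FALSE]
  hits <- hits[!duplicated(hits$pair), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(k)
    .interaction_row("salt_bridge",
                     .atom_label(ca[hits$i[k], ]),
                     .atom_label(an[hits$j[k], ]),
                     c(distance = hits$d[k]))))
  rownames(out) <- NULL
  out
}

#' Detect cation-pi interactions
#'
#' The cationic-group centroid (e.g. the mean of Arg NE/NH1/NH2) must lie
#' within `max_dist` of a ring centroid.  The geometry class comes from
#' the angle theta between the ring normal and the centroid-to-cation
#' vector: theta <= `stacked_max` is "stacked", theta >= `tshaped_min` is
#' "T-shaped", otherwise "intermediate".
#'
#' @param model A `structure_model`.
#' @param rings List of [ring_definition()] objects.
#' @param max_dist Centroid-centroid cutoff (Angstrom, default 6.0).
#' @param stacked_max,tshaped_min Class boundaries in degrees (30 / 60).
#' @return Interaction data frame (`kind == "cation_pi"`) with
#'   `geometry_class`.
#' @export
detect_cation_pi <- function(model, rings, max_dist = 6.0,
                             stacked_max = 30, tshaped_min = 60) {
  atoms <- model$atoms
  groups <- list()
  for (res in names(.protein_cations)) {
    sub <- get_atoms(model, resid = res, elety = .protein_cations[[res]],
                     het = FALSE)
    if (nrow(sub) == 0L) next
    for (key in unique(paste(sub$chain, sub$resno, sub$insert))) {
      g <- sub[paste(sub$chain, sub$resno, sub$insert) == key, , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(
        label = sprintf("%s%s%d", g$chain[1], g$resid[1], g$resno[1]),
        centroid = colMeans(as.matrix(g[, c("x", "y", "z")])))
    }
  }
  if (length(groups) == 0L || length(rings) == 0L) {
    return(.empty_interactions())
  }
  rows <- list()
  for (g in groups) {
    for (ring in rings) {
      v <- g$centroid - ring$centroid
      d <- sqrt(sum(v^2))
      if (d > max_dist) next
      cosang <- abs(sum(v * ring$normal)) / d
      theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      cls <- if (theta <= stacked_max) "stacked" else
        if (theta >= tshaped_min) "T-shaped" else "intermediate"
      rows[[length(rows) + 1L]] <- .interaction_row(
        "cation_pi", g$label, sprintf("ring:%s", ring$label),
        c(distance = d, angle = theta), geometry_class = cls)
    }
  }
  if (length(rows) == 0L) return(.empty_interactions())
  out <- do.call(rbind, rows)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect CH-pi interactions
#'
#' A carbon atom (aliphatic or aromatic CH donor) within `max_dist` of a
#' ring centroid and elevated at least `min_elevation` degrees out of the
#' ring plane counts as a CH-pi contact.  Ring member atoms and carbons
#' of the ring's own residue are excluded.
#'
#' @param model A `structure_model`.
#' @param rings List of [ring_definition()] objects.
#' @param max_dist Carbon to ring-centroid cutoff (Angstrom, default 4.5).
#' @param min_elevation Minimum elevation angle from the ring plane in
#'   degrees (default 30).
#' @return Interaction data frame (`kind == "ch_pi"`); `angle` is the
#'   elevation angle.
#' @export
detect_ch_pi <- function(model, rings, max_dist = 4.5, min_elevation = 30) {
  carbons <- get_atoms(model, element = "C")
  # the backbone carbonyl carbon bears no hydrogen
  carbons <- carbons[!(!carbons$het & carbons$elety == "C"), , drop = FALSE]
  rows <- list()
  for (ring in rings) {
    cand <- carbons[!(carbons$resid == ring$resid &
                        carbons$resno == ring$resno), , drop = FALSE]
    if (nrow(cand) == 0L) next
    v <- sweep(as.matrix(cand[, c("x", "y", "z")]), 2, ring$centroid)
    d <- sqrt(rowSums(v^2))
    elev <- asin(pmin(abs(v %*% ring$normal) / pmax(d, 1e-9), 1)) * 180 / pi
    hit <- which(d <= max_dist & elev >= min_elevation)
    for (k in hit) {
      rows[[length(rows) + 1L]] <- .interaction_row(
        "ch_pi", .atom_label(cand[k, ]), sprintf("ring:%s", ring$label),
        c(distance = unname(d[k]), angle = as.numeric(elev[k])))
    }
  }
  if (length(rows) == 0L) return(.empty_interactions())
  out <- do.call(rbind, rows)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect bridging waters
#'
#' A water oxygen within `max_dist` of two or more polar (N/O) protein or
#' ligand atoms is reported as a bridge, with all leg distances and the
#' spread (max - min leg, zero when equidistant).  `extra_refs` requests
#' additional distances from each bridging water to named atoms that need
#' not be within hydrogen-bonding range (e.g. a nearby non-bonded ether
#' oxygen).
#'
#' @param model A `structure_model`.
#' @param max_dist Leg cutoff (Angstrom, default 3.5).
#' @param extra_refs Character vector of atom references
#'   (`"chain:resno:atom"` / `"resno:atom"`).
#' @return Data frame: `water`, `n_legs`, `partners` (semicolon-joined),
#'   `leg_distances` (semicolon-joined, 3 dp), `spread`, plus one column
#'   per extra reference.
#' @export
detect_water_bridges <- function(model, max_dist = 3.5, extra_refs = NULL) {
  atoms <- model$atoms
  wat <- atoms[atoms$resid %in% c("HOH", "WAT") & atoms$element == "O", ,
               drop = FALSE]
  polar <- atoms[atoms$element %in% c("N", "O") &
                   !(atoms$resid %in% c("HOH", "WAT")), , drop = FALSE]
  empty <- data.frame(water = character(0), n_legs = integer(0),
                      partners = character(0), leg_distances = character(0),
                      spread = numeric(0), stringsAsFactors = FALSE)
  if (nrow(wat) == 0L || nrow(polar) == 0L) return(empty)
  dm <- .pair_distances(wat, polar)
  rows <- list()
  for (i in seq_len(nrow(wat))) {
    legs <- which(dm[i, ] <= max_dist)
    if (length(legs) < 2L) next
    d <- dm[i, legs]
    row <- data.frame(
      water = .atom_label(wat[i, ]), n_legs = length(legs),
      partners = paste(vapply(legs, function(j)
        .atom_label(polar[j, ]), character(1)), collapse = ";"),
      leg_distances = paste(sprintf("%.3f", d), collapse = ";"),
      spread = max(d) - min(d), stringsAsFactors = FALSE)
    if (!is.null(extra_refs)) {
      for (ref in extra_refs) {
        tgt <- .resolve_atom(model, ref)
        row[[paste0("dist_", gsub(":", "_", ref))]] <-
          sqrt(sum((c(wat$x[i], wat$y[i], wat$z[i]) -
                      c(tgt$x, tgt$y, tgt$z))^2))
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residues lining a ligand pocket
#'
#' Protein residues with any heavy atom within `cutoff` of any ligand
#' heavy atom, sorted by minimum distance.
#'
#' @param model A `structure_model`.
#' @param ligand_selector Het code (string), or a list with any of
#'   `resid`, `resno`, `chain`.
#' @param cutoff Heavy-atom cutoff (Angstrom, default 4.5).
#' @return Data frame: `chain`, `resno`, `resid`, `min_distance`,
#'   ascending in distance.
#' @export
ligand_pocket_residues <- function(model, ligand_selector, cutoff = 4.5) {
  if (is.character(ligand_selector)) {
    ligand_selector <- list(resid = ligand_selector)
  }
  lig <- get_atoms(model, chain = ligand_selector$chain,
                   resno = ligand_selector$resno,
                   resid = ligand_selector$resid)
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) {
    hets <- unique(model$atoms$resid[model$atoms$het &
                                       !(model$atoms$resid %in%
                                           c("HOH", "WAT"))])
    stop(sprintf("ligand not found; het residues present: %s",
                 if (length(hets)) paste(hets, collapse = ", ") else "none"),
         call. = FALSE)
  }
  prot <- model$atoms[!model$atoms$het & model$atoms$element != "H" &
                        model$atoms$resid %in% .protein_residues, ,
                      drop = FALSE]
  if (nrow(prot) == 0L) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_distance = numeric(0)))
  }
  dm <- .pair_distances(prot, lig)
  prot$min_d <- apply(dm, 1, min)
  prot$key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  agg <- stats::aggregate(min_d ~ key + chain + resno + resid, data = prot,
                          FUN = min)
  agg <- agg[agg$min_d <= cutoff, , drop = FALSE]
  agg <- agg[order(agg$min_d), , drop = FALSE]
  data.frame(chain = agg$chain, resno = agg$resno, resid = agg$resid,
             min_distance = agg$min_d, stringsAsFactors = FALSE,
             row.names = NULL)
}
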