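# Protein-ligand interaction profiling: geometric hydrogen bonds,
# per-residue contact fingerprints, key-residue triage, and a pairwise
# Coulomb + Lennard-Jones per-residue energy decomposition.

#' Geometric hydrogen-bond criteria
#'
#' @param max_da_dist Maximum donor-acceptor heavy-atom distance,
#'   Angstroms (default 3.5).
#' @param min_dha_angle Minimum donor-H-acceptor angle, degrees
#'   (default 120). Skipped (distance-only call, flagged) when the donor
#'   carries no resolved hydrogens, as in crystallographic receptors.
#' @param polar_dist Polar-contact distance between any ligand N/O and
#'   residue N/O, Angstroms (default 4.0).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_dist = 3.5, min_dha_angle = 120,
                           polar_dist = 4.0) {
  stopifnot(max_da_dist > 0, polar_dist > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_dist = max_da_dist, min_dha_angle = min_dha_angle,
                 polar_dist = polar_dist),
            class = "hbond_criteria")
}

#' Key-residue triage rule
#'
#' The screen keeps poses that make polar contact with the key residues
#' of the UDP-binding pocket. The default set is Gln839/Lys842/Thr921;
#' the threonine is configurable (some analyses place it at 922) and
#' Asn557 can be added as an optional screen residue.
#'
#' @param residues Integer residue numbers required (default
#'   `c(839, 842, 921)`).
#' @param mode `"any"` (default): pass on contact with at least one
#'   required residue; `"all"`: contact with every one.
#' @return A `triage_rule` list.
#' @export
triage_rule <- function(residues = c(839, 842, 921), mode = c("any", "all")) {
  stopifnot(length(residues) >= 1)
  structure(list(residues = as.integer(residues), mode = match.arg(mode)),
            class = "triage_rule")
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# pose/receptor atom tables: element, x, y, z (+ optional charge).
.xyz <- function(tbl) as.matrix(tbl[, c("x", "y", "z")])

# Hydrogens are attached to their nearest heavy atom within a covalent
# cutoff of 1.3 A.
.attached_h <- function(tbl, heavy_idx, cutoff = 1.3) {
  h_idx <- which(tbl$element == "H")
  if (!length(h_idx)) return(rep(list(integer(0)), length(heavy_idx)))
  xyz <- .xyz(tbl)
  lapply(heavy_idx, function(i) {
    d <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[i, ])^2))
    h_idx[d <= cutoff]
  })
}

#' Detect hydrogen bonds between a pose and a receptor
#'
#' N/O atoms with at least one attached hydrogen are donors; all N/O
#' atoms are acceptors. A donor-acceptor pair is reported when the
#' heavy-atom distance is within `max_da_dist` and some donor hydrogen
#' gives a D-H-A angle of at least `min_dha_angle`. Donors with no
#' resolved hydrogens fall back to the distance-only criterion with
#' `angle_checked = FALSE`. Both directions (ligand donor -> protein
#' acceptor and protein donor -> ligand acceptor) are scanned.
#'
#' @param pose Ligand atom tibble (`element`, `x`, `y`, `z`; hydrogen
#'   rows included when available).
#' @param receptor Atom tibble from [parse_pdb()].
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble: `donor_side`, `donor_res`, `donor_atom`,
#'   `donor_index`, `acceptor_res`, `acceptor_atom`, `acceptor_index`,
#'   `distance`, `angle`, `angle_checked` (residue fields are `NA` on
#'   the ligand side; indices are row numbers in the pose/receptor
#'   tables).
#' @export
detect_hbonds <- function(pose, receptor, criteria = hbond_criteria()) {
  res_key <- paste(receptor$chain, receptor$resno, receptor$resname)
  lig_polar <- which(pose$element %in% c("N", "O"))
  rec_polar <- which(receptor$element %in% c("N", "O"))
  out <- list()
  if (length(lig_polar) && length(rec_polar)) {
    lig_h <- .attached_h(pose, lig_polar)
    rec_h <- .attached_h(receptor, rec_polar)
    lig_xyz <- .xyz(pose); rec_xyz <- .xyz(receptor)
    scan <- function(didx, dh, dxyz, aidx, axyz, side) {
      for (u in seq_along(didx)) {
        i <- didx[u]; hs <- dh[[u]]
        has_h_info <- length(which(
          if (side == "ligand") pose$element == "H" else receptor$element == "H")) > 0
        if (has_h_info && !length(hs)) next # hydrogens resolved, none on this atom
        for (j in aidx) {
          d <- .dist3(dxyz[i, ], axyz[j, ])
          if (d > criteria$max_da_dist) next
          if (length(hs)) {
            hxyz <- if (side == "ligand") lig_xyz else rec_xyz
            ang <- max(vapply(hs, function(h) {
              v1 <- dxyz[i, ] - hxyz[h, ]; v2 <- axyz[j, ] - hxyz[h, ]
              cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
              acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
            }, numeric(1)))
            if (ang < criteria$min_dha_angle) next
            checked <- TRUE
          } else {
            ang <- NA_real_
            checked <- FALSE
          }
          out[[length(out) + 1]] <<- tibble::tibble(
            donor_side = side,
            donor_res = if (side == "protein") res_key[i] else NA_character_,
            donor_atom = if (side == "protein") receptor$atom_name[i]
                         else as.character(i),
            donor_index = i,
            acceptor_res = if (side == "ligand") res_key[j] else NA_character_,
            acceptor_atom = if (side == "ligand") receptor$atom_name[j]
                            else as.character(j),
            acceptor_index = j,
            distance = d, angle = ang, angle_checked = checked
          )
        }
      }
    }
    scan(lig_polar, lig_h, lig_xyz, rec_polar, rec_xyz, "ligand")
    scan(rec_polar, rec_h, rec_xyz, lig_polar, lig_xyz, "protein")
  }
  if (!length(out)) {
    return(tibble::tibble(
      donor_side = character(0), donor_res = character(0),
      donor_atom = character(0), donor_index = integer(0),
      acceptor_res = character(0), acceptor_atom = character(0),
      acceptor_index = integer(0), distance = numeric(0),
      angle = numeric(0), angle_checked = logical(0)
    ))
  }
  dplyr::bind_rows(out)
}

#' Per-residue contact fingerprint for one pose
#'
#' For every receptor residue: whether it hydrogen-bonds the pose
#' ([detect_hbonds()]), whether any of its N/O atoms lies within the
#' polar-contact distance of a ligand N/O, and (when `params` is
#' supplied) its pairwise interaction energy from
#' [per_residue_energy()], else zero. A hydrogen bond always implies a
#' polar contact.
#'
#' @param pose Ligand atom tibble.
#' @param receptor Atom tibble from [parse_pdb()].
#' @param criteria An [hbond_criteria()] object.
#' @param params Optional [lj_params()] table enabling the energy
#'   column; pose and receptor then need `charge` columns.
#' @param ligand_id,pose_id Identifier columns for the report.
#' @return `contact_fingerprint` tibble: `ligand_id`, `pose_id`,
#'   `chain`, `resno`, `resname`, `has_hbond`, `has_polar`,
#'   `energy_kcal_mol`.
#' @export
contact_fingerprint <- function(pose, receptor, criteria = hbond_criteria(),
                                params = NULL,
                                ligand_id = "ligand", pose_id = "pose") {
  residues <- dplyr::distinct(receptor, .data$chain, .data$resno, .data$resname)
  hb <- detect_hbonds(pose, receptor, criteria)
  hb_res <- unique(stats::na.omit(c(hb$donor_res, hb$acceptor_res)))

  lig_polar <- .xyz(pose[pose$element %in% c("N", "O"), , drop = FALSE])
  res_key <- paste(residues$chain, residues$resno, residues$resname)
  rec_key <- paste(receptor$chain, receptor$resno, receptor$resname)
  has_polar <- vapply(res_key, function(rk) {
    if (!nrow(lig_polar)) return(FALSE)
    rp <- receptor[rec_key == rk & receptor$element %in% c("N", "O"), ,
                   drop = FALSE]
    if (!nrow(rp)) return(FALSE)
    rxyz <- .xyz(rp)
    any(vapply(seq_len(nrow(rxyz)), function(r) {
      min(sqrt(colSums((t(lig_polar) - rxyz[r, ])^2))) <= criteria$polar_dist
    }, logical(1)))
  }, logical(1))
  has_hbond <- res_key %in% hb_res
  has_polar <- has_polar | has_hbond

  energy <- rep(0, nrow(residues))
  if (!is.null(params)) {
    en <- per_residue_energy(pose, receptor, params = params)
    idx <- match(res_key, paste(en$chain, en$resno, en$resname))
    energy <- ifelse(is.na(idx), 0, en$energy_kcal_mol[idx])
  }
  out <- tibble::tibble(
    ligand_id = ligand_id, pose_id = pose_id,
    chain = residues$chain, resno = residues$resno,
    resname = residues$resname,
    has_hbond = unname(has_hbond), has_polar = unname(has_polar),
    energy_kcal_mol = energy
  )
  class(out) <- c("contact_fingerprint", class(out))
  out
}

#' Triage a pose against the key-residue guideline
#'
#' @param fp A [contact_fingerprint()] table.
#' @param rule A [triage_rule()] object.
#' @return List: `pass` flag and `matched` (residue numbers of required
#'   residues with polar contact). Errors if a required residue is not
#'   in the receptor model.
#' @export
triage_key_residues <- function(fp, rule = triage_rule()) {
  absent <- setdiff(rule$residues, fp$resno)
  if (length(absent))
    stop("required residue(s) absent from the receptor model: ",
         paste(absent, collapse = ", "), call. = FALSE)
  contacted <- fp$resno[fp$has_polar]
  matched <- intersect(rule$residues, contacted)
  pass <- if (rule$mode == "any") length(matched) >= 1
          else length(matched) == length(rule$residues)
  list(pass = pass, matched = matched)
}

#' Element-based Lennard-Jones parameter table
#'
#' Minimal built-in 12-6 parameters (`rmin_half` in Angstroms, `epsilon`
#' in kcal/mol) keyed by element, in the Amber spirit; partial charges
#' are always user-supplied. Rows can be added or overridden.
#'
#' @param extra Optional tibble with columns `element`, `rmin_half`,
#'   `epsilon` overriding or extending the defaults.
#' @return Parameter tibble.
#' @export
lj_params <- function(extra = NULL) {
  tbl <- tibble::tibble(
    element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
    rmin_half = c(0.600, 1.908, 1.824, 1.661, 2.000, 2.100,
                  1.750, 1.948, 2.220, 2.350),
    epsilon = c(0.0157, 0.0860, 0.1700, 0.2100, 0.2500, 0.2000,
                0.0610, 0.2650, 0.3200, 0.4000)
  )
  if (!is.null(extra)) {
    tbl <- dplyr::bind_rows(
      dplyr::anti_join(tbl, extra, by = "element"), extra
    )
  }
  tbl
}

COULOMB_K <- 332.0636 # kcal * A / (mol * e^2)

.pair_energy_terms <- function(pose, receptor, params, cutoff, dielectric) {
  need_cols <- function(tbl, what) {
    if (!"charge" %in% names(tbl))
      stop(sprintf("missing partial charge column on %s atoms", what),
           call. = FALSE)
    if (anyNA(tbl$charge))
      stop(sprintf("missing partial charge on %s atom %d", what,
                   which(is.na(tbl$charge))[1]), call. = FALSE)
  }
  need_cols(pose, "pose"); need_cols(receptor, "receptor")
  param_of <- function(el, what) {
    idx <- match(el, params$element)
    if (anyNA(idx))
      stop(sprintf("no LJ parameters for %s element '%s'",
                   what, el[which(is.na(idx))[1]]), call. = FALSE)
    params[idx, ]
  }
  lp <- param_of(pose$element, "pose")
  rp <- param_of(receptor$element, "receptor")
  lx <- .xyz(pose); rx <- .xyz(receptor)
  # pairwise distances, receptor atoms x ligand atoms
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), `+`) - 2 * rx %*% t(lx)
  d <- sqrt(pmax(d2, 0))
  within <- d <= cutoff & d > 0
  qq <- outer(receptor$charge, pose$charge)
  coul <- ifelse(within, COULOMB_K * qq / (dielectric * d), 0)
  rmin <- outer(rp$rmin_half, lp$rmin_half, `+`)
  eps <- sqrt(outer(rp$epsilon, lp$epsilon))
  ratio6 <- ifelse(within, (rmin / pmax(d, 1e-12))^6, 0)
  lj <- ifelse(within, eps * (ratio6^2 - 2 * ratio6), 0)
  rowSums(coul + lj)
}

#' Per-residue pairwise interaction-energy decomposition
#'
#' For each receptor residue, the sum over (residue atom, ligand atom)
#' pairs within the cutoff of a Coulomb term `332.0636 * qi*qj / (eps_r
#' * r)` plus a 12-6 Lennard-Jones term
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with Lorentz-Berthelot
#' combination. This is a geometric pairwise surrogate used for triage
#' and ranking of pocket residues, not a binding free energy.
#'
#' @param pose Ligand atom tibble with `charge`.
#' @param receptor Atom tibble with `charge`.
#' @param params [lj_params()] table.
#' @param cutoff Pair cutoff, Angstroms (default 10).
#' @param dielectric Relative dielectric constant (default 1).
#' @return Tibble: `chain`, `resno`, `resname`, `energy_kcal_mol`, with
#'   a `total` attribute equal to the sum over residues.
#' @export
per_residue_energy <- function(pose, receptor, params = lj_params(),
                               cutoff = 10, dielectric = 1) {
  stopifnot(cutoff > 0, dielectric > 0)
  atom_e <- .pair_energy_terms(pose, receptor, params, cutoff, dielectric)
  out <- receptor |>
    dplyr::mutate(.energy = atom_e) |>
    dplyr::summarise(energy_kcal_mol = sum(.data$.energy),
                     .by = c("chain", "resno", "resname"))
  attr(out, "total") <- sum(out$energy_kcal_mol)
  out
}

#' Write fingerprint and triage reports as TSV
#'
#' @param fp A [contact_fingerprint()] table.
#' @param path Output path.
#' @export
write_fingerprint <- function(fp, path) {
  readr::write_tsv(fp, path)
  invisible(path)
}
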