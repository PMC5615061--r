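# Receptor structures, Kabsch superposition, pose RMSD and pose
# clustering.

#' Parse PDB text into an atom table
#'
#' Fixed-column `ATOM`/`HETATM` records are read (through bio3d) into a
#' tibble; for atoms with alternate locations the first occurrence is
#' kept. HETATM ligand records are retained under their residue name.
#'
#' @param text PDB-format text (single string or character vector of
#'   lines), or a path to a `.pdb` file.
#' @param id Structure identifier.
#' @return Tibble with `chain`, `resno`, `insert`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `het`.
#' @export
parse_pdb <- function(text, id = "structure") {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    path <- text
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(text) == 1) strsplit(text, "\n")[[1]] else text, path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("no ATOM/HETATM records parsed: ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!nrow(at)) stop("no ATOM/HETATM records parsed", call. = FALSE)
  out <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     toupper(substr(gsub("[0-9]", "", at$elety), 1, 1)),
                     at$elesy),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM"
  )
  # keep-first alternate-location policy
  out <- dplyr::distinct(
    out, .data$chain, .data$resno, .data$insert, .data$resname,
    .data$atom_name, .keep_all = TRUE
  )
  stopifnot(all(is.finite(out$x)), all(is.finite(out$y)), all(is.finite(out$z)))
  attr(out, "id") <- id
  out
}

#' Format an atom table as PDB text
#'
#' Minimal fixed-column writer for toy structures and poses.
#'
#' @param atoms Tibble in the [parse_pdb()] layout.
#' @return Character vector of PDB lines (no END record).
#' @export
format_pdb <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(k) {
    a <- atoms[k, ]
    rec <- if (isTRUE(a$het)) "HETATM" else "ATOM  "
    sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, k,
            if (nchar(a$atom_name) < 4) paste0(" ", a$atom_name) else a$atom_name,
            " ", a$resname, if (nzchar(a$chain)) a$chain else "A",
            a$resno, " ", a$x, a$y, a$z,
            if (is.null(a$occupancy)) 1 else a$occupancy, 0, a$element)
  }, character(1))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto
#' `reference` via SVD of the cross-covariance matrix, with the
#' reflection case resolved to a proper rotation (determinant +1).
#'
#' @param mobile,reference n x 3 matrices of paired coordinates
#'   (n >= 3, not collinear).
#' @return A `superposition`: list with `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (post-fit, Angstroms) and `n` atoms paired.
#'   The fitted coordinates are `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3) stop("need at least 3 paired atoms", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  scale <- sqrt(sum(Pc^2) / n)
  if (scale == 0) stop("degenerate configuration: all points coincide", call. = FALSE)
  sv_chk <- svd(Pc)$d
  if (sv_chk[2] / sv_chk[1] < 1e-8)
    stop("degenerate configuration: points are collinear", call. = FALSE)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(sum((fitted - Qc)^2) / n)
  structure(
    list(rotation = R, translation = as.numeric(cq - R %*% cp),
         rmsd = rmsd, n = n),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> n = %d atoms, rmsd = %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A [kabsch_superpose()] result.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Superpose one structure onto another over common CA atoms
#'
#' Pairs CA atoms present in both structures by (chain, residue number,
#' insertion code) and runs [kabsch_superpose()] on the paired
#' coordinates — the standard common-core alignment used to bring the
#' receptor ensemble into one frame before ensemble pose clustering.
#'
#' @param mobile,reference Atom tibbles from [parse_pdb()].
#' @return List: the `superposition` plus `atoms`, the mobile table with
#'   transformed coordinates.
#' @export
superpose_structures <- function(mobile, reference) {
  key <- function(s) paste(s$chain, s$resno, s$insert)
  mca <- dplyr::filter(mobile, .data$atom_name == "CA")
  rca <- dplyr::filter(reference, .data$atom_name == "CA")
  common <- intersect(key(mca), key(rca))
  if (length(common) < 3)
    stop("fewer than 3 common CA atoms between the structures", call. = FALSE)
  mca <- mca[match(common, key(mca)), ]
  rca <- rca[match(common, key(rca)), ]
  sp <- kabsch_superpose(as.matrix(mca[, c("x", "y", "z")]),
                         as.matrix(rca[, c("x", "y", "z")]))
  moved <- apply_superposition(sp, as.matrix(mobile[, c("x", "y", "z")]))
  out <- mobile
  out$x <- moved[, 1]; out$y <- moved[, 2]; out$z <- moved[, 3]
  list(superposition = sp, atoms = out)
}

#' In-place RMSD between two poses
#'
#' Root-mean-square deviation over corresponding atoms with no refitting
#' — poses are assumed to already live in the common (superposed) frame.
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in Angstroms.
#' @export
pose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("pose coordinate dimensions differ", call. = FALSE)
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Cluster docking poses by in-place RMSD
#'
#' Single-linkage clustering at a fixed RMSD radius, equivalent to the
#' connected components of the graph joining pose pairs with RMSD <=
#' threshold. The biggest cluster is selected (ties go to the cluster
#' holding the most negative affinity, then the lowest pose id) and its
#' representative is the member with the best affinity (fallback: lowest
#' pose id).
#'
#' @param poses Named list of n x 3 coordinate matrices (same atom
#'   ordering), or a list with elements `coords` and optional
#'   `affinity`.
#' @param threshold Cluster radius, Angstroms (default 2).
#' @param affinities Optional named/numeric vector of pose affinities
#'   (kcal/mol) aligned with `poses`.
#' @return A `pose_cluster` list: `assignments` tibble (`pose_id`,
#'   `cluster`, `cluster_size`, `is_biggest`, `is_representative`),
#'   `threshold`, `biggest_cluster`, `representative`.
#' @export
cluster_poses <- function(poses, threshold = 2, affinities = NULL) {
  stopifnot(length(poses) >= 1, threshold > 0)
  ids <- names(poses)
  if (is.null(ids)) ids <- sprintf("pose%02d", seq_along(poses))
  n <- length(poses)
  if (is.null(affinities)) affinities <- rep(NA_real_, n)

  if (n == 1) {
    labels <- 1L
  } else {
    dmat <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dmat[i, j] <- dmat[j, i] <- pose_rmsd(poses[[i]], poses[[j]])
    }
    hc <- stats::hclust(stats::as.dist(dmat), method = "single")
    labels <- stats::cutree(hc, h = threshold)
  }
  sizes <- table(labels)
  max_size <- max(sizes)
  cand <- as.integer(names(sizes)[sizes == max_size])
  if (length(cand) > 1 && any(!is.na(affinities))) {
    best_aff <- vapply(cand, function(cl) {
      v <- affinities[labels == cl]
      if (all(is.na(v))) Inf else min(v, na.rm = TRUE)
    }, numeric(1))
    cand <- cand[best_aff == min(best_aff)]
  }
  biggest <- min(cand)
  members <- which(labels == biggest)
  rep_idx <- if (any(!is.na(affinities[members]))) {
    members[which.min(replace(affinities[members],
                              is.na(affinities[members]), Inf))]
  } else members[order(ids[members])[1]]

  assignments <- tibble::tibble(
    pose_id = ids,
    cluster = as.integer(labels),
    cluster_size = as.integer(sizes[as.character(labels)]),
    is_biggest = labels == biggest,
    is_representative = seq_len(n) == rep_idx
  )
  structure(
    list(assignments = assignments, threshold = threshold,
         biggest_cluster = biggest, representative = ids[rep_idx]),
    class = "pose_cluster"
  )
}

#' @export
print.pose_cluster <- function(x, ...) {
  cat(sprintf(
    "<pose_cluster> %d poses, %d cluster(s) at %.1f A; biggest = %d (n = %d), representative = %s\n",
    nrow(x$assignments), length(unique(x$assignments$cluster)), x$threshold,
    x$biggest_cluster, max(x$assignments$cluster_size), x$representative
  ))
  invisible(x)
}

#' Write a pose-cluster report as TSV
#'
#' @param cl A [cluster_poses()] result.
#' @param path Output path.
#' @param ligand_id Ligand identifier column value.
#' @export
write_cluster_report <- function(cl, path, ligand_id = "ligand") {
  out <- dplyr::mutate(cl$assignments, ligand_id = ligand_id, .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}
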