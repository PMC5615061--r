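# Independent oracles used to cross-check the package's own
# implementations. Each is written from the definition, without reusing
# package internals.

# Horn's quaternion method for the optimal-superposition RMSD: the
# residual is (Gp + Gq - 2*lambda_max)/n with lambda_max the largest
# eigenvalue of the 4x4 key matrix built from the cross-covariance.
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P), 0))
}

# group / min / mean / sort recomputation of the consensus ranking,
# in base R
brute_consensus <- function(scores) {
  rows <- lapply(split(scores, scores$ligand_id), function(d) {
    bests <- tapply(d$affinity_kcal_mol, d$receptor_id, min)
    data.frame(ligand_id = d$ligand_id[1], mean_affinity = mean(bests),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_affinity, out$ligand_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# flat double loop over all atom pairs: Coulomb + 12-6 LJ within cutoff
brute_total_energy <- function(pose, receptor, params, cutoff = 10,
                               dielectric = 1) {
  k <- 332.0636
  total <- 0
  for (i in seq_len(nrow(receptor))) {
    pi_ <- params[match(receptor$element[i], params$element), ]
    for (j in seq_len(nrow(pose))) {
      pj <- params[match(pose$element[j], params$element), ]
      r <- sqrt((receptor$x[i] - pose$x[j])^2 +
                (receptor$y[i] - pose$y[j])^2 +
                (receptor$z[i] - pose$z[j])^2)
      if (r > cutoff || r == 0) next
      rmin <- pi_$rmin_half + pj$rmin_half
      eps <- sqrt(pi_$epsilon * pj$epsilon)
      total <- total + k * receptor$charge[i] * pose$charge[j] /
        (dielectric * r) +
        eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  total
}

# O(n^2) donor/acceptor scan from the geometric definition
brute_hbond_pairs <- function(pose, receptor, max_da = 3.5, min_angle = 120) {
  att_h <- function(tbl, i) {
    hs <- which(tbl$element == "H")
    hs[vapply(hs, function(h) {
      sqrt((tbl$x[h] - tbl$x[i])^2 + (tbl$y[h] - tbl$y[i])^2 +
             (tbl$z[h] - tbl$z[i])^2) <= 1.3
    }, logical(1))]
  }
  ang <- function(D, H, A) {
    v1 <- D - H; v2 <- A - H
    acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
  }
  xyz <- function(tbl, i) c(tbl$x[i], tbl$y[i], tbl$z[i])
  found <- character(0)
  sides <- list(list(d = pose, a = receptor, tag = "ligand"),
                list(d = receptor, a = pose, tag = "protein"))
  for (s in sides) {
    has_h <- any(s$d$element == "H")
    for (i in which(s$d$element %in% c("N", "O"))) {
      hs <- att_h(s$d, i)
      if (has_h && !length(hs)) next
      for (j in which(s$a$element %in% c("N", "O"))) {
        r <- sqrt(sum((xyz(s$d, i) - xyz(s$a, j))^2))
        if (r > max_da) next
        if (length(hs)) {
          best <- max(vapply(hs, function(h)
            ang(xyz(s$d, i), xyz(s$d, h), xyz(s$a, j)), numeric(1)))
          if (best < min_angle) next
        }
        found <- c(found, paste(s$tag, i, j))
      }
    }
  }
  sort(found)
}

# random rigid-body transform (proper rotation + translation)
random_rigid <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(tbl, tr) {
  xyz <- as.matrix(tbl[, c("x", "y", "z")]) %*% t(tr$R)
  xyz <- sweep(xyz, 2, tr$t, `+`)
  tbl$x <- xyz[, 1]; tbl$y <- xyz[, 2]; tbl$z <- xyz[, 3]
  tbl
}

# small random score table for consensus checks
random_score_table <- function(n_lig = 6, n_rec = 3, n_pose = 2) {
  tibble::tibble(
    ligand_id = rep(sprintf("L%02d", seq_len(n_lig)), each = n_rec * n_pose),
    receptor_id = rep(rep(sprintf("R%d", seq_len(n_rec)), each = n_pose),
                      times = n_lig),
    pose_rank = rep(seq_len(n_pose), times = n_lig * n_rec),
    affinity_kcal_mol = round(stats::rnorm(n_lig * n_rec * n_pose, -7, 1), 3)
  )
}
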