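# Seeded synthetic-data generators. Every generated artifact carries its
# ground truth by construction, so each pipeline stage can be tested
# offline against planted values. Each generator draws from its own
# stream, derived from the top-level seed by a fixed offset, so adding a
# generator never perturbs the others.

seed_offset <- c(library = 101L, scores = 202L, complex = 303L, assay = 404L)

#' Bundle of generator parameters
#'
#' Defaults mirror the screening study's scale: a 16-member receptor
#' ensemble, 4234 screened decoys with 10 planted actives, top-200
#' selection, the 0.25-500 uM dose grid with triplicates at 5% CV and a
#' planted potency of 21.8 uM. All scales are configurable downward for
#' fast tests.
#'
#' @param seed Top-level integer seed.
#' @param library List: `n` molecules and per-rule `pass_fractions`
#'   (named `mw`, `charge`, `rings`, `hbonds`, each in `[0, 1]`).
#' @param scores List: `n_decoys`, `n_actives`, `ensemble` (receptor
#'   ids), `active_mean`/`active_sd` and `decoy_mean`/`decoy_sd`
#'   (kcal/mol), `receptor_jitter_sd`, `poses_per_pair`,
#'   `pose_offset_scale`.
#' @param complex List: `contacts` (list of `list(resno, dist, angle)`),
#'   `n_poses`, `pose_jitter`, `n_outliers`, `outlier_shift`.
#' @param assay List: `ic50`, `hill`, `doses`, `replicates`, `cv`,
#'   `mode`, `Ki`, `Km`, `alpha`, `S_grid`.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1,
                           library = list(),
                           scores = list(),
                           complex = list(),
                           assay = list()) {
  lib <- utils::modifyList(list(
    n = 1000,
    pass_fractions = c(mw = 0.7, charge = 0.8, rings = 0.7, hbonds = 0.7)
  ), library)
  sc <- utils::modifyList(list(
    n_decoys = 4234, n_actives = 10, ensemble = ogt_ensemble_ids(),
    active_mean = -9.0, active_sd = 0.5,
    decoy_mean = -6.0, decoy_sd = 1.0,
    receptor_jitter_sd = 0.25, poses_per_pair = 3, pose_offset_scale = 0.5
  ), scores)
  cx <- utils::modifyList(list(
    contacts = list(list(resno = 842, dist = 2.8, angle = 170)),
    n_poses = 5, pose_jitter = 0.5, n_outliers = 1, outlier_shift = 10
  ), complex)
  # modifyList merges nested lists recursively; the contact list is
  # positional and must be replaced wholesale
  if (!is.null(complex$contacts)) cx$contacts <- complex$contacts
  as_ <- utils::modifyList(list(
    ic50 = 21.8, hill = 1, doses = default_dose_grid(),
    replicates = 3, cv = 0.05,
    mode = "competitive", Ki = 10, Km = 20, alpha = 2,
    S_grid = default_substrate_grid()
  ), assay)
  stopifnot(all(lib$pass_fractions >= 0 & lib$pass_fractions <= 1),
            sc$n_actives <= sc$n_decoys + sc$n_actives)
  structure(list(seed = as.integer(seed), library = lib, scores = sc,
                 complex = cx, assay = as_),
            class = "generator_spec")
}

# ---- compound library ------------------------------------------------

# Assemble one molecule compositionally. Cyclohexane scaffolds control
# the ring-system count, hydroxyl/amine substituents the donor count,
# methoxy groups extra acceptors, charged tails the ionization state,
# and a methylene tail tunes the molecular weight. Formula bookkeeping
# runs alongside the SMILES string, so every descriptor's true value is
# recorded by construction.
build_molecule <- function(n_rings, n_oh, n_ome, charge_type, mw_mode) {
  n_subs <- n_oh + n_ome +
    switch(charge_type, none = 0L, pos = 1L, neg = 1L, zwitter = 2L)
  capacity <- if (n_rings > 0) 4L * n_rings else 1000L
  if (n_subs > capacity)
    stop(sprintf("infeasible molecule: %d substituents exceed %d slots",
                 n_subs, capacity), call. = FALSE)

  subs <- c(rep("(O)", n_oh), rep("(OC)", n_ome),
            switch(charge_type,
                   none = character(0), pos = "([NH3+])",
                   neg = "(C(=O)[O-])", zwitter = c("([NH3+])", "(C(=O)[O-])")))
  nC <- 0; nH <- 0; nN <- 0; nO <- 0
  add_sub <- function(s) {
    nH <<- nH - 1 # slot hydrogen replaced
    switch(s,
      "(O)" = { nO <<- nO + 1; nH <<- nH + 1 },
      "(OC)" = { nO <<- nO + 1; nC <<- nC + 1; nH <<- nH + 3 },
      "([NH3+])" = { nN <<- nN + 1; nH <<- nH + 3 },
      "(C(=O)[O-])" = { nC <<- nC + 1; nO <<- nO + 2 }
    )
  }
  smi <- ""
  if (n_rings > 0) {
    si <- 1
    for (r in seq_len(n_rings)) {
      nC <- nC + 6; nH <- nH + 12
      if (r > 1) nH <- nH - 2 # link to previous ring costs one H each side
      ring_subs <- character(4)
      for (slot in 1:4) {
        if (si <= length(subs)) {
          ring_subs[slot] <- subs[si]
          add_sub(subs[si])
          si <- si + 1
        }
      }
      smi <- paste0(smi, "C1C", ring_subs[1], "C", ring_subs[2],
                    "C", ring_subs[3], "C", ring_subs[4], "C1")
    }
  } else {
    k <- max(3L, n_subs + 2L)
    nC <- nC + k; nH <- nH + 2 * k + 2
    toks <- rep("C", k)
    for (si in seq_along(subs)) {
      toks[1 + si] <- paste0("C", subs[si])
      add_sub(subs[si])
    }
    smi <- paste0(toks, collapse = "")
  }

  mass <- function() nC * 12.011 + nH * 1.008 + nN * 14.007 + nO * 15.999
  tail_c <- 0L
  if (mw_mode == "pass") {
    while (mass() < 250) { nC <- nC + 1; nH <- nH + 2; tail_c <- tail_c + 1L }
    if (mass() > 600)
      stop("infeasible molecule: base mass already above the window",
           call. = FALSE)
  } else if (mw_mode == "heavy") {
    while (mass() <= 600) { nC <- nC + 1; nH <- nH + 2; tail_c <- tail_c + 1L }
  } else if (mw_mode == "light") {
    if (mass() >= 250)
      stop("infeasible molecule: base mass already above 250", call. = FALSE)
  } # "asis": keep the assembled mass unchanged
  if (tail_c > 0) smi <- paste0(smi, strrep("C", tail_c))

  net_charge <- switch(charge_type, none = 0L, pos = 1L, neg = -1L,
                       zwitter = 0L)
  list(
    smiles = smi,
    truth = tibble::tibble(
      mw = mass(),
      net_charge = net_charge,
      is_zwitterion = charge_type == "zwitter",
      n_ring_systems = as.integer(n_rings),
      hba = as.integer(n_oh + n_ome +
        switch(charge_type, none = 0L, pos = 1L, neg = 2L, zwitter = 3L)),
      hbd = as.integer(n_oh +
        switch(charge_type, none = 0L, pos = 1L, neg = 0L, zwitter = 1L))
    )
  )
}

#' Generate a synthetic compound library with planted descriptors
#'
#' Each molecule is assembled compositionally so its molecular weight,
#' ionization, ring-system count and donor/acceptor counts are known by
#' construction; per-rule pass/fail status is drawn independently at the
#' spec's `pass_fractions`.
#'
#' @param spec A [generator_spec()].
#' @return List: `molecules` (list of `mol_graph`s with SMILES
#'   attached) and `truth` (tibble of planted descriptors and the
#'   intended pass flags under the default [filter_rules()]).
#' @export
gen_library <- function(spec = generator_spec()) {
  lib <- spec$library
  pf <- lib$pass_fractions
  withr_seed(spec$seed + seed_offset[["library"]], {
    rows <- vector("list", lib$n)
    mols <- vector("list", lib$n)
    for (k in seq_len(lib$n)) {
      pass_mw <- stats::runif(1) < pf[["mw"]]
      pass_charge <- stats::runif(1) < pf[["charge"]]
      pass_rings <- stats::runif(1) < pf[["rings"]]
      pass_hbonds <- stats::runif(1) < pf[["hbonds"]]

      n_rings <- if (pass_rings) sample(2:4, 1) else sample(c(0L, 1L, 5L, 6L), 1)
      charge_type <- if (pass_charge) "none"
        else sample(c("pos", "neg", "zwitter"), 1)
      # charged tails carry N/O that would defeat an intended
      # donor/acceptor failure; failing molecules keep neutral tails
      if (!pass_hbonds && charge_type %in% c("pos", "zwitter"))
        charge_type <- "neg"
      n_charged <- switch(charge_type, none = 0L, pos = 1L, neg = 1L,
                          zwitter = 2L)
      slots_left <- (if (n_rings > 0) 4L * n_rings else 99L) - n_charged
      if (pass_hbonds) {
        n_oh <- sample(2:min(4L, slots_left), 1)
        n_ome <- sample(0:min(2L, slots_left - n_oh), 1)
      } else {
        n_oh <- sample(0:min(1L, slots_left), 1)
        n_ome <- if (n_oh >= 1) 0L else sample(0:min(1L, slots_left), 1)
        if (charge_type == "neg") n_oh <- 0L
      }
      # keep heavily ringed molecules inside the weight window when the
      # weight rule is meant to pass
      est_mass <- n_rings * 84.3 + n_oh * 16 + n_ome * 30 + n_charged * 35
      if (pass_mw) {
        while (est_mass > 580 && n_ome > 0) {
          n_ome <- n_ome - 1L; est_mass <- est_mass - 30
        }
        while (est_mass > 580 && n_oh > (if (pass_hbonds) 2L else 0L)) {
          n_oh <- n_oh - 1L; est_mass <- est_mass - 16
        }
      }
      base_mass <- build_molecule(n_rings, n_oh, n_ome, charge_type,
                                  "asis")$truth$mw
      mw_mode <- if (pass_mw) "pass" else {
        if (base_mass < 240 && stats::runif(1) < 0.5) "light" else "heavy"
      }
      bm <- build_molecule(n_rings, n_oh, n_ome, charge_type, mw_mode)
      id <- sprintf("SYN%05d", k)
      m <- parse_smiles(bm$smiles, id = id)
      mols[[k]] <- m
      rows[[k]] <- dplyr::mutate(bm$truth, id = id, smiles = bm$smiles,
                                 .before = 1)
    }
    truth <- dplyr::bind_rows(rows)
  })
  rules <- filter_rules()
  truth <- truth |>
    dplyr::mutate(
      pass_mw = .data$mw >= rules$mw_min & .data$mw <= rules$mw_max,
      pass_charge = .data$net_charge == 0L & !.data$is_zwitterion,
      pass_rings = .data$n_ring_systems >= rules$ring_systems_min &
        .data$n_ring_systems <= rules$ring_systems_max,
      pass_hbonds = .data$hba >= rules$hba_min & .data$hbd >= rules$hbd_min,
      pass_overall = .data$pass_mw & .data$pass_charge &
        .data$pass_rings & .data$pass_hbonds
    )
  list(molecules = mols, truth = truth)
}

# ---- docking score matrices ------------------------------------------

#' Generate a synthetic ligand-by-receptor docking score table
#'
#' Poses are drawn around a ligand-level latent affinity (actives
#' stronger than decoys), with receptor-level Gaussian jitter and
#' strictly positive pose-level offsets, so the first pose of each
#' ligand-receptor pair is its best by construction.
#'
#' @param spec A [generator_spec()].
#' @return List: `scores` (long tibble `ligand_id`, `receptor_id`,
#'   `pose_rank`, `affinity_kcal_mol`), `active_ids`, and `latent`
#'   (per-ligand true mean affinity).
#' @export
gen_score_matrix <- function(spec = generator_spec()) {
  sc <- spec$scores
  n <- sc$n_decoys + sc$n_actives
  ids <- sprintf("LIG%05d", seq_len(n))
  R <- length(sc$ensemble)
  P <- sc$poses_per_pair
  withr_seed(spec$seed + seed_offset[["scores"]], {
    active_ids <- sort(sample(ids, sc$n_actives))
    is_active <- ids %in% active_ids
    latent <- ifelse(is_active,
                     stats::rnorm(n, sc$active_mean, sc$active_sd),
                     stats::rnorm(n, sc$decoy_mean, sc$decoy_sd))
    base <- rep(latent, each = R) +
      stats::rnorm(n * R, 0, sc$receptor_jitter_sd)
    offsets <- matrix(abs(stats::rnorm(n * R * P, 0, sc$pose_offset_scale)),
                      nrow = n * R, ncol = P)
    offsets[, 1] <- 0
    if (P > 1) offsets[, -1] <- t(apply(offsets[, -1, drop = FALSE], 1, cumsum))
  })
  scores <- tibble::tibble(
    ligand_id = rep(ids, each = R * P),
    receptor_id = rep(rep(sc$ensemble, each = P), times = n),
    pose_rank = rep(seq_len(P), times = n * R),
    affinity_kcal_mol = as.vector(t(offsets)) + rep(base, each = P)
  )
  list(scores = scores,
       active_ids = active_ids,
       latent = tibble::tibble(ligand_id = ids, latent_affinity = latent,
                               is_active = is_active))
}

# ---- toy binding pocket ----------------------------------------------

toy_pocket_residues <- function() {
  tibble::tibble(
    resname = c("ASN", "GLN", "LYS", "HIS", "THR"),
    resno = c(557L, 839L, 842L, 920L, 921L),
    polar_atom = c("ND2", "NE2", "NZ", "NE2", "OG1"),
    polar_element = c("N", "N", "N", "N", "O")
  )
}

#' Generate a toy pocket, ligand poses and planted interaction truth
#'
#' Five pocket residues (Asn557, Gln839, Lys842, His920, Thr921) are
#' placed on a ring around the site with their polar side-chain atoms
#' pointing inward; a ligand pose is planted so that each requested
#' contact realizes exactly the requested donor-acceptor distance and
#' D-H-A angle (the ligand hydroxyl is the donor). Additional poses are
#' jittered copies for clustering, plus displaced outliers.
#'
#' @param spec A [generator_spec()]; `spec$complex$contacts` lists the
#'   planted hydrogen bonds as `list(resno =, dist =, angle =)`.
#' @return List: `receptor` (atom tibble with charges), `pose` (ligand
#'   atom tibble with charges), `poses` (named list of jittered
#'   coordinate matrices), `pose_affinities`, and `truth` (`contact_resno`,
#'   `dist`, `angle`).
#' @export
gen_toy_complex <- function(spec = generator_spec()) {
  cx <- spec$complex
  resdef <- toy_pocket_residues()
  nres <- nrow(resdef)
  theta <- 2 * pi * (seq_len(nres) - 1) / nres
  r_polar <- 5; r_ca <- 9

  rec <- purrr::map_dfr(seq_len(nres), function(i) {
    dir <- c(cos(theta[i]), sin(theta[i]))
    tibble::tibble(
      chain = "A",
      resno = resdef$resno[i], insert = "", resname = resdef$resname[i],
      atom_name = c("N", "CA", "C", resdef$polar_atom[i]),
      element = c("N", "C", "C", resdef$polar_element[i]),
      x = c(r_ca * dir[1] + 0.8, r_ca * dir[1], r_ca * dir[1] - 0.8,
            r_polar * dir[1]),
      y = c(r_ca * dir[2], r_ca * dir[2], r_ca * dir[2] + 0.8,
            r_polar * dir[2]),
      z = c(0.5, 0, -0.5, 0),
      occupancy = 1, alt = "", het = FALSE
    )
  })

  for (ct in cx$contacts) {
    if (!ct$resno %in% resdef$resno)
      stop("unknown pocket residue ", ct$resno, call. = FALSE)
    if (ct$dist <= 1.1)
      stop("planted donor-acceptor distance must exceed the O-H bond length",
           call. = FALSE)
    if (ct$angle <= 0 || ct$angle > 180)
      stop("planted angle must lie in (0, 180]", call. = FALSE)
  }

  # ligand: central carbon plus one hydroxyl (O + H) per planted contact
  lig_rows <- list(tibble::tibble(atom = "C1", element = "C",
                                  x = 0, y = 0, z = 0))
  for (u in seq_along(cx$contacts)) {
    ct <- cx$contacts[[u]]
    i <- match(ct$resno, resdef$resno)
    acc <- c(r_polar * cos(theta[i]), r_polar * sin(theta[i]), 0)
    inward <- -acc / sqrt(sum(acc^2))
    D <- acc + inward * ct$dist # donor O at the planted distance
    # place H so the D-H-A angle equals the request: triangle with
    # |DH| = 1.0, |DA| = dist, angle at H = angle
    th <- ct$angle * pi / 180
    sinA <- sin(th) * 1.0 / ct$dist
    angA <- asin(pmin(1, sinA))
    angD <- pi - th - angA
    toA <- -inward # unit vector D -> A
    perp <- c(-toA[2], toA[1], 0)
    hdir <- cos(angD) * toA + sin(angD) * perp
    H <- D + hdir * 1.0
    lig_rows[[length(lig_rows) + 1]] <- tibble::tibble(
      atom = c(sprintf("O%d", u), sprintf("HO%d", u)),
      element = c("O", "H"),
      x = c(D[1], H[1]), y = c(D[2], H[2]), z = c(D[3], H[3])
    )
  }
  pose <- dplyr::bind_rows(lig_rows)

  withr_seed(spec$seed + seed_offset[["complex"]], {
    rec$charge <- round(stats::rnorm(nrow(rec), 0, 0.2), 3)
    pose$charge <- round(stats::rnorm(nrow(pose), 0, 0.2), 3)
    base_xyz <- as.matrix(pose[, c("x", "y", "z")])
    n_main <- max(1L, cx$n_poses - cx$n_outliers)
    poses <- list()
    for (p in seq_len(n_main)) {
      jit <- if (p == 1) 0 else cx$pose_jitter
      poses[[sprintf("pose%02d", p)]] <- base_xyz +
        matrix(stats::runif(length(base_xyz), -jit, jit) / sqrt(3),
               ncol = 3)
    }
    for (o in seq_len(cx$n_outliers)) {
      shift <- c(cx$outlier_shift, 0, 0) * o
      poses[[sprintf("pose%02d", n_main + o)]] <- sweep(base_xyz, 2, shift, `+`)
    }
    pose_affinities <- stats::setNames(
      round(-9 + stats::runif(length(poses)), 2), names(poses))
  })

  list(
    receptor = rec, pose = pose, poses = poses,
    pose_affinities = pose_affinities,
    truth = tibble::tibble(
      contact_resno = as.integer(vapply(cx$contacts, function(ct)
        as.numeric(ct$resno), numeric(1))),
      dist = vapply(cx$contacts, `[[`, numeric(1), "dist"),
      angle = vapply(cx$contacts, `[[`, numeric(1), "angle")
    )
  )
}

# ---- assay data ------------------------------------------------------

#' Generate synthetic plate-reader dose-response tables
#'
#' A potency experiment (4PL with the planted IC50) plus a kinetic
#' series of mechanistic curves across the substrate grid, all via
#' [simulate_dose_response()].
#'
#' @param spec A [generator_spec()].
#' @return List: `potency` (dose-response tibble), `kinetic` (tibble
#'   with an `S_uM` column stacking one dose-response per substrate
#'   concentration), and `truth` (planted parameters).
#' @export
gen_assay_data <- function(spec = generator_spec()) {
  a <- spec$assay
  base_seed <- spec$seed + seed_offset[["assay"]]
  potency <- simulate_dose_response(
    doses = a$doses,
    params = list(bottom = 0, top = 1, ic50 = a$ic50, hill = a$hill),
    replicates = a$replicates, cv = a$cv, seed = base_seed
  )
  model <- inhibition_model(a$mode, Ki = a$Ki, Km = a$Km, alpha = a$alpha)
  kinetic <- purrr::map_dfr(seq_along(a$S_grid), function(si) {
    simulate_dose_response(
      doses = a$doses, params = NULL, model = model, S = a$S_grid[si],
      replicates = a$replicates, cv = a$cv, seed = base_seed + si
    ) |>
      dplyr::mutate(S_uM = a$S_grid[si], .before = 1)
  })
  list(potency = potency, kinetic = kinetic,
       truth = list(ic50 = a$ic50, hill = a$hill, model = model,
                    predicted_ic50 = predicted_ic50(model, a$S_grid)))
}
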