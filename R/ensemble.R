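# Ensemble docking-score aggregation: per-receptor best scores, the
# consensus mean over the receptor ensemble, and top-K selection.

#' The 16-member OGT crystal-structure ensemble
#'
#' PDB identifiers of the human OGT structures (bound to UDP,
#' UDP-GlcNAc or an inhibitor) used as the default receptor ensemble.
#'
#' @return Character vector of 16 PDB ids.
#' @export
ogt_ensemble_ids <- function() {
  c("3PE3", "3PE4", "3TAX", "4AY6", "4CDR", "4GYW", "4GYY", "4GZ3",
    "4N39", "4N3A", "4N3C", "4XI9", "4XIF", "5BNW", "5C1D", "5HGV")
}

#' Parse AutoDock-Vina-style PDBQT output
#'
#' Extracts one score record per `MODEL` block from the
#' `REMARK VINA RESULT:` line (first numeric field, kcal/mol). Pose rank
#' follows file order starting at 1.
#'
#' @param text PDBQT output text (single string or character vector of
#'   lines).
#' @param ligand_id,receptor_id Identifiers to attach.
#' @return Tibble with `ligand_id`, `receptor_id`, `pose_rank`,
#'   `affinity_kcal_mol`.
#' @export
parse_vina_result <- function(text, ligand_id = "ligand", receptor_id = "receptor") {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  model_idx <- grep("^MODEL", lines)
  if (!length(model_idx))
    stop("no MODEL block found in Vina output", call. = FALSE)
  ends <- c(model_idx[-1] - 1L, length(lines))
  aff <- vapply(seq_along(model_idx), function(k) {
    blk <- lines[model_idx[k]:ends[k]]
    rem <- grep("REMARK VINA RESULT:", blk, value = TRUE, fixed = TRUE)
    if (!length(rem))
      stop(sprintf("MODEL %d has no 'REMARK VINA RESULT:' line", k), call. = FALSE)
    flds <- strsplit(trimws(sub(".*REMARK VINA RESULT:", "", rem[1])), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(flds[1]))
    if (is.na(v))
      stop(sprintf("MODEL %d: non-numeric affinity '%s'", k, flds[1]), call. = FALSE)
    v
  }, numeric(1))
  tibble::tibble(
    ligand_id = ligand_id, receptor_id = receptor_id,
    pose_rank = seq_along(aff), affinity_kcal_mol = aff
  )
}

#' Read a long-format docking score table
#'
#' TSV with columns `ligand_id`, `receptor_id`, `pose_rank`,
#' `affinity_kcal_mol`.
#'
#' @param path TSV path.
#' @return Score tibble.
#' @export
read_scores_tsv <- function(path) {
  sc <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("ligand_id", "receptor_id", "pose_rank", "affinity_kcal_mol")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("score table missing columns: ", paste(miss, collapse = ", "))
  sc
}

#' Define a cubic docking search box at a residue side chain
#'
#' The screen's search area is a cube centred on the centroid of the
#' side-chain atoms of a chosen residue (Pro559 next to the UDP pocket
#' in the OGT protocol), default edge 22 Angstroms.
#'
#' @param receptor Structure tibble from [parse_pdb()].
#' @param resno Residue sequence number.
#' @param chain Chain id (default first chain carrying the residue).
#' @param edge Box edge length, Angstroms (default 22).
#' @return List with `center` (xyz) and `edge` (length-3 vector).
#' @export
make_search_box <- function(receptor, resno, chain = NULL, edge = 22) {
  stopifnot(edge > 0)
  res <- dplyr::filter(receptor, .data$resno == !!resno)
  if (!is.null(chain)) res <- dplyr::filter(res, .data$chain == !!chain)
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- dplyr::filter(res, !.data$atom_name %in% backbone)
  if (!nrow(side))
    stop(sprintf("residue %s has no side-chain atoms in the model", resno),
         call. = FALSE)
  list(
    center = c(x = mean(side$x), y = mean(side$y), z = mean(side$z)),
    edge = rep(edge, 3)
  )
}

#' Consensus ranking of ensemble docking scores
#'
#' For each ligand and receptor the best (most negative) pose affinity is
#' taken; the consensus score is the arithmetic mean of these bests over
#' the receptor ensemble, and ligands are ranked ascending by mean
#' (strongest predicted binder first). Ties are broken by ligand id.
#'
#' In `"strict"` mode a ligand missing any ensemble member is excluded
#' with a warning (the protocol docks every ligand against all 16
#' structures); `"available"` mode averages over the receptors present
#' and records how many there were.
#'
#' @param scores Tibble with `ligand_id`, `receptor_id`,
#'   `affinity_kcal_mol` (one row per pose).
#' @param ensemble Character vector of receptor ids (default the ids
#'   present in `scores`).
#' @param mode `"strict"` or `"available"`.
#' @return `consensus_result` tibble: `ligand_id`, `mean_affinity`,
#'   `n_receptors`, `rank`, plus one `best_<receptor>` column per member.
#' @export
consensus_rank <- function(scores, ensemble = NULL,
                           mode = c("strict", "available")) {
  mode <- match.arg(mode)
  if (!nrow(scores)) {
    out <- tibble::tibble(ligand_id = character(0),
                          mean_affinity = numeric(0),
                          n_receptors = integer(0), rank = integer(0))
    class(out) <- c("consensus_result", class(out))
    return(out)
  }
  stopifnot(all(is.finite(scores$affinity_kcal_mol)))
  if (is.null(ensemble)) ensemble <- sort(unique(scores$receptor_id))
  stopifnot(!anyDuplicated(ensemble), length(ensemble) >= 1)

  best <- scores |>
    dplyr::filter(.data$receptor_id %in% ensemble) |>
    dplyr::summarise(
      best = min(.data$affinity_kcal_mol),
      .by = c("ligand_id", "receptor_id")
    )
  agg <- best |>
    dplyr::summarise(
      mean_affinity = mean(.data$best),
      n_receptors = dplyr::n(),
      .by = "ligand_id"
    )
  if (mode == "strict") {
    incomplete <- agg$ligand_id[agg$n_receptors < length(ensemble)]
    if (length(incomplete)) {
      warning(sprintf(
        "excluding %d ligand(s) without scores on all %d receptors: %s",
        length(incomplete), length(ensemble),
        paste(utils::head(incomplete, 5), collapse = ", ")
      ), call. = FALSE)
      agg <- dplyr::filter(agg, !.data$ligand_id %in% incomplete)
      best <- dplyr::filter(best, !.data$ligand_id %in% incomplete)
    }
  }
  wide <- best |>
    dplyr::mutate(receptor_id = paste0("best_", .data$receptor_id)) |>
    tidyr::pivot_wider(names_from = "receptor_id", values_from = "best")
  out <- agg |>
    dplyr::left_join(wide, by = "ligand_id") |>
    dplyr::arrange(.data$mean_affinity, .data$ligand_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("ligand_id", "mean_affinity", "n_receptors", "rank")
  class(out) <- c("consensus_result", class(out))
  out
}

#' Select the top-K consensus ligands
#'
#' The protocol carries the 200 best-ranked compounds forward; `k`
#' larger than the table is clamped.
#'
#' @param ranked A [consensus_rank()] table.
#' @param k Number of ligands to keep (default 200).
#' @return The first `min(k, n)` rows.
#' @export
select_top_k <- function(ranked, k = 200) {
  stopifnot(k >= 0)
  utils::head(ranked, k)
}

#' Enrichment factor of a ranked list
#'
#' EF(k) = (actives in top k / k) / (total actives / n); 1 means no
#' enrichment over random ordering.
#'
#' @param ranked A [consensus_rank()] table.
#' @param active_ids Ligand ids of the known/planted actives.
#' @param k Depth of the ranked list to score.
#' @return Enrichment factor (numeric scalar).
#' @export
enrichment_factor <- function(ranked, active_ids, k) {
  n <- nrow(ranked)
  stopifnot(k > 0, k <= n)
  n_act <- sum(ranked$ligand_id %in% active_ids)
  if (n_act == 0) stop("no actives present in the ranked list", call. = FALSE)
  hits <- sum(utils::head(ranked$ligand_id, k) %in% active_ids)
  (hits / k) / (n_act / n)
}

#' Write a consensus table as TSV
#'
#' @param ranked A [consensus_rank()] table.
#' @param path Output path.
#' @export
write_consensus <- function(ranked, path) {
  readr::write_tsv(ranked, path)
  invisible(path)
}
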