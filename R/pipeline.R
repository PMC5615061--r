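# End-to-end orchestration of the screening cascade:
# library -> property filter -> ensemble consensus ranking -> top-K ->
# pose clustering + key-residue triage, with materialized intermediates
# and a consolidated report.

#' Configuration for a screening run
#'
#' @param library List of `mol_graph`s, or path to a SMILES/SDF file.
#' @param scores Score tibble (`ligand_id`, `receptor_id`, `pose_rank`,
#'   `affinity_kcal_mol`) or path to such a TSV.
#' @param rules A [filter_rules()] object.
#' @param ensemble Receptor ids (default: those present in the scores).
#' @param mode Consensus coverage mode, `"strict"` or `"available"`.
#' @param top_k Compounds carried past the consensus ranking
#'   (default 200).
#' @param cluster_threshold Pose-cluster radius, Angstroms.
#' @param triage A [triage_rule()] object.
#' @param poses Optional named list (by ligand id) of pose sets; each
#'   entry a list with `poses` (named coordinate matrices),
#'   `affinities`, `pose` (atom tibble of the ligand) and `receptor`
#'   (atom tibble). Ligands without poses are not triaged.
#' @param criteria An [hbond_criteria()] object.
#' @param out_dir Directory for intermediate TSVs.
#' @param seed Integer seed recorded in the provenance block.
#' @return A `screen_config` list.
#' @export
screen_config <- function(library, scores, rules = filter_rules(),
                          ensemble = NULL, mode = "strict", top_k = 200,
                          cluster_threshold = 2, triage = triage_rule(),
                          poses = NULL, criteria = hbond_criteria(),
                          out_dir = tempfile("screen"), seed = 1) {
  stopifnot(top_k >= 1)
  if (is.character(library) && !file.exists(library))
    stop("library path does not exist: ", library, call. = FALSE)
  if (is.character(scores) && !file.exists(scores))
    stop("scores path does not exist: ", scores, call. = FALSE)
  structure(
    list(library = library, scores = scores, rules = rules,
         ensemble = ensemble, mode = mode, top_k = top_k,
         cluster_threshold = cluster_threshold, triage = triage,
         poses = poses, criteria = criteria, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Run the screening cascade
#'
#' Stages run in order — filter, consensus rank, top-K selection,
#' pose clustering and key-residue triage — each materialized as a TSV
#' under `config$out_dir` for auditability. Stage counts are
#' non-increasing along the cascade and the run is deterministic for a
#' fixed configuration.
#'
#' @param config A [screen_config()].
#' @return A `screen_report`: `counts` (stage, n), `final` (per-ligand
#'   table over the top-K), `files` (intermediate paths) and
#'   `provenance` (config hash, package version, timestamp).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  mols <- stage("library", {
    if (is.character(config$library)) read_library(config$library)
    else config$library
  })
  n_in <- length(mols)

  filt <- stage("filter", {
    if (n_in) filter_library(mols, config$rules)
    else tibble::tibble(id = character(0), pass_overall = logical(0))
  })
  if (n_in) write_filter_report(filt, file.path(config$out_dir, "filter.tsv"))
  passing <- filt$id[filt$pass_overall]

  scores <- stage("scores", {
    sc <- if (is.character(config$scores)) read_scores_tsv(config$scores)
      else config$scores
    if (!"ligand_id" %in% names(sc))
      stop("score table lacks a ligand_id column")
    dplyr::filter(sc, .data$ligand_id %in% passing)
  })

  ranked <- stage("consensus", {
    consensus_rank(scores, ensemble = config$ensemble, mode = config$mode)
  })
  write_consensus(ranked, file.path(config$out_dir, "consensus.tsv"))

  k_clamped <- config$top_k > nrow(ranked)
  top <- stage("top_k", select_top_k(ranked, config$top_k))
  readr::write_tsv(top, file.path(config$out_dir, "topk.tsv"))

  triage_rows <- list()
  for (lid in top$ligand_id) {
    ps <- config$poses[[lid]]
    if (is.null(ps)) next
    cl <- stage("cluster", {
      cluster_poses(ps$poses, threshold = config$cluster_threshold,
                    affinities = ps$affinities)
    })
    rep_id <- cl$representative
    rep_xyz <- ps$poses[[rep_id]]
    pose_tbl <- ps$pose
    pose_tbl$x <- rep_xyz[, 1]; pose_tbl$y <- rep_xyz[, 2]
    pose_tbl$z <- rep_xyz[, 3]
    tri <- stage("triage", {
      fp <- contact_fingerprint(pose_tbl, ps$receptor, config$criteria,
                                ligand_id = lid, pose_id = rep_id)
      triage_key_residues(fp, config$triage)
    })
    triage_rows[[lid]] <- tibble::tibble(
      ligand_id = lid, representative_pose = rep_id,
      biggest_cluster_size = max(cl$assignments$cluster_size),
      triage_pass = tri$pass,
      matched_residues = paste(tri$matched, collapse = ",")
    )
  }
  triage_tbl <- if (length(triage_rows)) dplyr::bind_rows(triage_rows)
    else tibble::tibble(ligand_id = character(0),
                        representative_pose = character(0),
                        biggest_cluster_size = integer(0),
                        triage_pass = logical(0),
                        matched_residues = character(0))
  readr::write_tsv(triage_tbl, file.path(config$out_dir, "triage.tsv"))

  final <- top |>
    dplyr::select("ligand_id", "mean_affinity", "n_receptors", "rank") |>
    dplyr::left_join(triage_tbl, by = "ligand_id") |>
    dplyr::mutate(triage_pass = !is.na(.data$triage_pass) & .data$triage_pass)
  readr::write_tsv(final, file.path(config$out_dir, "final.tsv"))

  counts <- tibble::tibble(
    stage = c("library_in", "filter_pass", "ranked", "top_k", "triage_pass"),
    n = c(n_in, length(passing), nrow(ranked), nrow(top),
          sum(final$triage_pass))
  )
  structure(
    list(
      counts = counts, final = final,
      top_k_clamped = k_clamped,
      files = file.path(config$out_dir,
                        c("filter.tsv", "consensus.tsv", "topk.tsv",
                          "triage.tsv", "final.tsv")),
      provenance = list(
        config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("ogtscreen")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (k in seq_len(nrow(x$counts)))
    cat(sprintf("  %-12s %d\n", x$counts$stage[k], x$counts$n[k]))
  if (x$top_k_clamped) cat("  (top-K clamped to the ranked count)\n")
  cat(sprintf("  config hash %s\n", x$provenance$config_hash))
  invisible(x)
}
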