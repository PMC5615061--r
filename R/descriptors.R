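# The four screened physicochemical descriptors and the filter cascade.

#' Filter rules for the lead-like cascade
#'
#' The default thresholds are the four library rules used for the OGT
#' natural-product screen: 250 <= MW <= 600 Da, neutral and
#' non-zwitterionic, 2-4 ring systems, >= 1 hydrogen-bond acceptor and
#' >= 2 donors.
#'
#' @param mw_min,mw_max Molecular-weight window, Da.
#' @param require_neutral_non_zwitterion Require net charge 0 and no
#'   mixed-sign formal charges.
#' @param ring_systems_min,ring_systems_max Ring-system count window.
#' @param hba_min Minimum hydrogen-bond acceptors.
#' @param hbd_min Minimum hydrogen-bond donors.
#' @return A `filter_rules` list.
#' @export
filter_rules <- function(mw_min = 250, mw_max = 600,
                         require_neutral_non_zwitterion = TRUE,
                         ring_systems_min = 2, ring_systems_max = 4,
                         hba_min = 1, hbd_min = 2) {
  stopifnot(mw_min < mw_max, ring_systems_min >= 0,
            ring_systems_max >= ring_systems_min, hba_min >= 0, hbd_min >= 0)
  structure(
    list(mw_min = mw_min, mw_max = mw_max,
         require_neutral_non_zwitterion = require_neutral_non_zwitterion,
         ring_systems_min = ring_systems_min,
         ring_systems_max = ring_systems_max,
         hba_min = hba_min, hbd_min = hbd_min),
    class = "filter_rules"
  )
}

#' Molecular weight from average atomic masses
#'
#' Sum of conventional atomic masses over all heavy atoms plus implicit
#' and explicit hydrogens.
#'
#' @param g A `mol_graph`.
#' @return Weight in Da.
#' @export
molecular_weight <- function(g) {
  el <- g$atoms$element
  missing_el <- setdiff(el, names(ATOMIC_MASS))
  if (length(missing_el))
    stop("no atomic mass for element: ", paste(missing_el, collapse = ", "))
  sum(ATOMIC_MASS[el]) + sum(g$atoms$implicit_h) * ATOMIC_MASS[["H"]]
}

#' Count ring systems
#'
#' A ring bond is a bond lying on at least one cycle (a non-bridge edge);
#' a ring system is a connected component of the subgraph induced by ring
#' bonds, so fused and spiro rings sharing at least one atom count as one
#' system and an acyclic molecule has zero.
#'
#' @param g A `mol_graph`.
#' @return Integer count.
#' @export
count_ring_systems <- function(g) {
  if (!nrow(g$bonds)) return(0L)
  gr <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j), directed = FALSE)
  br <- igraph::bridges(gr)
  ring_edges <- setdiff(seq_len(igraph::ecount(gr)), as.integer(br))
  if (!length(ring_edges)) return(0L)
  sub <- igraph::subgraph_from_edges(gr, ring_edges, delete.vertices = TRUE)
  as.integer(igraph::components(sub)$no)
}

#' Count hydrogen-bond donors and acceptors
#'
#' Lipinski-style convention: donors are N/O atoms bearing at least one
#' hydrogen (each heteroatom counted once, however many H it carries);
#' acceptors are all N and O atoms. Pyrrole-type aromatic nitrogens can
#' optionally be excluded from the acceptor count.
#'
#' @param g A `mol_graph`.
#' @param exclude_pyrrole_n Drop aromatic N-H nitrogens from the acceptor
#'   count (default `FALSE`).
#' @return Named list with `hbd` and `hba` counts.
#' @export
count_hb_donors_acceptors <- function(g, exclude_pyrrole_n = FALSE) {
  at <- g$atoms
  n_h_neighbors <- integer(nrow(at))
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      if (at$element[j] == "H") n_h_neighbors[i] <- n_h_neighbors[i] + 1L
      if (at$element[i] == "H") n_h_neighbors[j] <- n_h_neighbors[j] + 1L
    }
  }
  h_total <- at$implicit_h + n_h_neighbors
  polar <- at$element %in% c("N", "O")
  hbd <- sum(polar & h_total >= 1)
  acc <- polar
  if (exclude_pyrrole_n)
    acc <- acc & !(at$element == "N" & at$aromatic & h_total >= 1)
  list(hbd = as.integer(hbd), hba = as.integer(sum(acc)))
}

#' Classify ionization state
#'
#' Formal charges are taken as drawn; no protonation model is applied.
#' A zwitterion carries at least one positively and one negatively
#' charged atom simultaneously, whatever the net charge.
#'
#' @param g A `mol_graph`.
#' @return Named list with `net_charge` and `is_zwitterion`.
#' @export
classify_ionization <- function(g) {
  ch <- g$atoms$charge
  list(net_charge = as.integer(sum(ch)),
       is_zwitterion = any(ch > 0) && any(ch < 0))
}

#' Apply the four-rule filter cascade to one molecule
#'
#' All four descriptors are computed and every rule flag is evaluated
#' independently (no short-circuiting), so a failing molecule reports
#' every rule it violates.
#'
#' @param g A `mol_graph`.
#' @param rules A [filter_rules()] object.
#' @return One-row tibble: descriptors, the four `pass_*` flags, and
#'   `pass_overall` (their conjunction).
#' @export
apply_filter_cascade <- function(g, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  mw <- molecular_weight(g)
  ion <- classify_ionization(g)
  nring <- count_ring_systems(g)
  hb <- count_hb_donors_acceptors(g)
  pass_mw <- mw >= rules$mw_min & mw <= rules$mw_max
  pass_charge <- if (rules$require_neutral_non_zwitterion)
    ion$net_charge == 0L && !ion$is_zwitterion else TRUE
  pass_rings <- nring >= rules$ring_systems_min & nring <= rules$ring_systems_max
  pass_hbonds <- hb$hba >= rules$hba_min & hb$hbd >= rules$hbd_min
  tibble::tibble(
    id = g$id, mw = mw, net_charge = ion$net_charge,
    is_zwitterion = ion$is_zwitterion, n_ring_systems = nring,
    hba = hb$hba, hbd = hb$hbd,
    pass_mw = pass_mw, pass_charge = pass_charge,
    pass_rings = pass_rings, pass_hbonds = pass_hbonds,
    pass_overall = pass_mw && pass_charge && pass_rings && pass_hbonds
  )
}

#' Filter a compound library
#'
#' Runs [apply_filter_cascade()] over a list of molecules and returns the
#' per-molecule property/flag table.
#'
#' @param mols List of `mol_graph`s (e.g. from [read_library()] or
#'   [gen_library()]).
#' @param rules A [filter_rules()] object.
#' @return Tibble with one row per molecule (see
#'   [apply_filter_cascade()]).
#' @export
filter_library <- function(mols, rules = filter_rules()) {
  purrr::map_dfr(mols, apply_filter_cascade, rules = rules)
}

#' Write a filter report as TSV
#'
#' @param report Tibble from [filter_library()].
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
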