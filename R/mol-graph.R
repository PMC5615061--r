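# Molecular graphs: a light container for one library compound.
# Atoms and bonds are tibbles so every downstream descriptor is a
# data-frame computation.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# Default valences, lowest first; implicit hydrogens use the smallest
# valence that accommodates the drawn bonds.
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

# Conventional (average) atomic masses, Da.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845,
  Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.904
)

new_mol_graph <- function(id, atoms, bonds, source) {
  stopifnot(nrow(atoms) >= 1)
  if (nrow(bonds)) {
    stopifnot(
      all(bonds$i >= 1), all(bonds$j >= 1),
      all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)),
      all(bonds$i != bonds$j)
    )
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }
  stopifnot(all(atoms$implicit_h >= 0))
  structure(
    list(id = id, atoms = atoms, bonds = bonds, source = source),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %s: %d atoms, %d bonds (%s)\n",
    x$id, nrow(x$atoms), nrow(x$bonds), x$source
  ))
  invisible(x)
}

#' Parse a molecule from SMILES or an SDF block
#'
#' Dispatches on content: text containing a V2000 counts line (or an
#' `M  END` record) is read as an SDF/molfile block, anything else as a
#' single SMILES string with an optional whitespace-separated identifier.
#'
#' @param text A single SMILES line or one SDF (V2000 molfile) block.
#' @param id Identifier to assign; defaults to the id carried in the text
#'   (SMILES second field or molfile title line) or `"mol"`.
#' @return A `mol_graph`: a list with `id`, an `atoms` tibble (`element`,
#'   `aromatic`, `charge`, `implicit_h`, `explicit`), a `bonds` tibble
#'   (`i`, `j`, `order` with `"a"` for aromatic) and `source`.
#' @examples
#' parse_molecule("c1ccccc1 benzene")
#' parse_molecule("CCO ethanol")
#' @export
parse_molecule <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1, nzchar(trimws(text)))
  if (grepl("V2000", text, fixed = TRUE) || grepl("M  END", text, fixed = TRUE)) {
    parse_sdf_block(text, id = id)
  } else {
    parse_smiles(text, id = id)
  }
}

smiles_error <- function(msg, pos) {
  stop(sprintf("SMILES parse error at position %d: %s", pos, msg), call. = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic
#' lowercase atoms, bracket atoms with explicit H counts and formal
#' charges, branches, ring closures (single digit and `%nn`), bond
#' symbols `- = # :` and dot-separated fragments. Stereo markers
#' (`/ \ @`) are accepted and ignored. Implicit hydrogens follow the
#' standard valence model (lowest valence accommodating the drawn bonds;
#' aromatic atoms reserve one valence unit for the ring system). Aromatic
#' flags are trusted as drawn; no aromaticity perception is applied.
#'
#' @param smiles A single SMILES string, optionally followed by
#'   whitespace and an identifier.
#' @param id Identifier override.
#' @return A `mol_graph`.
#' @export
parse_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  line <- trimws(smiles)
  if (!nzchar(line)) stop("empty SMILES input", call. = FALSE)
  parts <- strsplit(line, "\\s+")[[1]]
  smi <- parts[[1]]
  if (is.null(id)) id <- if (length(parts) > 1) parts[[2]] else "mol"

  chars <- strsplit(smi, "")[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  imph <- integer(0); exph <- logical(0) # exph: bracket atom with explicit H spec
  bi <- integer(0); bj <- integer(0); bo <- character(0)

  add_bond <- function(a, b, order) {
    bi <<- c(bi, a); bj <<- c(bj, b); bo <<- c(bo, order)
  }

  prev_stack <- integer(0) # branch stack
  prev <- NA_integer_
  pending_bond <- NULL
  ring_open <- list() # digit -> list(atom, bond, pos)
  pos <- 1

  add_atom <- function(element, aromatic, charge, hcount, explicit_h) {
    el <<- c(el, element); arom <<- c(arom, aromatic)
    chg <<- c(chg, as.integer(charge)); imph <<- c(imph, as.integer(hcount))
    exph <<- c(exph, explicit_h)
    idx <- length(el)
    if (!is.na(prev)) {
      order <- if (!is.null(pending_bond)) pending_bond
        else if (aromatic && arom[prev]) "a" else "1"
      add_bond(prev, idx, order)
    }
    pending_bond <<- NULL
    prev <<- idx
    idx
  }

  close_ring <- function(key, p) {
    if (is.na(prev)) smiles_error("ring closure before any atom", p)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      order <- pending_bond
      if (is.null(order)) order <- op$bond
      if (is.null(order)) {
        order <- if (arom[prev] && arom[op$atom]) "a" else "1"
      }
      add_bond(op$atom, prev, order)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond, pos = p)
    }
    pending_bond <<- NULL
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "a",
                             "/" = "1", "\\" = "1")
      pos <- pos + 1
    } else if (ch == "(") {
      if (is.na(prev)) smiles_error("branch open before any atom", pos)
      prev_stack <- c(prev_stack, prev)
      pos <- pos + 1
    } else if (ch == ")") {
      if (!length(prev_stack)) smiles_error("unmatched ')'", pos)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      pos <- pos + 1
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
      pos <- pos + 1
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, pos)
      pos <- pos + 1
    } else if (ch == "%") {
      if (pos + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[pos + 1], chars[pos + 2])))
        smiles_error("malformed %nn ring closure", pos)
      close_ring(paste0(chars[pos + 1], chars[pos + 2]), pos)
      pos <- pos + 3
    } else if (ch == "[") {
      close_pos <- pos
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1
      if (close_pos > n) smiles_error("unclosed bracket atom", pos)
      body <- paste0(chars[(pos + 1):(close_pos - 1)], collapse = "")
      at <- parse_bracket_atom(body, pos)
      add_atom(at$element, at$aromatic, at$charge, at$hcount, TRUE)
      pos <- close_pos + 1
    } else {
      # organic-subset atom, possibly two letters (Cl, Br)
      two <- if (pos < n) paste0(ch, chars[pos + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, FALSE)
        pos <- pos + 2
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE, 0L, NA_integer_, FALSE)
        pos <- pos + 1
      } else if (ch %in% AROMATIC_SUBSET) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
        pos <- pos + 1
      } else {
        smiles_error(sprintf("unknown element or token '%s'", ch), pos)
      }
    }
  }
  if (length(prev_stack)) smiles_error("unclosed branch '('", n)
  open_digits <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_digits)) {
    op <- ring_open[[open_digits[[1]]]]
    smiles_error(
      sprintf("ring closure '%s' opened but never closed", open_digits[[1]]),
      op$pos
    )
  }
  if (!length(el)) stop("SMILES contains no atoms", call. = FALSE)

  atoms <- tibble::tibble(
    element = el, aromatic = arom, charge = chg,
    implicit_h = imph, explicit = exph
  )
  bonds <- tibble::tibble(i = bi, j = bj, order = bo)
  atoms$implicit_h <- assign_implicit_h(atoms, bonds)
  out <- new_mol_graph(id, atoms, bonds, source = "SMILES")
  attr(out, "smiles") <- smi
  out
}

parse_bracket_atom <- function(body, pos) {
  m <- regmatches(
    body,
    regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$", body)
  )[[1]]
  if (!length(m)) smiles_error(sprintf("malformed bracket atom '[%s]'", body), pos)
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_SUBSET
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% names(ATOMIC_MASS) && element != "H")
    smiles_error(sprintf("unknown element '%s'", sym), pos)
  hspec <- m[5]
  hcount <- if (!nzchar(hspec)) 0L
    else if (hspec == "H") 1L else as.integer(sub("^H", "", hspec))
  cspec <- m[6]
  charge <- 0L
  if (nzchar(cspec)) {
    if (grepl("^[+-][0-9]+$", cspec)) {
      charge <- as.integer(cspec)
    } else if (grepl("^\\++$", cspec)) {
      charge <- nchar(cspec)
    } else if (grepl("^-+$", cspec)) {
      charge <- -nchar(cspec)
    } else smiles_error(sprintf("malformed charge '%s'", cspec), pos)
  }
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount)
}

# Implicit hydrogens by the standard valence model. Bracket atoms keep
# their explicit count; organic-subset atoms get (valence - bond order
# sum), aromatic atoms reserve one unit for the delocalized system and
# use only their lowest valence.
assign_implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  osum <- numeric(n)
  if (nrow(bonds)) {
    val <- as.numeric(replace(bonds$order, bonds$order == "a", "1"))
    for (k in seq_len(nrow(bonds))) {
      osum[bonds$i[k]] <- osum[bonds$i[k]] + val[k]
      osum[bonds$j[k]] <- osum[bonds$j[k]] + val[k]
    }
  }
  out <- atoms$implicit_h
  for (a in seq_len(n)) {
    if (!is.na(out[a])) next # bracket atom: explicit spec
    vals <- DEFAULT_VALENCE[[atoms$element[a]]]
    if (is.null(vals)) { out[a] <- 0L; next }
    used <- osum[a] + if (atoms$aromatic[a]) 1 else 0
    if (atoms$aromatic[a]) {
      out[a] <- as.integer(max(0, vals[1] - used))
    } else {
      fit <- vals[vals >= used]
      out[a] <- if (length(fit)) as.integer(fit[1] - used) else 0L
    }
  }
  out
}

parse_sdf_block <- function(text, id = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts_idx <- grep("V2000", lines, fixed = TRUE)[1]
  if (is.na(counts_idx)) stop("SDF block has no V2000 counts line", call. = FALSE)
  counts <- lines[counts_idx]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1) stop("SDF counts line malformed", call. = FALSE)
  if (is.null(id)) {
    title <- if (counts_idx >= 4) trimws(lines[counts_idx - 3]) else ""
    id <- if (nzchar(title)) title else "mol"
  }
  atom_lines <- lines[(counts_idx + 1):(counts_idx + natoms)]
  el <- trimws(substr(atom_lines, 32, 34))
  bad <- which(!el %in% names(ATOMIC_MASS))
  if (length(bad))
    stop(sprintf("SDF atom %d: unknown element '%s'", bad[1], el[bad[1]]),
         call. = FALSE)
  bi <- integer(0); bj <- integer(0); bo <- character(0)
  if (nbonds > 0) {
    bond_lines <- lines[(counts_idx + natoms + 1):(counts_idx + natoms + nbonds)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    otype <- as.integer(substr(bond_lines, 7, 9))
    bo <- ifelse(otype == 4L, "a", as.character(otype))
  }
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- flds[1]
    for (p in seq_len(k)) charge[flds[2 * p]] <- flds[2 * p + 1]
  }
  aromatic <- rep(FALSE, natoms)
  if (length(bo)) {
    ar <- bo == "a"
    aromatic[unique(c(bi[ar], bj[ar]))] <- TRUE
  }
  atoms <- tibble::tibble(
    element = el, aromatic = aromatic, charge = charge,
    implicit_h = NA_integer_, explicit = el == "H"
  )
  bonds <- tibble::tibble(i = bi, j = bj, order = bo)
  atoms$implicit_h <- assign_implicit_h_sdf(atoms, bonds)
  new_mol_graph(id, atoms, bonds, source = "SDF")
}

# SDF carries no per-atom H spec; valence is charge-adjusted
# (e.g. [O-] -> 1, [N+] -> 4) and explicit H atoms in the block count
# toward the bond-order sum.
assign_implicit_h_sdf <- function(atoms, bonds) {
  n <- nrow(atoms)
  osum <- numeric(n)
  if (nrow(bonds)) {
    val <- as.numeric(replace(bonds$order, bonds$order == "a", "1"))
    for (k in seq_len(nrow(bonds))) {
      osum[bonds$i[k]] <- osum[bonds$i[k]] + val[k]
      osum[bonds$j[k]] <- osum[bonds$j[k]] + val[k]
    }
  }
  out <- integer(n)
  for (a in seq_len(n)) {
    if (atoms$element[a] == "H") { out[a] <- 0L; next }
    vals <- DEFAULT_VALENCE[[atoms$element[a]]]
    if (is.null(vals)) { out[a] <- 0L; next }
    vals <- vals + atoms$charge[a]
    vals <- vals[vals >= 0]
    used <- osum[a] + if (atoms$aromatic[a]) 1 else 0
    if (atoms$aromatic[a]) {
      out[a] <- as.integer(max(0, vals[1] - used))
    } else {
      fit <- vals[vals >= used]
      out[a] <- if (length(fit)) as.integer(fit[1] - used) else 0L
    }
  }
  out
}

#' Read a compound library
#'
#' Reads either a SMILES file (one molecule per line, optional
#' whitespace-separated identifier, `#` comments skipped) or a multi-record
#' SDF (records separated by `$$$$`). Molecules that fail to parse are
#' dropped with a warning naming them, not fatal to the run.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @return A list of `mol_graph` objects.
#' @export
read_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  txt <- readLines(path, warn = FALSE)
  if (format == "smiles") {
    lines <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
    blocks <- as.list(lines)
    parser <- parse_smiles
  } else {
    recs <- split(txt, cumsum(c(0, head(txt, -1) == "$$$$")))
    blocks <- lapply(recs, paste, collapse = "\n")
    blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b), logical(1))]
    parser <- parse_sdf_block
  }
  mols <- vector("list", length(blocks))
  keep <- logical(length(blocks))
  for (k in seq_along(blocks)) {
    m <- tryCatch(parser(blocks[[k]]), error = function(e) e)
    if (inherits(m, "error")) {
      warning(sprintf("skipping unparsable molecule %d: %s",
                      k, conditionMessage(m)), call. = FALSE)
    } else {
      mols[[k]] <- m
      keep[k] <- TRUE
    }
  }
  mols[keep]
}

#' Write molecules as an SDF (V2000) file
#'
#' Connection-table export: atoms (with zero coordinates — the graphs
#' carry no geometry), bonds (aromatic as type 4) and `M  CHG` records,
#' one `$$$$`-terminated block per molecule.
#'
#' @param mols List of `mol_graph`s.
#' @param path Output path.
#' @export
write_sdf <- function(mols, path) {
  blocks <- lapply(mols, function(m) {
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    lines <- c(
      m$id, "  ogtscreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0, m$atoms$element),
      if (nb) sprintf("%3d%3d%3d  0", m$bonds$i, m$bonds$j,
                      ifelse(m$bonds$order == "a", 4L,
                             as.integer(sub("a", "4", m$bonds$order))))
    )
    chg <- which(m$atoms$charge != 0)
    if (length(chg)) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(chg)),
        paste(sprintf("%4d%4d", chg, m$atoms$charge[chg]), collapse = "")))
    }
    c(lines, "M  END", "$$$$")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Write molecules as a SMILES file
#'
#' One `<smiles> <id>` line per molecule. Only graphs that carry a
#' `smiles` attribute (all generator output does) or were parsed from
#' SMILES can be written.
#'
#' @param mols List of `mol_graph`s.
#' @param path Output path.
#' @export
write_smiles <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    smi <- attr(m, "smiles")
    if (is.null(smi)) stop("molecule ", m$id, " has no SMILES string attached")
    paste(smi, m$id)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
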