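# Molecular graph layer on top of ChemmineR / Open Babel.
#
# Molecules are held as plain atom/bond tables (the V2000 blocks ChemmineR
# exposes) so that the two reaction transforms can be written as explicit
# graph edits; Open Babel does all SMILES parsing, aromaticity perception
# and canonicalization.

# V2000 atom-line charge field <-> formal charge
.CHG_FROM_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
.CODE_FROM_CHG <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the Open Babel canonical form used throughout the
#' package. All structure-equality comparisons go through this function;
#' raw SMILES strings are never compared directly.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length and order.
#' @examples
#' canonical_smiles(c("OCC", "C(C)O"))  # both ethanol
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(is.na(smiles) | !nzchar(smiles)))
    stop("empty or NA SMILES cannot be canonicalized")
  # batch through one conversion; titles carry the positions back
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src),
    error = function(e) stop("SMILES parse error: ", conditionMessage(e), call. = FALSE)
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(smiles))
  for (p in parts) {
    idx <- as.integer(sub("^m", "", trimws(p[2])))
    res[idx] <- trimws(p[1])
  }
  if (anyNA(res)) {
    bad <- which(is.na(res))
    stop("SMILES parse error for input(s): ", paste(smiles[bad], collapse = ", "),
         call. = FALSE)
  }
  res
}

# Parse one SMILES into an atom/bond table molecule.
mol_from_smiles <- function(smiles, name = "mol") {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  blocks <- tryCatch({
    set <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, name)))
    if (length(set) != 1L || !ChemmineR::validSDF(set))
      stop("structure did not parse to a valid molecule")
    list(ab = ChemmineR::atomblock(set[[1]]), bb = ChemmineR::bondblock(set[[1]]))
  }, error = function(e) stop("SMILES parse error for '", smiles, "': ",
                              conditionMessage(e), call. = FALSE))
  ab <- blocks$ab
  bb <- blocks$bb
  if (nrow(ab) == 0L) stop("SMILES parse error for '", smiles, "'", call. = FALSE)
  elem <- sub("_\\d+$", "", rownames(ab))
  code <- as.character(ab[, 5L])
  charge <- unname(.CHG_FROM_CODE[code])
  charge[is.na(charge)] <- 0L
  bonds <- if (nrow(bb) > 0L) {
    data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  structure(list(elem = elem, charge = as.integer(charge), bonds = bonds,
                 name = name), class = "clickmol")
}

n_heavy_atoms <- function(mol) length(mol$elem)

# heavy-atom degree of every atom
.mol_degree <- function(mol) {
  deg <- integer(length(mol$elem))
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds$a1, nbins = length(deg))
    t2 <- tabulate(mol$bonds$a2, nbins = length(deg))
    deg <- t1 + t2
  }
  deg
}

.mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

.bond_row <- function(mol, i, j) {
  b <- mol$bonds
  which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
}

.bond_order_between <- function(mol, i, j) {
  r <- .bond_row(mol, i, j)
  if (length(r) == 0L) 0L else mol$bonds$order[r[1L]]
}

# Serialize molecules back through Open Babel for canonical SMILES.
# Accepts a list of clickmol objects; returns canonical SMILES per molecule.
mols_to_smiles <- function(mols) {
  stopifnot(length(mols) >= 1L)
  sdfs <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    na <- length(m$elem); nb <- nrow(m$bonds)
    ab <- matrix(0, nrow = na, ncol = 15L)
    ab[, 5L] <- unname(.CODE_FROM_CHG[as.character(m$charge)])
    rownames(ab) <- paste(m$elem, seq_len(na), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    bb <- matrix(0L, nrow = nb, ncol = 7L)
    if (nb > 0L) {
      bb[, 1L] <- m$bonds$a1; bb[, 2L] <- m$bonds$a2; bb[, 3L] <- m$bonds$order
    }
    rownames(bb) <- as.character(seq_len(max(nb, 0L)))
    colnames(bb) <- paste0("C", 1:7)
    hdr <- c(Molecule_Name = sprintf("m%d", k), Source = "clickscreen",
             Comment = "", Counts_Line = sprintf(
               "%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    sdfs[[k]] <- methods::new("SDF", header = hdr, atomblock = ab,
                              bondblock = bb, datablock = character(0))
  }
  set <- methods::new("SDFset", SDF = sdfs, ID = sprintf("m%d", seq_along(mols)))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  suppressWarnings(ChemmineR::write.SDF(set, file = tf))
  txt <- readLines(tf)
  # the molfile text is regenerated with elastic columns, which can shift
  # the legacy atom-line charge field out of place; explicit M CHG lines
  # take precedence and are immune to that, so add one per charged molecule
  ends <- which(txt == "M  END")
  stopifnot(length(ends) == length(mols))
  extra <- lapply(seq_along(mols), function(k) {
    chg <- mols[[k]]$charge
    idx <- which(chg != 0L)
    if (length(idx) == 0L) return(character(0))
    vapply(split(seq_along(idx), ceiling(seq_along(idx) / 8)), function(grp) {
      paste0("M  CHG", sprintf("%3d", length(grp)),
             paste0(sprintf("%4d%4d", idx[grp], chg[idx[grp]]), collapse = ""))
    }, character(1))
  })
  pieces <- character(0); prev <- 1L
  for (k in seq_along(ends)) {
    pieces <- c(pieces, txt[prev:(ends[k] - 1L)], extra[[k]], txt[ends[k]])
    prev <- ends[k] + 1L
  }
  if (prev <= length(txt)) pieces <- c(pieces, txt[prev:length(txt)])
  out <- ChemmineOB::convertFormat("SDF", "CAN",
                                   source = paste(pieces, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- rep(NA_character_, length(mols))
  for (p in parts) {
    idx <- as.integer(sub("^m", "", trimws(p[2])))
    res[idx] <- trimws(p[1])
  }
  res
}

mol_to_smiles <- function(mol) mols_to_smiles(list(mol))[[1L]]

# SMARTS definitions for the reactive groups handled by the cascade.
# Azides may parse charge-separated or hypervalent, so two patterns are summed.
.SMARTS <- list(
  azide            = c("[#6][NX2]=[NX2+]=[NX1-]", "[#6][NX2]=[NX2]#[NX1]"),
  terminal_alkyne  = "[CX2]#[CX2;H1]",
  carboxylic_acid  = "[CX3](=O)[OX2;H1]",
  primary_sulfonamide = "[#6]S(=O)(=O)[NX3;H2]",
  nacyl_sulfonamide   = "S(=O)(=O)[NX3;H1][CX3]=O",
  triazole_ring       = "c1cnnn1",
  triazole_14disub    = "[#6]c1cn([#6])nn1"
)

#' Count reactive and product groups by substructure matching
#'
#' Counts, for each input structure, the functional groups that drive or
#' terminate the two-step cascade: carbon-bound azide, terminal alkyne,
#' carboxylic acid, primary sulfonamide, N-acyl sulfonamide, aromatic
#' 1,2,3-triazole ring, and 1,4-disubstituted triazole.
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per input, one column per group.
#' @export
count_groups <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  src <- paste0(smiles, " m", seq_along(smiles), collapse = "\n")
  obmols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(src, "\n"), identity, c),
    error = function(e) stop("SMILES parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.list(obmols)) obmols <- list(obmols)
  if (length(obmols) != length(smiles))
    stop("SMILES parse error: ", length(smiles) - length(obmols),
         " structure(s) failed to parse", call. = FALSE)
  out <- matrix(0L, nrow = length(smiles), ncol = length(.SMARTS),
                dimnames = list(NULL, names(.SMARTS)))
  for (g in names(.SMARTS)) {
    tot <- integer(length(smiles))
    for (pat in .SMARTS[[g]]) {
      tot <- tot + as.integer(ChemmineOB::smartsSearch_OB(obmols, pat,
                                                          uniqueMatches = TRUE))
    }
    out[, g] <- tot
  }
  out
}
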