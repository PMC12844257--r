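# The two structural transforms of the cascade.
#
# Step 1, CuAAC: an organic azide and a terminal alkyne combine into the
# 1,4-disubstituted 1,2,3-triazole (the copper(I)-catalyzed reaction is
# 1,4-selective, so no 1,5-regioisomer is ever emitted). The transform is
# a pure cycloaddition: all heavy atoms of both reactants are retained.
#
# Step 2, sulfonamide N-acylation: the primary sulfonamide nitrogen of the
# cycloadduct is acylated by a carboxylic acid, forming the N-acyl
# sulfonamide -S(=O)2-N(H)-C(=O)- and losing one water, i.e. exactly one
# heavy atom (the acid's hydroxyl oxygen) disappears.
#
# Both transforms are explicit graph edits on the Kekulé structure;
# aromaticity of the new triazole ring is perceived by Open Babel when the
# product is canonicalized.

# locate the azide triple: returns list(Na, Nb, Nc) with Na bound to carbon
.find_azide <- function(mol) {
  hits <- list()
  deg <- .mol_degree(mol)
  for (i in which(mol$elem == "N")) {
    nb <- .mol_neighbors(mol, i)
    cn <- nb[mol$elem[nb] == "C"]
    nn <- nb[mol$elem[nb] == "N"]
    if (length(cn) != 1L || length(nn) != 1L || deg[i] != 2L) next
    mid <- nn
    nb2 <- setdiff(.mol_neighbors(mol, mid), i)
    term <- nb2[mol$elem[nb2] == "N" & deg[nb2] == 1L]
    if (length(nb2) == 1L && length(term) == 1L)
      hits[[length(hits) + 1L]] <- list(Na = i, Nb = mid, Nc = term)
  }
  hits
}

# locate terminal alkyne: returns list(Ci = internal C, Ct = terminal CH)
.find_terminal_alkyne <- function(mol) {
  deg <- .mol_degree(mol)
  hits <- list()
  b <- mol$bonds
  for (r in which(b$order == 3L)) {
    i <- b$a1[r]; j <- b$a2[r]
    if (mol$elem[i] != "C" || mol$elem[j] != "C") next
    if (deg[j] == 1L)      hits[[length(hits) + 1L]] <- list(Ci = i, Ct = j)
    else if (deg[i] == 1L) hits[[length(hits) + 1L]] <- list(Ci = j, Ct = i)
  }
  hits
}

# locate primary sulfonamide: returns list(S, N) with N the NH2 nitrogen
.find_primary_sulfonamide <- function(mol) {
  deg <- .mol_degree(mol)
  hits <- list()
  for (s in which(mol$elem == "S")) {
    nb <- .mol_neighbors(mol, s)
    os <- nb[mol$elem[nb] == "O" &
             vapply(nb, function(o) .bond_order_between(mol, s, o) == 2L, logical(1)) &
             deg[nb] == 1L]
    ns <- nb[mol$elem[nb] == "N" & deg[nb] == 1L]
    cs <- nb[mol$elem[nb] == "C"]
    if (length(os) == 2L && length(ns) == 1L && length(cs) == 1L)
      hits[[length(hits) + 1L]] <- list(S = s, N = ns)
  }
  hits
}

# locate carboxylic acid: returns list(C = carbonyl carbon, OH = hydroxyl O)
.find_carboxylic_acid <- function(mol) {
  deg <- .mol_degree(mol)
  hits <- list()
  for (cc in which(mol$elem == "C")) {
    nb <- .mol_neighbors(mol, cc)
    od <- nb[mol$elem[nb] == "O" & deg[nb] == 1L &
             vapply(nb, function(o) .bond_order_between(mol, cc, o) == 2L, logical(1))]
    oh <- nb[mol$elem[nb] == "O" & deg[nb] == 1L &
             vapply(nb, function(o) .bond_order_between(mol, cc, o) == 1L, logical(1))]
    if (length(od) == 1L && length(oh) == 1L)
      hits[[length(hits) + 1L]] <- list(C = cc, OH = oh)
  }
  hits
}

# merge two molecules into one atom/bond table; returns mol plus the index
# offset applied to the second molecule
.merge_mols <- function(m1, m2) {
  off <- length(m1$elem)
  bonds2 <- m2$bonds
  bonds2$a1 <- bonds2$a1 + off
  bonds2$a2 <- bonds2$a2 + off
  structure(list(elem = c(m1$elem, m2$elem),
                 charge = c(m1$charge, m2$charge),
                 bonds = rbind(m1$bonds, bonds2),
                 name = paste(m1$name, m2$name, sep = "+")),
            class = "clickmol")
}

.as_block <- function(x, role) {
  if (inherits(x, "building_block")) {
    if (x$role != role) stop("expected a '", role, "' building block, got '",
                             x$role, "'", call. = FALSE)
    x
  } else {
    validate_building_block(x, role)
  }
}

# graph edit for one CuAAC cycloaddition; returns the product clickmol
.cuaac_mol <- function(azmol, akmol, az_atoms, ak_atoms) {
  m <- .merge_mols(azmol, akmol)
  off <- length(azmol$elem)
  Na <- az_atoms$Na; Nb <- az_atoms$Nb; Nc <- az_atoms$Nc
  Ci <- ak_atoms$Ci + off; Ct <- ak_atoms$Ct + off
  # ring Kekulé: N1(Na)-N2(Nb) single, N2=N3(Nc) double, N3-C4(Ci) single,
  # C4=C5(Ct) double, C5-N1 single; azide charges are neutralized
  m$charge[c(Na, Nb, Nc)] <- 0L
  m$bonds$order[.bond_row(m, Na, Nb)] <- 1L
  m$bonds$order[.bond_row(m, Nb, Nc)] <- 2L
  m$bonds$order[.bond_row(m, Ci, Ct)] <- 2L
  m$bonds <- rbind(m$bonds,
                   data.frame(a1 = Nc, a2 = Ci, order = 1L),
                   data.frame(a1 = Ct, a2 = Na, order = 1L))
  m
}

#' CuAAC cycloaddition product
#'
#' Joins an organic azide and a terminal alkyne into the 1,4-disubstituted
#' 1,2,3-triazole: the azide's carbon substituent ends up on ring N1, the
#' alkyne's substituent on C4. Heavy atoms are conserved.
#'
#' @param azide,alkyne `building_block` objects (or SMILES, validated on
#'   the fly) with the matching roles.
#' @return canonical SMILES of the product.
#' @examples
#' cuaac_product("[N-]=[N+]=NCc1ccccc1", "C#CCS(N)(=O)=O")
#' @export
cuaac_product <- function(azide, alkyne) {
  azide <- .as_block(azide, "azide")
  alkyne <- .as_block(alkyne, "alkyne")
  az <- .find_azide(azide$mol)
  ak <- .find_terminal_alkyne(alkyne$mol)
  if (length(az) != 1L)
    stop("enumeration error: found ", length(az), " azide sites in ",
         azide$smiles, call. = FALSE)
  if (length(ak) != 1L)
    stop("enumeration error: found ", length(ak), " terminal alkyne sites in ",
         alkyne$smiles, call. = FALSE)
  prod <- mol_to_smiles(.cuaac_mol(azide$mol, alkyne$mol, az[[1L]], ak[[1L]]))
  if (is.na(prod) || grepl(".", prod, fixed = TRUE))
    stop("enumeration error: cycloaddition produced an invalid structure",
         call. = FALSE)
  prod
}

# graph edit for the N-acylation; returns the product clickmol
.acylate_mol <- function(submol, acmol, sulf, acid) {
  m <- .merge_mols(submol, acmol)
  off <- length(submol$elem)
  N <- sulf$N
  Cc <- acid$C + off; OH <- acid$OH + off
  # drop the hydroxyl oxygen (condensation loses it as water)
  keep <- setdiff(seq_along(m$elem), OH)
  remap <- integer(length(m$elem)); remap[keep] <- seq_along(keep)
  b <- m$bonds
  b <- b[b$a1 != OH & b$a2 != OH, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  m$elem <- m$elem[keep]; m$charge <- m$charge[keep]
  b <- rbind(b, data.frame(a1 = remap[N], a2 = remap[Cc], order = 1L))
  m$bonds <- b
  m
}

#' Acylate a primary sulfonamide with a carboxylic acid
#'
#' Forms the N-acyl sulfonamide -S(=O)2-N(H)-C(=O)- by condensing the
#' substrate's single primary sulfonamide nitrogen with the acid's
#' carboxyl carbon; one water is lost, so the product has one heavy atom
#' (the acid's hydroxyl oxygen) fewer than the sum of its parents. Only
#' the sulfonamide nitrogen is ever acylated, even if the substrate
#' carries other N-H groups.
#'
#' @param substrate SMILES of a molecule bearing exactly one primary
#'   sulfonamide (typically a CuAAC cycloadduct).
#' @param acid `building_block` of role `"acid"` (or SMILES).
#' @return canonical SMILES of the product.
#' @examples
#' acylate_sulfonamide("NS(=O)(=O)c1ccccc1", "CC(=O)O")
#' @export
acylate_sulfonamide <- function(substrate, acid) {
  stopifnot(is.character(substrate), length(substrate) == 1L)
  acid <- .as_block(acid, "acid")
  submol <- mol_from_smiles(substrate)
  sulf <- .find_primary_sulfonamide(submol)
  if (length(sulf) != 1L)
    stop("precondition error: substrate must contain exactly one primary ",
         "sulfonamide, found ", length(sulf), " in ", substrate, call. = FALSE)
  ac <- .find_carboxylic_acid(acid$mol)
  if (length(ac) != 1L)
    stop("enumeration error: found ", length(ac), " carboxylic acid sites in ",
         acid$smiles, call. = FALSE)
  prod <- mol_to_smiles(.acylate_mol(submol, acid$mol, sulf[[1L]], ac[[1L]]))
  if (is.na(prod) || grepl(".", prod, fixed = TRUE))
    stop("enumeration error: acylation produced an invalid structure",
         call. = FALSE)
  prod
}
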