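# Building-block validation.
#
# A building block is one reactant for the two-step cascade: an organic
# azide, a terminal alkyne, or a carboxylic acid. Each must carry exactly
# one reactive group of its declared role and none of the other two roles,
# so that every planned combination has a single unambiguous product.
# A primary sulfonamide (the handle for the second, N-acylation step) is
# allowed on azides and alkynes and recorded in `carries_sulfonamide`.

.ROLES <- c("azide", "alkyne", "acid")
.ROLE_GROUP <- c(azide = "azide", alkyne = "terminal_alkyne", acid = "carboxylic_acid")

#' Validate a building block
#'
#' Parses the SMILES, checks connectivity and reactive-group content, and
#' returns a `building_block` object or raises an informative error.
#'
#' Rules enforced: the SMILES must parse to a single connected molecule;
#' it must contain exactly one reactive group matching `role` (azide on
#' carbon, terminal alkyne, or carboxylic acid); it must contain no
#' reactive group of the other two roles; it may contain at most one
#' primary sulfonamide (recorded, not required); it must not already
#' contain an N-acyl sulfonamide.
#'
#' @param smiles SMILES string of the reactant.
#' @param role one of `"azide"`, `"alkyne"`, `"acid"`.
#' @param set_label label of the building-block set (e.g. `"1"`, `"2"`, `"3"`).
#' @param index 1-based label of the block within its set; labels may be
#'   non-contiguous, so this is an identifier, not a position.
#' @return object of class `building_block` with fields `set_label`,
#'   `index`, `role`, `smiles` (canonical), `carries_sulfonamide`, and the
#'   parsed molecule.
#' @examples
#' validate_building_block("C#CCS(N)(=O)=O", "alkyne")
#' validate_building_block("CC(=O)O", "acid")
#' @export
validate_building_block <- function(smiles, role, set_label = "1", index = 1L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("SMILES must be non-empty", call. = FALSE)
  role <- match.arg(role, .ROLES)
  can <- canonical_smiles(smiles)
  if (grepl(".", can, fixed = TRUE))
    stop("building block must be a single connected molecule, got multi-fragment SMILES '",
         smiles, "'", call. = FALSE)
  counts <- count_groups(can)[1L, ]
  own <- .ROLE_GROUP[[role]]
  if (counts[[own]] != 1L)
    stop(sprintf("validation error for '%s': expected exactly 1 %s group for role '%s', found %d",
                 smiles, gsub("_", " ", own), role, counts[[own]]), call. = FALSE)
  for (other in setdiff(.ROLES, role)) {
    g <- .ROLE_GROUP[[other]]
    if (counts[[g]] != 0L)
      stop(sprintf("validation error for '%s': role '%s' block must not contain a %s group (found %d)",
                   smiles, role, gsub("_", " ", g), counts[[g]]), call. = FALSE)
  }
  if (counts[["primary_sulfonamide"]] > 1L)
    stop(sprintf("validation error for '%s': %d primary sulfonamide groups; at most one is allowed",
                 smiles, counts[["primary_sulfonamide"]]), call. = FALSE)
  if (counts[["nacyl_sulfonamide"]] != 0L)
    stop(sprintf("validation error for '%s': block already contains an N-acyl sulfonamide",
                 smiles), call. = FALSE)
  structure(list(
    set_label = as.character(set_label),
    index = as.integer(index),
    role = role,
    smiles = can,
    carries_sulfonamide = counts[["primary_sulfonamide"]] == 1L,
    mol = mol_from_smiles(can)
  ), class = "building_block")
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf("<building_block %s{%d}> role=%s  sulfonamide=%s\n  %s\n",
              x$set_label, x$index, x$role,
              if (x$carries_sulfonamide) "yes" else "no", x$smiles))
  invisible(x)
}

block_id <- function(b) sprintf("%s{%d}", b$set_label, b$index)

#' Read building blocks from a CSV table
#'
#' Expects columns `set_label`, `index`, `role`, `smiles`; every row is
#' validated with [validate_building_block()].
#'
#' @param path CSV file path.
#' @return named list of `building_block` objects (names are
#'   `set_label{index}` tokens).
#' @export
read_building_blocks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_label", "index", "role", "smiles")
  if (!all(need %in% names(df)))
    stop("building-block CSV must have columns: ", paste(need, collapse = ", "))
  blocks <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    blocks[[r]] <- validate_building_block(df$smiles[r], df$role[r],
                                           df$set_label[r], df$index[r])
  }
  names(blocks) <- vapply(blocks, block_id, character(1))
  if (anyDuplicated(names(blocks)))
    stop("duplicate building-block labels in ", path)
  blocks
}

#' Write building blocks to CSV
#' @param blocks list of `building_block` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_building_blocks <- function(blocks, path) {
  df <- data.frame(
    set_label = vapply(blocks, `[[`, character(1), "set_label"),
    index = vapply(blocks, `[[`, integer(1), "index"),
    role = vapply(blocks, `[[`, character(1), "role"),
    smiles = vapply(blocks, `[[`, character(1), "smiles"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
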