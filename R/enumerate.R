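# Virtual library enumeration.
#
# A library design holds three building-block sets (azides, alkynes,
# acids); exactly one of the azide/alkyne sets carries the primary
# sulfonamide that the second step acylates. Members are addressed by
# {i,j,k} label triples (1-based set labels, possibly non-contiguous),
# following the usual combinatorial numeration where library member
# lib{i,j,k} is the product of azide i, alkyne j and acid k.

#' Assemble and check a library design
#'
#' @param library_label label of the product library (e.g. `"4"` or `"7"`).
#' @param azides,alkynes,acids lists of `building_block` objects of the
#'   matching roles.
#' @param sulfonamide_carrier which click partner carries the primary
#'   sulfonamide: `"alkyne"` (alkynyl sulfonamides) or `"azide"`
#'   (azido sulfonamides). Every member of that set must carry one; no
#'   member of the other set may.
#' @param planned optional data frame with integer columns `i`, `j`, `k`
#'   giving the planned combinations as label triples. `NULL` means the
#'   full factorial space.
#' @return object of class `library_design`.
#' @export
library_design <- function(library_label, azides, alkynes, acids,
                           sulfonamide_carrier = c("alkyne", "azide"),
                           planned = NULL) {
  sulfonamide_carrier <- match.arg(sulfonamide_carrier)
  chk_role <- function(set, role) {
    ok <- vapply(set, function(b) inherits(b, "building_block") && b$role == role,
                 logical(1))
    if (!all(ok)) stop("all members of the ", role, " set must be validated '",
                       role, "' building blocks", call. = FALSE)
  }
  chk_role(azides, "azide"); chk_role(alkynes, "alkyne"); chk_role(acids, "acid")
  carrier_set <- if (sulfonamide_carrier == "alkyne") alkynes else azides
  other_set   <- if (sulfonamide_carrier == "alkyne") azides else alkynes
  if (!all(vapply(carrier_set, `[[`, logical(1), "carries_sulfonamide")))
    stop("every ", sulfonamide_carrier,
         " must carry a primary sulfonamide in this design", call. = FALSE)
  if (any(vapply(other_set, `[[`, logical(1), "carries_sulfonamide")))
    stop("only the ", sulfonamide_carrier, " set may carry primary sulfonamides",
         call. = FALSE)
  if (any(vapply(acids, `[[`, logical(1), "carries_sulfonamide")))
    stop("acid building blocks must not carry primary sulfonamides", call. = FALSE)
  labs <- function(set) vapply(set, `[[`, integer(1), "index")
  if (!is.null(planned)) {
    planned <- as.data.frame(planned)
    if (!all(c("i", "j", "k") %in% names(planned)))
      stop("planned combinations need columns i, j, k", call. = FALSE)
    if (!all(planned$i %in% labs(azides)) ||
        !all(planned$j %in% labs(alkynes)) ||
        !all(planned$k %in% labs(acids)))
      stop("planned triples reference labels absent from the building-block sets",
           call. = FALSE)
  }
  structure(list(library_label = as.character(library_label),
                 azides = azides, alkynes = alkynes, acids = acids,
                 sulfonamide_carrier = sulfonamide_carrier,
                 planned = planned),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf(paste0("<library_design %s> %d azides x %d alkynes x %d acids",
                     " (sulfonamide on %ss)\n  theoretical space: %d; planned: %s\n"),
              x$library_label, length(x$azides), length(x$alkynes),
              length(x$acids), x$sulfonamide_carrier, count_theoretical(x),
              if (is.null(x$planned)) "full factorial" else nrow(x$planned)))
  invisible(x)
}

#' Size of the theoretical combination space
#'
#' The number of reactant combinations accessible to a design is the plain
#' product of the three set sizes, independent of which combinations were
#' actually planned.
#'
#' @param design a `library_design`, or an integer vector of three set sizes.
#' @return non-negative integer count.
#' @examples
#' count_theoretical(c(83, 8, 95))   # 63080
#' count_theoretical(c(3, 51, 67))   # 10251
#' @export
count_theoretical <- function(design) {
  sizes <- if (inherits(design, "library_design")) {
    c(length(design$azides), length(design$alkynes), length(design$acids))
  } else {
    stopifnot(is.numeric(design), length(design) == 3L)
    as.integer(design)
  }
  if (any(sizes == 0L)) warning("empty building-block set: theoretical space is 0")
  total <- prod(as.numeric(sizes))
  if (total <= .Machine$integer.max) as.integer(total) else total
}

#' Enumerate library members
#'
#' Runs the two-step transform (CuAAC, then sulfonamide N-acylation) for
#' every planned -- or, with `planned_only = FALSE`, every possible --
#' {i,j,k} combination. Failed transforms are recorded, not fatal, so one
#' bad combination never aborts a campaign. Distinct triples that collapse
#' to the same canonical product are kept but flagged as duplicates.
#'
#' @param design a `library_design`.
#' @param planned_only if `TRUE` (default) and the design has a planned
#'   list, enumerate only those triples; otherwise the full factorial.
#' @return data frame of class `library_members` with columns `member_id`,
#'   `i`, `j`, `k`, `azide_id`, `alkyne_id`, `acid_id`, `product_smiles`,
#'   `duplicate`, `status`, `message`.
#' @export
enumerate_library <- function(design, planned_only = TRUE) {
  stopifnot(inherits(design, "library_design"))
  labs <- function(set) vapply(set, `[[`, integer(1), "index")
  az_by <- stats::setNames(design$azides, labs(design$azides))
  ak_by <- stats::setNames(design$alkynes, labs(design$alkynes))
  ac_by <- stats::setNames(design$acids, labs(design$acids))
  triples <- if (planned_only && !is.null(design$planned)) {
    design$planned[, c("i", "j", "k")]
  } else {
    expand.grid(i = as.integer(names(az_by)), j = as.integer(names(ak_by)),
                k = as.integer(names(ac_by)), KEEP.OUT.ATTRS = FALSE)[, c("i", "j", "k")]
  }
  n <- nrow(triples)
  out <- data.frame(member_id = character(n), i = triples$i, j = triples$j,
                    k = triples$k, azide_id = character(n),
                    alkyne_id = character(n), acid_id = character(n),
                    product_smiles = rep(NA_character_, n), duplicate = logical(n),
                    status = rep("ok", n), message = rep("", n),
                    stringsAsFactors = FALSE)
  adduct_cache <- new.env(parent = emptyenv())
  for (r in seq_len(n)) {
    i <- triples$i[r]; j <- triples$j[r]; k <- triples$k[r]
    az <- az_by[[as.character(i)]]; ak <- ak_by[[as.character(j)]]
    ac <- ac_by[[as.character(k)]]
    out$member_id[r] <- sprintf("%s{%d,%d,%d}", design$library_label, i, j, k)
    out$azide_id[r] <- block_id(az)
    out$alkyne_id[r] <- block_id(ak)
    out$acid_id[r] <- block_id(ac)
    key <- sprintf("%d_%d", i, j)
    res <- tryCatch({
      adduct <- if (!is.null(adduct_cache[[key]])) adduct_cache[[key]]
                else assign(key, cuaac_product(az, ak), envir = adduct_cache)
      acylate_sulfonamide(adduct, ac)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[r] <- "failed"
      out$message[r] <- conditionMessage(res)
    } else {
      out$product_smiles[r] <- res
    }
  }
  ok <- out$status == "ok"
  out$duplicate[ok] <- duplicated(out$product_smiles[ok])
  class(out) <- c("library_members", "data.frame")
  out
}

#' Write enumerated products as SDF plus a CSV manifest
#'
#' The SDF carries `member_id` and the three parent labels as data fields;
#' the manifest mirrors the `library_members` table.
#'
#' @param members `library_members` data frame from [enumerate_library()].
#' @param sdf_path,manifest_path output file paths.
#' @return invisibly, the number of structures written.
#' @export
write_products <- function(members, sdf_path, manifest_path = NULL) {
  ok <- members$status == "ok"
  if (any(ok)) {
    sub <- members[ok, , drop = FALSE]
    set <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(sub$product_smiles, sub$member_id)))
    ChemmineR::datablock(set) <- lapply(seq_len(nrow(sub)), function(q) {
      c(member_id = sub$member_id[q], azide_id = sub$azide_id[q],
        alkyne_id = sub$alkyne_id[q], acid_id = sub$acid_id[q])
    })
    suppressWarnings(ChemmineR::write.SDF(set, file = sdf_path, cid = TRUE))
  } else {
    file.create(sdf_path)
  }
  if (!is.null(manifest_path))
    utils::write.csv(as.data.frame(members), manifest_path, row.names = FALSE)
  invisible(sum(ok))
}
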