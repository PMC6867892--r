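#' Venn partition of stage DEG sets across species
#'
#' Partitions the union of per-species ortho-DEG id sets into the 15
#' species-combination cells of a four-way Venn diagram. Convenience views:
#' `brown_unique` (ids present in both brown-rot species and neither
#' white-rot species), `white_unique` (symmetric) and `common_to_all`
#' (intersection of all four). The cells are pairwise disjoint and their
#' union is the union of the input sets.
#'
#' @param id_sets Named list of character id vectors, one per species (for
#'   one stage), as from [assign_orthodeg_ids()].
#' @param rot_type Named character vector mapping each species to `"brown"`
#'   or `"white"`.
#' @return Object of class `venn_partition`: list with `cells` (named list
#'   keyed by `sp1+sp2+...`), `brown_unique`, `white_unique`,
#'   `common_to_all`, `species`, `rot_type`.
#' @export
venn_partition <- function(id_sets, rot_type) {
  species <- names(id_sets)
  if (is.null(species) || !length(species))
    stop("id_sets must be a named per-species list", call. = FALSE)
  unknown <- setdiff(species, names(rot_type))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  ids <- sort(unique(unlist(id_sets, use.names = FALSE)))
  member <- vapply(species, function(sp) ids %in% id_sets[[sp]],
                   logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, species))
  key <- apply(member, 1L, function(m) paste(species[m], collapse = "+"))
  cells <- split(ids, key)

  # emit every non-empty species combination, even when its cell is empty
  combos <- unlist(lapply(seq_along(species), function(k)
    utils::combn(species, k, paste, collapse = "+", simplify = FALSE)))
  all_cells <- stats::setNames(
    lapply(combos, function(cb) if (cb %in% names(cells)) cells[[cb]]
           else character(0)),
    combos)

  brown <- species[rot_type[species] == "brown"]
  white <- species[rot_type[species] == "white"]
  cell_of <- function(sps) {
    cb <- paste(sps, collapse = "+")
    if (cb %in% names(all_cells)) all_cells[[cb]] else character(0)
  }
  structure(list(
    cells = all_cells,
    brown_unique = cell_of(brown),
    white_unique = cell_of(white),
    common_to_all = cell_of(species),
    species = species,
    rot_type = rot_type[species]
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition over %d ids (%d species)\n",
              length(unlist(x$cells, use.names = FALSE)), length(x$species)))
  cat(sprintf("  brown-unique %d, white-unique %d, common-to-all %d\n",
              length(x$brown_unique), length(x$white_unique),
              length(x$common_to_all)))
  invisible(x)
}

#' Flatten a Venn partition to a two-column table
#' @param venn A `venn_partition`.
#' @return Data frame with `cell` and `id` columns.
#' @export
venn_table <- function(venn) {
  stopifnot(inherits(venn, "venn_partition"))
  n <- lengths(venn$cells)
  data.frame(cell = rep(names(venn$cells), n),
             id = unlist(venn$cells, use.names = FALSE),
             stringsAsFactors = FALSE)
}
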