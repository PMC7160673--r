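#' Residue alphabet of the Kme-OPL
#'
#' The degenerate positions of the library draw from the 20 standard amino
#' acids minus cysteine, which is excluded for synthetic-chemistry reasons.
#' The canonical order (sorted one-letter codes) fixes matrix column layout
#' and set enumeration across the package.
#'
#' @return Character vector of 19 one-letter residue codes.
#' @export
kme_alphabet <- function() {
  sort(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C"))
}

#' Flanking positions of the Kme-OPL seven-mer
#'
#' Offsets relative to the fixed central lysine (position 0): minus three to
#' plus three, excluding zero.
#'
#' @return Integer vector `c(-3, -2, -1, 1, 2, 3)`.
#' @export
kme_positions <- function() {
  c(-3L, -2L, -1L, 1L, 2L, 3L)
}

#' Methyl orders of the central lysine
#'
#' @return Integer vector `0:3` (Kme0 through Kme3).
#' @export
kme_orders <- function() 0:3

# "P-3" ... "P+3" labels used for matrix rows and set ids
position_label <- function(offset) sprintf("P%+d", offset)

#' Serialize a set identifier
#'
#' Stable string form `Kme{m}_P{+k}_{residue}` used in file I/O.
#'
#' @param methyl_order integer in 0:3
#' @param fixed_position integer offset in `kme_positions()`
#' @param fixed_residue one-letter residue code (not `"C"`)
#' @return Character set id.
#' @export
kme_set_id <- function(methyl_order, fixed_position, fixed_residue) {
  sprintf("Kme%d_P%+d_%s", methyl_order, fixed_position, fixed_residue)
}

#' Enumerate Kme-OPL sets
#'
#' Each set fixes one residue at one flanking position for one methyl order;
#' all other flanks are an equimolar degenerate mix. With the full 19-residue
#' alphabet and six flanking positions this yields the 114 sets per methyl
#' order that make up one library pool.
#'
#' @param methyl_order integer in 0:3.
#' @param alphabet residue alphabet (default the canonical 19 letters).
#'   Must not contain `"C"`.
#' @param positions flank offsets (default `kme_positions()`).
#' @return A data.frame with columns `set_id`, `methyl_order`,
#'   `fixed_position`, `fixed_residue`, ordered position-major then by
#'   alphabet order.
#' @examples
#' nrow(enumerate_sets(3)) # 114
#' @export
enumerate_sets <- function(methyl_order, alphabet = kme_alphabet(),
                           positions = kme_positions()) {
  stopifnot(length(alphabet) > 0, length(positions) > 0)
  if (!methyl_order %in% kme_orders()) {
    stop("methyl_order must be one of 0, 1, 2, 3")
  }
  if ("C" %in% alphabet) {
    stop("invalid alphabet: cysteine is excluded from the Kme-OPL")
  }
  if (anyDuplicated(alphabet) || any(0L %in% positions)) {
    stop("alphabet must be duplicate-free and positions must exclude 0")
  }
  grid <- expand.grid(fixed_residue = alphabet, fixed_position = positions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("fixed_position", "fixed_residue")]
  grid <- grid[order(match(grid$fixed_position, positions),
                     match(grid$fixed_residue, alphabet)), ]
  data.frame(
    set_id = kme_set_id(methyl_order, grid$fixed_position, grid$fixed_residue),
    methyl_order = as.integer(methyl_order),
    fixed_position = as.integer(grid$fixed_position),
    fixed_residue = grid$fixed_residue,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Validate a lysine-centered seven-mer window; returns invisibly.
check_window <- function(window) {
  if (length(window) != 1L || !is.character(window) || nchar(window) != 7L) {
    stop("motif window must be a single 7-character string")
  }
  if (substr(window, 4L, 4L) != "K") {
    stop("motif window must have 'K' at the central (4th) position")
  }
  invisible(window)
}

# residue of a window at a flank offset in -3..3 (0 = central K)
window_residue <- function(window, offset) {
  substr(window, offset + 4L, offset + 4L)
}

#' Test whether a motif belongs to a Kme-OPL set
#'
#' A lysine-centered seven-mer of a given methyl order is a member of a set
#' when the methyl orders match, the residue at the set's fixed position
#' equals the fixed residue, and no flanking residue is cysteine (peptides
#' with cysteine were never synthesized, so no set contains them).
#'
#' @param set one row of [enumerate_sets()] (or a list with
#'   `methyl_order`, `fixed_position`, `fixed_residue`).
#' @param window 7-character motif string, central residue `"K"`.
#' @param methyl_order methyl order carried by the motif.
#' @return Logical scalar.
#' @examples
#' set <- list(methyl_order = 3, fixed_position = -2, fixed_residue = "A")
#' set_membership(set, "TARKSTG", 3) # TRUE: H3K9-like context, A at P-2
#' @export
set_membership <- function(set, window, methyl_order) {
  check_window(window)
  if (methyl_order != set$methyl_order) return(FALSE)
  flanks <- strsplit(window, "")[[1]][-4]
  if ("C" %in% flanks) return(FALSE)
  window_residue(window, set$fixed_position) == set$fixed_residue
}

#' Per-position residue composition of a Kme-OPL set
#'
#' The fixed position carries its fixed residue at fraction 1; every other
#' flank is an equimolar mix over the alphabet; the central position is the
#' methylated lysine at fraction 1.
#'
#' @inheritParams set_membership
#' @param alphabet residue alphabet of the degenerate positions.
#' @return Named list keyed by position label (`"P-3"` ... `"P+3"`, `"P0"`),
#'   each a named numeric vector of residue fractions summing to 1.
#' @export
degenerate_composition <- function(set, alphabet = kme_alphabet()) {
  positions <- kme_positions()
  out <- vector("list", length(positions) + 1L)
  names(out) <- c(position_label(positions[positions < 0]), "P0",
                  position_label(positions[positions > 0]))
  for (p in positions) {
    lab <- position_label(p)
    if (p == set$fixed_position) {
      out[[lab]] <- stats::setNames(1, set$fixed_residue)
    } else {
      out[[lab]] <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                    alphabet)
    }
  }
  out[["P0"]] <- stats::setNames(1, sprintf("Kme%d", set$methyl_order))
  out
}

#' Export the library definition
#'
#' Writes the set table (one row per set, all four methyl orders by default)
#' as TSV with columns `set_id`, `methyl_order`, `fixed_position`,
#' `fixed_residue`.
#'
#' @param path output file path.
#' @param methyl_orders methyl orders to include.
#' @inheritParams enumerate_sets
#' @return The written data.frame, invisibly.
#' @export
write_library_definition <- function(path, methyl_orders = kme_orders(),
                                     alphabet = kme_alphabet(),
                                     positions = kme_positions()) {
  tab <- do.call(rbind, lapply(methyl_orders, enumerate_sets,
                               alphabet = alphabet, positions = positions))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
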