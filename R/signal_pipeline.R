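#' Subtract GST background from a reader signal
#'
#' Reader wells carry a GST-tag sandwich signal; GST-only control wells
#' measure the background, which is subtracted. Negative differences are
#' clamped to zero: a reader cannot bind less than not at all, and downstream
#' LoB scores are floored at zero on the RFU scale.
#'
#' @param reader_mean mean reader fluorescence (RFU, >= 0).
#' @param gst_mean mean GST-control fluorescence (RFU, >= 0).
#' @return `max(reader_mean - gst_mean, 0)`, vectorized.
#' @export
subtract_background <- function(reader_mean, gst_mean) {
  if (any(!is.finite(reader_mean)) || any(!is.finite(gst_mean)) ||
      any(reader_mean < 0) || any(gst_mean < 0)) {
    stop("invalid signal: fluorescence values must be finite and non-negative")
  }
  pmax(reader_mean - gst_mean, 0)
}

#' Infer which background reference to subtract
#'
#' Some plates lack a simultaneous GST measurement. For those, the unmodified
#' (Kme0) pool signal — which for a methyl-dependent reader reflects
#' background only — decides whether the low or the high background reference
#' applies: the nearer reference is chosen, ties going to the high reference
#' (the conservative choice that minimizes false positives).
#'
#' @param kme0_pool_signal Kme0 pool fluorescence (RFU).
#' @param low_ref,high_ref low and high background references (RFU),
#'   `low_ref <= high_ref`.
#' @return The chosen background level (RFU).
#' @export
infer_background <- function(kme0_pool_signal, low_ref, high_ref) {
  stopifnot(low_ref <= high_ref)
  if (abs(kme0_pool_signal - high_ref) <= abs(kme0_pool_signal - low_ref)) {
    high_ref
  } else {
    low_ref
  }
}

#' Construct a reader profile from matrices
#'
#' A reader profile is the positions x residues matrix of GST-subtracted
#' average signals for one reader at one methyl order, plus a 0-1 normalized
#' twin (divided by its maximum). This constructor accepts a raw matrix
#' directly; [build_profile()] assembles one from plate measurements. Row
#' names must be position labels (`"P-3"` ... `"P+3"`) and column names the
#' residue alphabet; toy alphabets of any size are allowed so reduced models
#' can be profiled.
#'
#' @param raw numeric matrix of GST-subtracted signals (RFU, >= 0), rows =
#'   flank positions, columns = residues.
#' @param reader_id reader identifier.
#' @param methyl_order methyl order profiled.
#' @param n_replicates optional matrix of per-cell replicate counts.
#' @param background character note on how background was obtained.
#' @return An object of class `kme_profile`.
#' @export
kme_profile <- function(raw, reader_id = "reader", methyl_order = 3L,
                        n_replicates = NULL, background = "matched") {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("profile raw matrix must be finite and non-negative")
  }
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    stop("raw matrix needs position row names and residue column names")
  }
  offsets <- as.integer(sub("P", "", rownames(raw)))
  if (anyNA(offsets) || any(offsets == 0L)) {
    stop("row names must be flank position labels like 'P-3', 'P+1'")
  }
  mx <- max(raw)
  norm <- if (mx > 0) raw / mx else raw * 0
  structure(
    list(reader_id = reader_id,
         methyl_order = as.integer(methyl_order),
         raw = raw,
         norm = norm,
         positions = offsets,
         alphabet = colnames(raw),
         n_replicates = n_replicates,
         background = background,
         no_binding = mx == 0),
    class = "kme_profile"
  )
}

#' @export
print.kme_profile <- function(x, ...) {
  cat(sprintf("Kme-OPL reader profile: %s, Kme%d\n", x$reader_id,
              x$methyl_order))
  cat(sprintf("  %d positions x %d residues; background: %s\n",
              nrow(x$raw), ncol(x$raw), x$background))
  if (x$no_binding) {
    cat("  flagged: no binding (all-zero matrix)\n")
  } else {
    i <- which(x$raw == max(x$raw), arr.ind = TRUE)[1, ]
    cat(sprintf("  max signal %.1f RFU at (%s, %s)\n", max(x$raw),
                rownames(x$raw)[i[1]], colnames(x$raw)[i[2]]))
  }
  invisible(x)
}

#' @export
plot.kme_profile <- function(x, normalized = TRUE, ...) {
  m <- if (normalized) x$norm else x$raw
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, ]),
                  axes = FALSE, xlab = "residue", ylab = "position",
                  main = sprintf("%s Kme%d-OPL profile", x$reader_id,
                                 x$methyl_order), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 1, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1)
  invisible(x)
}

# Subset of a plate table: set wells (pool == FALSE) for one reader/order.
plate_set_wells <- function(plate, reader_id, methyl_order) {
  keep <- plate$reader_id == reader_id &
    plate$methyl_order == methyl_order & !plate$pool
  plate[keep, , drop = FALSE]
}

#' Build a reader profile from plate measurements
#'
#' Averages replicate reader signals per set, subtracts the matched GST mean
#' (or an inferred low/high background when GST wells are absent), clamps at
#' zero, and normalizes by the matrix maximum. Every set of the library must
#' be present at least once.
#'
#' @param plate plate table as read by [read_plate()] / produced by
#'   [simulate_plate()]: columns `reader_id`, `methyl_order`,
#'   `fixed_position`, `fixed_residue`, `pool` (logical), `replicate`,
#'   `signal`, and optionally `gst_signal`.
#' @param reader_id reader to profile (default: the single reader present).
#' @param methyl_order methyl order to profile.
#' @param alphabet,positions library geometry (defaults: the full library).
#' @param background `"matched"` to subtract per-set GST means, or
#'   `"inferred"` to use [infer_background()] with `low_ref`/`high_ref` and
#'   the Kme0 pool signal from the same plate.
#' @param low_ref,high_ref background references for `background = "inferred"`.
#' @return A [kme_profile()] object.
#' @export
build_profile <- function(plate, reader_id = unique(plate$reader_id),
                          methyl_order = 3L,
                          alphabet = kme_alphabet(),
                          positions = kme_positions(),
                          background = c("matched", "inferred"),
                          low_ref = NULL, high_ref = NULL) {
  background <- match.arg(background)
  stopifnot(length(reader_id) == 1L)
  wells <- plate_set_wells(plate, reader_id, methyl_order)

  sets <- enumerate_sets(methyl_order, alphabet, positions)
  have <- unique(kme_set_id(methyl_order, wells$fixed_position,
                            wells$fixed_residue))
  missing <- setdiff(sets$set_id, have)
  if (length(missing) > 0) {
    stop(sprintf("incomplete profile: %d sets absent (%s%s)",
                 length(missing), paste(utils::head(missing, 5),
                                        collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }

  if (background == "inferred") {
    if (is.null(low_ref) || is.null(high_ref)) {
      stop("background = 'inferred' needs low_ref and high_ref")
    }
    kme0 <- plate$signal[plate$reader_id == reader_id & plate$pool &
                           plate$methyl_order == 0L]
    if (length(kme0) == 0) stop("no Kme0 pool wells to infer background from")
    bg_level <- infer_background(mean(kme0), low_ref, high_ref)
  }

  raw <- matrix(0, nrow = length(positions), ncol = length(alphabet),
                dimnames = list(position_label(positions), alphabet))
  nrep <- raw
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    w <- wells[wells$fixed_position == s$fixed_position &
                 wells$fixed_residue == s$fixed_residue, ]
    reader_mean <- mean(w$signal)
    bg <- if (background == "matched") {
      g <- w$gst_signal[is.finite(w$gst_signal)]
      if (length(g) == 0) stop(sprintf(
        "set %s has no GST wells; use background = 'inferred'", s$set_id))
      mean(g)
    } else {
      bg_level
    }
    raw[position_label(s$fixed_position), s$fixed_residue] <-
      subtract_background(reader_mean, bg)
    nrep[position_label(s$fixed_position), s$fixed_residue] <- nrow(w)
  }
  prof <- kme_profile(raw, reader_id, methyl_order, nrep,
                      if (background == "matched") "matched GST wells"
                      else sprintf("inferred (%.1f RFU)", bg_level))
  if (prof$no_binding) warning(sprintf(
    "profile %s Kme%d flagged 'no binding': all GST-subtracted signals are 0",
    reader_id, methyl_order))
  prof
}

#' Summarize pool measurements
#'
#' Per methyl order: mean reader signal, mean GST signal, GST-subtracted
#' signal (clamped at zero), replicate count and SD across replicates.
#'
#' @param plate plate table (see [build_profile()]); only `pool == TRUE`
#'   wells are used.
#' @param reader_id reader to summarize.
#' @return data.frame with one row per methyl order present.
#' @export
pool_summary <- function(plate, reader_id = unique(plate$reader_id)) {
  stopifnot(length(reader_id) == 1L)
  wells <- plate[plate$reader_id == reader_id & plate$pool, , drop = FALSE]
  if (nrow(wells) == 0) stop("no pool wells for this reader")
  orders <- sort(unique(wells$methyl_order))
  out <- do.call(rbind, lapply(orders, function(m) {
    w <- wells[wells$methyl_order == m, ]
    g <- w$gst_signal[is.finite(w$gst_signal)]
    gst_mean <- if (length(g)) mean(g) else 0
    data.frame(methyl_order = m,
               reader_mean = mean(w$signal),
               gst_mean = gst_mean,
               subtracted = subtract_background(mean(w$signal), gst_mean),
               n = nrow(w),
               sd = stats::sd(w$signal))
  }))
  rownames(out) <- NULL
  out
}

#' Call the preferred methyl order from pool signals
#'
#' The order with the highest GST-subtracted pool signal is the preferred
#' methyl order; any order within `tol` (default 10%) of that maximum is
#' co-reported, capturing dual me2/me3 readers.
#'
#' @param pools either a [pool_summary()] data.frame or a numeric vector of
#'   subtracted pool signals named/ordered by methyl order 0..3.
#' @param tol relative co-call tolerance on the max.
#' @return List with `orders` (integer vector of called orders, empty when no
#'   signal), `status` (`"ok"` or `"no methyl-order preference detected"`),
#'   and `signals`.
#' @export
call_methyl_order <- function(pools, tol = 0.10) {
  if (is.data.frame(pools)) {
    signals <- stats::setNames(pools$subtracted, pools$methyl_order)
  } else {
    signals <- pools
    if (is.null(names(signals))) names(signals) <- kme_orders()
  }
  if (length(signals) != 4L) stop("all four methyl orders must be measured")
  mx <- max(signals)
  if (mx == 0) {
    return(list(orders = integer(0),
                status = "no methyl-order preference detected",
                signals = signals))
  }
  called <- as.integer(names(signals)[signals >= (1 - tol) * mx])
  list(orders = sort(called), status = "ok", signals = signals)
}

#' Sequence-specificity histogram of a reader profile
#'
#' Bins the per-set normalized signals over [0, 1]. Sequence-specific readers
#' pile most sets near zero (few sequences tolerated); promiscuous readers
#' spread sets toward one. The specificity index is the fraction of sets at
#' normalized signal >= 0.5; profiles are labelled specific (index <= 0.15),
#' promiscuous (index >= 0.5) or intermediate.
#'
#' @param profile a [kme_profile()].
#' @param n_bins number of equal-width bins over [0, 1] (>= 2).
#' @return List of class `kme_specificity`: `breaks`, `counts`,
#'   `specificity_index`, `label`, `n_sets`.
#' @export
specificity_histogram <- function(profile, n_bins = 10L) {
  stopifnot(inherits(profile, "kme_profile"))
  if (n_bins < 2L) stop("n_bins must be at least 2")
  vals <- as.vector(profile$norm)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  idx <- mean(vals >= 0.5)
  label <- if (idx <= 0.15) "specific" else if (idx >= 0.5) "promiscuous"
           else "intermediate"
  structure(list(breaks = breaks, counts = counts,
                 specificity_index = idx, label = label,
                 n_sets = length(vals)),
            class = "kme_specificity")
}

#' @export
print.kme_specificity <- function(x, ...) {
  cat(sprintf("Specificity over %d sets: index %.3f (%s)\n",
              x$n_sets, x$specificity_index, x$label))
  invisible(x)
}

#' Read a plate measurement table
#'
#' Reads the TSV/CSV plate dialect: columns `reader_id`, `methyl_order`,
#' `fixed_position`, `fixed_residue`, `pool`, `replicate`, `signal`,
#' `gst_signal`. Pool wells carry `pool = TRUE` and empty set fields.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame in the plate dialect.
#' @export
read_plate <- function(path, sep = "\t") {
  plate <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("reader_id", "methyl_order", "replicate", "signal")
  if (!all(needed %in% names(plate))) {
    stop("plate table must have columns: ", paste(needed, collapse = ", "))
  }
  if (is.null(plate$pool)) plate$pool <- is.na(plate$fixed_position)
  if (is.null(plate$gst_signal)) plate$gst_signal <- NA_real_
  plate$pool <- as.logical(plate$pool)
  plate
}

#' Write a plate measurement table
#'
#' @param plate plate data.frame.
#' @param path output TSV path.
#' @export
write_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(plate)
}

#' Write a reader profile to TSV matrices plus a JSON sidecar
#'
#' Writes `<stem>_raw.tsv` and `<stem>_norm.tsv` (rows = positions P-3..P+3,
#' columns = residues) and `<stem>.json` with metadata (reader, methyl order,
#' replicate counts, background mode).
#'
#' @param profile a [kme_profile()].
#' @param stem output path stem (no extension).
#' @export
write_profile <- function(profile, stem) {
  write_mat <- function(m, path) {
    utils::write.table(data.frame(position = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(profile$raw, paste0(stem, "_raw.tsv"))
  write_mat(profile$norm, paste0(stem, "_norm.tsv"))
  meta <- list(reader_id = profile$reader_id,
               methyl_order = profile$methyl_order,
               background = profile$background,
               no_binding = profile$no_binding,
               n_replicates = profile$n_replicates)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(profile)
}

#' Read a reader profile written by [write_profile()]
#'
#' @param stem path stem used when writing.
#' @return A [kme_profile()].
#' @export
read_profile <- function(stem) {
  tab <- utils::read.table(paste0(stem, "_raw.tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  raw <- as.matrix(tab[, -1, drop = FALSE])
  rownames(raw) <- tab$position
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  kme_profile(raw, meta$reader_id, meta$methyl_order,
              background = meta$background)
}
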