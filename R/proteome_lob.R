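#' Read a proteome from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return Named character vector of sequences (names = record ids, first
#'   whitespace-delimited token of the header).
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

# Coerce the accepted proteome representations to a named character vector.
as_proteome <- function(proteome) {
  if (is.data.frame(proteome)) {
    stats::setNames(as.character(proteome$sequence),
                    as.character(proteome$id))
  } else if (is.character(proteome)) {
    if (is.null(names(proteome))) {
      names(proteome) <- sprintf("protein_%d", seq_along(proteome))
    }
    proteome
  } else if (inherits(proteome, "AAStringSet")) {
    stats::setNames(as.character(proteome),
                    sub("\\s.*$", "", names(proteome)))
  } else {
    stop("proteome must be a named character vector, a data.frame with ",
         "columns id/sequence, or an AAStringSet")
  }
}

#' Extract lysine-centered seven-mers from a proteome
#'
#' Emits one motif per lysine with at least three residues on each side.
#' Lysines closer than three residues to a terminus are reported as excluded
#' (`near_terminus`): the minimum rule cannot evaluate a missing position and
#' padding would fabricate signal. Windows containing cysteine
#' (`contains_C`, never measured by the library) or a non-standard residue
#' code (`ambiguous_residue`) are likewise reported excluded so totals
#' reconcile.
#'
#' @param proteome named character vector of sequences, a data.frame with
#'   `id`/`sequence`, or an `AAStringSet`.
#' @return data.frame with columns `protein_id`, `k_position` (1-based index
#'   of the central K), `window` (7-character string, `NA` for terminal K's),
#'   `excluded` (logical), `reason` (`NA`, `"near_terminus"`, `"contains_C"`,
#'   `"ambiguous_residue"`).
#' @examples
#' extract_motifs(c(p1 = "GGGKGGG"))
#' @export
extract_motifs <- function(proteome) {
  seqs <- as_proteome(proteome)
  if (length(seqs) == 0 || all(nchar(seqs) == 0)) {
    warning("empty proteome: no motifs extracted")
    return(data.frame(protein_id = character(0), k_position = integer(0),
                      window = character(0), excluded = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    kpos <- which(strsplit(s, "")[[1]] == "K")
    if (length(kpos) == 0) return(NULL)
    near <- kpos < 4L | kpos > n - 3L
    window <- ifelse(near, NA_character_,
                     substr(rep(s, length(kpos)), kpos - 3L, kpos + 3L))
    reason <- rep(NA_character_, length(kpos))
    reason[near] <- "near_terminus"
    ok <- !near
    if (any(ok)) {
      chars <- strsplit(window[ok], "")
      has_c <- vapply(chars, function(x) "C" %in% x[-4], logical(1))
      nonstd <- vapply(chars, function(x) any(!x %in% standard), logical(1))
      reason[ok][nonstd] <- "ambiguous_residue"
      reason[ok][has_c & !nonstd] <- "contains_C"
    }
    data.frame(protein_id = id, k_position = as.integer(kpos),
               window = window, excluded = !is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(protein_id = character(0),
                                      k_position = integer(0),
                                      window = character(0),
                                      excluded = logical(0),
                                      reason = character(0))
  rownames(out) <- NULL
  out
}

#' Lowest-Bin (LoB) score of a motif
#'
#' The score of a lysine-centered seven-mer is the minimum, over its six
#' flanking (position, residue) pairs, of the profile's raw GST-subtracted
#' signal. Letting the weakest position dictate the score minimizes false
#' positives: a single disfavored residue vetoes the motif. Scores are on the
#' raw RFU scale; normalization is applied only for cross-reader comparison.
#'
#' @param profile a [kme_profile()].
#' @param window 7-character motif string with central `"K"`.
#' @return Numeric score (RFU), vectorized over `window`.
#' @export
lob_score <- function(profile, window) {
  stopifnot(inherits(profile, "kme_profile"))
  vapply(window, function(w) {
    check_window(w)
    flanks <- stats::setNames(strsplit(w, "")[[1]][-4],
                              c(-3, -2, -1, 1, 2, 3))
    if ("C" %in% flanks) {
      stop("scoring refused: motif contains cysteine (contains_C)")
    }
    if (any(!flanks %in% profile$alphabet)) {
      stop("scoring refused: motif residue outside profile alphabet ",
           "(ambiguous_residue)")
    }
    # pair each profile row with the window residue at that row's offset
    min(profile$raw[cbind(position_label(profile$positions),
                          flanks[as.character(profile$positions)])])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score and rank every lysine-centered motif in a proteome
#'
#' Extracts motifs with [extract_motifs()], scores the non-excluded ones with
#' [lob_score()], normalizes by the highest score in the scan, and ranks by
#' descending score. Tied motifs share the minimum rank; rows are ordered by
#' rank, then protein id, then position, so output is reproducible regardless
#' of input record order.
#'
#' @param profile a [kme_profile()].
#' @param proteome see [extract_motifs()].
#' @return data.frame with columns `protein_id`, `k_position`, `window`,
#'   `lob_score`, `norm_score`, `rank`, `excluded`, `reason`; excluded motifs
#'   carry `NA` scores and ranks.
#' @export
score_proteome <- function(profile, proteome) {
  stopifnot(inherits(profile, "kme_profile"))
  if (profile$no_binding || max(profile$raw) == 0) {
    stop("ranking refused: no binding signal (profile is all zeros)")
  }
  motifs <- extract_motifs(proteome)
  motifs$lob_score <- NA_real_
  scored <- !motifs$excluded
  if (any(scored)) {
    motifs$lob_score[scored] <- lob_score(profile, motifs$window[scored])
  }
  mx <- if (any(scored)) max(motifs$lob_score[scored]) else NA_real_
  motifs$norm_score <- if (isTRUE(mx > 0)) motifs$lob_score / mx
                       else motifs$lob_score * 0
  motifs$rank <- NA_integer_
  if (any(scored)) {
    sc <- motifs$lob_score[scored]
    # min rank for ties: 1 + number of strictly greater scores
    motifs$rank[scored] <- as.integer(
      rank(-sc, ties.method = "min"))
  }
  rank_key <- ifelse(is.na(motifs$rank), Inf, motifs$rank)
  ord <- order(!scored, rank_key, motifs$protein_id, motifs$k_position)
  out <- motifs[ord, c("protein_id", "k_position", "window", "lob_score",
                       "norm_score", "rank", "excluded", "reason")]
  rownames(out) <- NULL
  out
}

# argmax/argmin residues per profile position with full tie sets
position_extreme <- function(profile, which = c("max", "min")) {
  which <- match.arg(which)
  lapply(seq_along(profile$positions), function(i) {
    row <- profile$raw[i, ]
    target <- if (which == "max") max(row) else min(row)
    ties <- sort(names(row)[row == target])
    list(offset = profile$positions[i], residues = ties,
         unconstrained = length(unique(row)) == 1L ||
           (which == "max" && target == 0))
  })
}

# assemble a seven-mer from per-position residue choices (central K)
assemble_window <- function(choices) {
  offs <- vapply(choices, function(p) p$offset, numeric(1))
  res <- vapply(choices, function(p) p$residues[1], character(1))[order(offs)]
  paste0(paste(res[1:3], collapse = ""), "K", paste(res[4:6], collapse = ""))
}

#' Predict the optimal binding seven-mer from a profile
#'
#' Chooses, at each flanking position, the residue of the set with the
#' highest raw signal (central residue is the methylated K). Ties are
#' reported exhaustively; the primary answer takes the lexicographically
#' smallest residue at each tied position. An all-zero column is reported as
#' unconstrained.
#'
#' @param profile a [kme_profile()].
#' @return List of class `kme_prediction`: `window` (7-character string),
#'   `per_position` (offset, tied residues, unconstrained flag), `type`.
#' @export
predict_optimal_sequence <- function(profile) {
  stopifnot(inherits(profile, "kme_profile"))
  choices <- position_extreme(profile, "max")
  structure(list(window = assemble_window(choices), per_position = choices,
                 type = "optimal", methyl_order = profile$methyl_order),
            class = "kme_prediction")
}

#' Predict a poor binding seven-mer from a profile
#'
#' As [predict_optimal_sequence()] but taking the lowest-signal set at each
#' position.
#'
#' @inheritParams predict_optimal_sequence
#' @return List of class `kme_prediction`.
#' @export
predict_worst_sequence <- function(profile) {
  stopifnot(inherits(profile, "kme_profile"))
  choices <- position_extreme(profile, "min")
  structure(list(window = assemble_window(choices), per_position = choices,
                 type = "worst", methyl_order = profile$methyl_order),
            class = "kme_prediction")
}

#' @export
print.kme_prediction <- function(x, ...) {
  w <- x$window
  cat(sprintf("Predicted %s binding sequence: %s(Kme%d)%s\n", x$type,
              substr(w, 1, 3), x$methyl_order, substr(w, 5, 7)))
  for (p in x$per_position) {
    extra <- if (p$unconstrained) " (unconstrained)"
             else if (length(p$residues) > 1)
               sprintf(" (ties: %s)", paste(p$residues, collapse = ","))
             else ""
    cat(sprintf("  P%+d: %s%s\n", p$offset, p$residues[1], extra))
  }
  invisible(x)
}

#' Count motifs scoring at or above a reference motif
#'
#' How many proteome motifs have a LoB score greater than or equal to the
#' reference motif's score, excluding the reference itself — e.g. how many
#' seven-mers an antibody is predicted to bind as well as its intended
#' histone target.
#'
#' @param results a [score_proteome()] table.
#' @param protein_id,k_position identify the reference motif in `results`.
#' @return Integer count.
#' @export
count_at_or_above <- function(results, protein_id, k_position) {
  hit <- results$protein_id == protein_id & results$k_position == k_position
  if (!any(hit)) stop("reference motif not found in results")
  ref <- results$lob_score[hit][1]
  if (is.na(ref)) stop("reference motif was excluded from scoring")
  sum(results$lob_score >= ref, na.rm = TRUE) - 1L
}

#' Read a protein copy-number table
#'
#' @param path TSV with columns `protein_id`, `copy_number`
#'   (particles/cell), `sd`.
#' @return data.frame.
#' @export
read_abundance <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "copy_number") %in% names(tab)))
  if (any(tab$copy_number <= 0)) stop("copy numbers must be positive")
  tab
}

#' Annotate LoB results with protein abundance
#'
#' Joins per-cell copy numbers onto the scored motifs and computes, for each
#' protein, how many times more abundant a reference protein (typically a
#' histone) is: `fold_abundance = copy_number(reference) /
#' copy_number(protein)`. A high-scoring motif on a protein that is orders of
#' magnitude less abundant than histones may never be detected in cells even
#' if it binds as tightly.
#'
#' @param results a [score_proteome()] table (or any data.frame with a
#'   `protein_id` column).
#' @param abundance data.frame with `protein_id`, `copy_number`, optional
#'   `sd` (see [read_abundance()]).
#' @param reference_protein id of the reference protein; must be present in
#'   `abundance`.
#' @return `results` with added columns `copy_number`, `fold_abundance`, and
#'   `abundance_missing` (TRUE where the protein has no abundance record).
#' @export
annotate_with_abundance <- function(results, abundance, reference_protein) {
  i <- match(reference_protein, abundance$protein_id)
  if (is.na(i)) stop("reference protein not found in abundance table")
  ref_copies <- abundance$copy_number[i]
  j <- match(results$protein_id, abundance$protein_id)
  results$copy_number <- abundance$copy_number[j]
  results$fold_abundance <- ref_copies / results$copy_number
  results$abundance_missing <- is.na(j)
  results
}

#' Write scored motifs to TSV
#'
#' @param results a [score_proteome()] (optionally abundance-annotated) table.
#' @param path output TSV path.
#' @export
write_lob_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}
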