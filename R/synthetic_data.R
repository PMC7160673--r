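#' Latent reader model for plate simulation
#'
#' Binding of a reader to a degenerate peptide is modeled as independent
#' multiplicative occupancy per position: a peptide with residues r_q at the
#' six flanks binds proportionally to the product of position weights
#' `w(q, r_q)` in (0, 1], times a methyl-order weight (1 for the preferred
#' order), times a maximum signal S0. Signals from an equimolar mixture are
#' then averages of this product over the degenerate positions, which gives
#' closed-form set and pool expectations ([expected_set_signal()],
#' [expected_pool_signal()]).
#'
#' @param preferred_order methyl order with order weight 1.
#' @param order_weights numeric length 4 (Kme0..Kme3), each in [0, 1], with
#'   the preferred order at 1.
#' @param position_weights positions x residues matrix of weights in (0, 1];
#'   rows named `"P-3"` ... `"P+3"`, columns the residue alphabet. Defaults
#'   to a near one-hot matrix (a sequence-specific reader).
#' @param hot_residues used only to build the default `position_weights`:
#'   the favored residue at each of the six positions.
#' @param epsilon weight of non-favored residues in the default matrix.
#'   Note that under the multiplicative mixture model, set expectations scale
#'   with the fifth power of the mean position weight, so sharp (small
#'   epsilon) models need a much larger `S0` than promiscuous ones to yield
#'   set signals of comparable magnitude; see [s0_for_best_set()].
#' @param S0 maximum signal (RFU) of a fully favored peptide.
#' @param gst_background mean GST-control well signal (RFU).
#' @param noise_sd Gaussian well noise SD (RFU).
#' @param reader_id identifier stamped on simulated plates.
#' @param alphabet,positions library geometry.
#' @return Object of class `latent_reader_model`.
#' @export
latent_reader_model <- function(preferred_order = 3L,
                                order_weights = NULL,
                                position_weights = NULL,
                                hot_residues = c("K", "A", "K", "T", "G", "K"),
                                epsilon = 0.8,
                                S0 = 2000, gst_background = 150,
                                noise_sd = 50,
                                reader_id = "synthetic_reader",
                                alphabet = kme_alphabet(),
                                positions = kme_positions()) {
  if (is.null(order_weights)) {
    # methyl-dependent reader: near-zero on Kme0, ramping to the preferred
    order_weights <- if (preferred_order == 3L) c(0.02, 0.05, 0.25, 1) else {
      ow <- rep(0.05, 4)
      ow[preferred_order + 1L] <- 1
      ow
    }
  }
  stopifnot(length(order_weights) == 4, all(order_weights >= 0),
            all(order_weights <= 1),
            order_weights[preferred_order + 1L] == 1)
  if (is.null(position_weights)) {
    stopifnot(length(hot_residues) == length(positions),
              all(hot_residues %in% alphabet), epsilon > 0, epsilon <= 1)
    position_weights <- matrix(epsilon, nrow = length(positions),
                               ncol = length(alphabet),
                               dimnames = list(position_label(positions),
                                               alphabet))
    for (i in seq_along(positions)) {
      position_weights[i, hot_residues[i]] <- 1
    }
  }
  stopifnot(is.matrix(position_weights),
            nrow(position_weights) == length(positions),
            ncol(position_weights) == length(alphabet),
            all(position_weights > 0), all(position_weights <= 1),
            S0 > 0, noise_sd >= 0, gst_background >= 0)
  rownames(position_weights) <- position_label(positions)
  colnames(position_weights) <- alphabet
  structure(list(preferred_order = as.integer(preferred_order),
                 order_weights = order_weights,
                 position_weights = position_weights,
                 S0 = S0, gst_background = gst_background,
                 noise_sd = noise_sd, reader_id = reader_id,
                 alphabet = alphabet, positions = positions),
            class = "latent_reader_model")
}

#' @export
print.latent_reader_model <- function(x, ...) {
  cat(sprintf("Latent reader model '%s': preferred Kme%d, S0 = %.0f RFU\n",
              x$reader_id, x$preferred_order, x$S0))
  cat(sprintf("  GST background %.0f RFU, noise SD %.0f RFU\n",
              x$gst_background, x$noise_sd))
  invisible(x)
}

#' Maximum signal giving a target best-set expectation
#'
#' Under the mixture model a sequence-specific (sharp) weight matrix dilutes
#' every set's signal by the product of the free positions' mean weights, so
#' the latent `S0` consistent with observed set signals of a given magnitude
#' grows as that product shrinks. Returns the `S0` for which the highest set
#' expectation of the preferred order equals `best_set_rfu`.
#'
#' @param position_weights positions x residues weight matrix in (0, 1].
#' @param best_set_rfu desired expectation (RFU) of the best set.
#' @return `S0` value to pass to [latent_reader_model()].
#' @export
s0_for_best_set <- function(position_weights, best_set_rfu = 1000) {
  means <- rowMeans(position_weights)
  best <- max(vapply(seq_len(nrow(position_weights)), function(i) {
    max(position_weights[i, ]) * prod(means[-i])
  }, numeric(1)))
  best_set_rfu / best
}

#' Closed-form expected signal of a Kme-OPL set
#'
#' For the equimolar mixture of a set fixing residue `a` at position `p`:
#' `E = S0 * order_weight * w(p, a) * prod over the other five flanks of
#' mean_r w(q, r)`.
#'
#' @param model a [latent_reader_model()].
#' @param methyl_order methyl order of the set.
#' @param fixed_position,fixed_residue the set definition.
#' @return Expected fluorescence (RFU), excluding GST background.
#' @export
expected_set_signal <- function(model, methyl_order, fixed_position,
                                fixed_residue) {
  w <- model$position_weights
  p <- position_label(fixed_position)
  other <- setdiff(rownames(w), p)
  model$S0 * model$order_weights[methyl_order + 1L] *
    w[p, fixed_residue] * prod(rowMeans(w)[other])
}

#' Closed-form expected signal of a Kme-OPL pool
#'
#' The pool combines all sets of one methyl order, i.e. the fully degenerate
#' mixture: `E = S0 * order_weight * prod over all six flanks of
#' mean_r w(q, r)`. Sequence-specific readers (near one-hot weights) have
#' pool expectations orders of magnitude below their best set — their
#' favored peptides are diluted in the pool — while promiscuous readers
#' (uniform weights near 1) approach S0.
#'
#' @param model a [latent_reader_model()].
#' @param methyl_order methyl order of the pool.
#' @return Expected fluorescence (RFU), excluding GST background.
#' @export
expected_pool_signal <- function(model, methyl_order) {
  model$S0 * model$order_weights[methyl_order + 1L] *
    prod(rowMeans(model$position_weights))
}

#' Noise-free profile of a latent model
#'
#' The reader profile a perfect, noise-free assay would measure: the matrix
#' of closed-form set expectations for one methyl order. Useful as the oracle
#' against which [build_profile()] on simulated plates is compared.
#'
#' @param model a [latent_reader_model()].
#' @param methyl_order methyl order (default the model's preferred order).
#' @return A [kme_profile()].
#' @export
expected_profile <- function(model, methyl_order = model$preferred_order) {
  raw <- model$position_weights * 0
  for (p in model$positions) {
    for (a in model$alphabet) {
      raw[position_label(p), a] <-
        expected_set_signal(model, methyl_order, p, a)
    }
  }
  kme_profile(raw, model$reader_id, methyl_order,
              background = "noise-free expectation")
}

#' Simulate a full assay plate
#'
#' Generates reader and matched GST wells for all sets of all four methyl
#' orders plus the four pools, with `n_replicates` each. Well signal =
#' closed-form expectation + GST background + Gaussian noise, truncated at
#' zero; GST wells carry background + noise. Bit-reproducible from the seed.
#'
#' @param model a [latent_reader_model()].
#' @param n_replicates replicate wells per set/pool.
#' @param seed integer RNG seed.
#' @param methyl_orders orders to simulate (default all four).
#' @return Plate data.frame in the dialect [build_profile()] reads.
#' @export
simulate_plate <- function(model, n_replicates = 4L, seed = 1L,
                           methyl_orders = kme_orders()) {
  stopifnot(n_replicates >= 1)
  sets <- do.call(rbind, lapply(methyl_orders, enumerate_sets,
                                alphabet = model$alphabet,
                                positions = model$positions))
  mu_set <- mapply(expected_set_signal,
                   methyl_order = sets$methyl_order,
                   fixed_position = sets$fixed_position,
                   fixed_residue = sets$fixed_residue,
                   MoreArgs = list(model = model))
  pools <- data.frame(methyl_order = methyl_orders)
  mu_pool <- vapply(pools$methyl_order, expected_pool_signal,
                    numeric(1), model = model)

  mu <- c(rep(mu_set, each = n_replicates), rep(mu_pool, each = n_replicates))
  n_wells <- length(mu)
  noise <- with_seed(seed, stats::rnorm(2 * n_wells, 0, model$noise_sd))
  noise_r <- noise[seq_len(n_wells)]
  noise_g <- noise[n_wells + seq_len(n_wells)]

  signal <- pmax(mu + model$gst_background + noise_r, 0)
  gst <- pmax(model$gst_background + noise_g, 0)

  plate <- data.frame(
    reader_id = model$reader_id,
    methyl_order = c(rep(sets$methyl_order, each = n_replicates),
                     rep(pools$methyl_order, each = n_replicates)),
    fixed_position = c(rep(sets$fixed_position, each = n_replicates),
                       rep(NA_integer_, length(methyl_orders) * n_replicates)),
    fixed_residue = c(rep(sets$fixed_residue, each = n_replicates),
                      rep(NA_character_, length(methyl_orders) * n_replicates)),
    pool = c(rep(FALSE, nrow(sets) * n_replicates),
             rep(TRUE, length(methyl_orders) * n_replicates)),
    replicate = rep(seq_len(n_replicates),
                    times = nrow(sets) + length(methyl_orders)),
    signal = signal,
    gst_signal = gst,
    stringsAsFactors = FALSE
  )
  plate
}

#' Generate a synthetic proteome with planted motifs
#'
#' Random protein sequences drawn from given residue frequencies, with
#' chosen seven-mer motifs (central K) planted at recorded positions at
#' least three residues from either terminus. A manifest of ground-truth
#' plant locations is returned alongside the records.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of protein lengths (uniform draw).
#' @param residue_freqs named numeric vector of residue frequencies over the
#'   20 standard amino acids (default uniform); normalized internally.
#' @param planted_motifs character vector of seven-mer windows (central
#'   `"K"`) to plant, one per randomly chosen distinct protein.
#' @param seed integer RNG seed.
#' @return List with `records` (named character vector of sequences) and
#'   `manifest` (data.frame `protein_id`, `k_position`, `window`).
#' @export
generate_proteome <- function(n_proteins = 100L,
                              length_range = c(150L, 400L),
                              residue_freqs = NULL,
                              planted_motifs = character(0),
                              seed = 1L) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(residue_freqs)) {
    residue_freqs <- stats::setNames(rep(1 / 20, 20), aas)
  }
  residue_freqs <- residue_freqs / sum(residue_freqs)
  if (length(planted_motifs) > n_proteins) {
    stop("more planted motifs than proteins")
  }
  for (w in planted_motifs) check_window(w)

  with_seed(seed, {
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  records <- vapply(lens, function(L) {
    paste(sample(names(residue_freqs), L, replace = TRUE,
                 prob = residue_freqs), collapse = "")
  }, character(1))
  names(records) <- sprintf("synthetic_%03d", seq_len(n_proteins))

  manifest <- NULL
  if (length(planted_motifs) > 0) {
    hosts <- sample(n_proteins, length(planted_motifs))
    manifest <- do.call(rbind, lapply(seq_along(planted_motifs), function(i) {
      host <- hosts[i]
      L <- lens[host]
      start <- sample(seq(4L, L - 9L), 1) # window occupies start..start+6
      s <- records[[host]]
      records[[host]] <<- paste0(substr(s, 1, start - 1), planted_motifs[i],
                                 substr(s, start + 7L, L))
      data.frame(protein_id = names(records)[host],
                 k_position = start + 3L,
                 window = planted_motifs[i], stringsAsFactors = FALSE)
    }))
  } else {
    manifest <- data.frame(protein_id = character(0), k_position = integer(0),
                           window = character(0))
  }
  list(records = records, manifest = manifest)
  })
}

#' Write proteome records to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_proteome_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(aa, path)
  invisible(records)
}

#' Simulate a fluorescence-polarization titration
#'
#' Generates anisotropy from the specific-binding-with-Hill-slope model,
#' adds seeded Gaussian noise, and converts to milli-polarization via
#' `P = 3A / (2 + A)` so the series looks like plate-reader output.
#'
#' @param kd dissociation constant (uM, > 0).
#' @param hill Hill coefficient (> 0).
#' @param amax saturating anisotropy (> 0).
#' @param baseline zero-binding anisotropy.
#' @param concentrations protein concentrations (uM); default a 12-point
#'   serial dilution spanning 0.01-100 uM around typical reader Kds.
#' @param noise_sd Gaussian anisotropy noise SD.
#' @param seed integer RNG seed.
#' @param peptide_id identifier column value.
#' @return data.frame `peptide_id`, `concentration_uM`, `mP`, `anisotropy`.
#' @export
simulate_fp_titration <- function(kd, hill = 1, amax = 0.1, baseline = 0,
                                  concentrations =
                                    100 / 2.3^(0:11),
                                  noise_sd = 0, seed = 1L,
                                  peptide_id = "synthetic_peptide") {
  stopifnot(kd > 0, hill > 0, amax > 0, all(concentrations > 0))
  mu <- hill_model(concentrations, kd, hill, amax, baseline)
  A <- mu + with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  data.frame(peptide_id = peptide_id,
             concentration_uM = concentrations,
             mP = anisotropy_to_polarization(A, mP = TRUE),
             anisotropy = A,
             stringsAsFactors = FALSE)
}

#' Read a latent-model configuration from YAML
#'
#' Accepts keys matching [latent_reader_model()] arguments
#' (`preferred_order`, `order_weights`, `hot_residues`, `epsilon`, `S0`,
#' `gst_background`, `noise_sd`, `reader_id`) plus optional `seed` and
#' `n_replicates` returned alongside.
#'
#' @param path YAML file path.
#' @return List with `model` (a [latent_reader_model()]), `seed`,
#'   `n_replicates`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        names(formals(latent_reader_model)))]
  model <- do.call(latent_reader_model, args)
  list(model = model,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       n_replicates = if (is.null(cfg$n_replicates)) 4L
                      else as.integer(cfg$n_replicates))
}
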