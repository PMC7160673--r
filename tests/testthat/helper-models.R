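# Shared fixtures, all built in code.

# Sequence-specific reader: one-hot weights spelling KAK(K)TGK, S0 scaled so
# the best set expectation sits at 1000 RFU despite mixture dilution.
specific_model <- function(epsilon = 0.05, noise_sd = 50,
                           hot = c("K", "A", "K", "T", "G", "K")) {
  w <- matrix(epsilon, 6, 19,
              dimnames = list(sprintf("P%+d", c(-3, -2, -1, 1, 2, 3)),
                              kme_alphabet()))
  for (i in 1:6) w[i, hot[i]] <- 1
  latent_reader_model(position_weights = w,
                      S0 = s0_for_best_set(w, 1000),
                      noise_sd = noise_sd)
}

# Small profile over a 3-letter alphabet for brute-force comparisons.
toy_profile <- function(values = NULL, alphabet = c("A", "G", "S")) {
  pos <- c(-3, -2, -1, 1, 2, 3)
  if (is.null(values)) {
    values <- matrix(seq_len(6 * length(alphabet)), 6, length(alphabet))
  }
  dimnames(values) <- list(sprintf("P%+d", pos), alphabet)
  kme_profile(values, "toy", 3L)
}

# Independent brute-force LoB: six explicit lookups, minimum by hand.
brute_lob <- function(raw, window) {
  chars <- strsplit(window, "")[[1]]
  offsets <- c(-3, -2, -1, 1, 2, 3)
  vals <- numeric(6)
  for (i in 1:6) {
    vals[i] <- raw[sprintf("P%+d", offsets[i]), chars[offsets[i] + 4]]
  }
  min(vals)
}

# Random cysteine-free seven-mer over a given alphabet.
random_window <- function(alphabet = kme_alphabet()) {
  f <- sample(alphabet, 6, replace = TRUE)
  paste0(paste(f[1:3], collapse = ""), "K", paste(f[4:6], collapse = ""))
}
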