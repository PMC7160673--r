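test_that("motif extraction handles termini, flanking K's and exclusions", {
  m <- extract_motifs(c(p1 = "GGGKGGG"))
  expect_equal(nrow(m), 1)
  expect_equal(m$window, "GGGKGGG")
  expect_equal(m$k_position, 4L)
  expect_false(m$excluded)

  m2 <- extract_motifs(c(p2 = "KAAAA"))
  expect_equal(sum(!m2$excluded), 0)
  expect_equal(m2$reason, "near_terminus")

  m3 <- extract_motifs(c(p3 = "GGKKGGG"))
  expect_equal(m3$reason[m3$k_position == 3], "near_terminus")
  row4 <- m3[m3$k_position == 4, ]
  expect_false(row4$excluded)
  expect_equal(substr(row4$window, 3, 3), "K") # flanking K at offset -1

  m4 <- extract_motifs(c(p4 = "GGCKGGGXKGGG"))
  expect_equal(m4$reason[m4$k_position == 4], "contains_C")
  expect_equal(m4$reason[m4$k_position == 9], "ambiguous_residue")
  expect_warning(extract_motifs(character(0)), "empty proteome")
})

test_that("LoB score equals the brute-force minimum of six lookups", {
  prof <- toy_profile()
  set.seed(21)
  for (i in 1:10) {
    w <- random_window(prof$alphabet)
    expect_equal(lob_score(prof, w), brute_lob(prof$raw, w))
  }
  # constant profile scores every motif the same
  flat <- toy_profile(matrix(7.5, 6, 3))
  expect_equal(lob_score(flat, "AGSKSGA"), 7.5)
  # a zero cell dominates any motif passing through it
  z <- prof$raw
  z["P+2", "A"] <- 0
  zprof <- toy_profile(z)
  expect_equal(lob_score(zprof, "GGGKGAG"), 0)
  # scoring refused for excluded motifs
  expect_error(lob_score(prof, "CGGKGGG"), "cysteine")
  expect_error(lob_score(toy_profile(), "BGGKGGG"), "alphabet")
})

test_that("LoB min property holds with equality at some position", {
  prof <- toy_profile(matrix(runif(18, 0, 100), 6, 3))
  set.seed(33)
  for (i in 1:20) {
    w <- random_window(prof$alphabet)
    chars <- strsplit(w, "")[[1]][-4]
    lookups <- prof$raw[cbind(sprintf("P%+d", c(-3, -2, -1, 1, 2, 3)), chars)]
    s <- lob_score(prof, w)
    expect_true(all(s <= lookups))
    expect_true(any(s == lookups))
  }
})

test_that("raising a single profile cell never decreases any score", {
  set.seed(44)
  prof <- toy_profile(matrix(runif(18, 0, 100), 6, 3))
  windows <- replicate(30, random_window(prof$alphabet))
  before <- lob_score(prof, windows)
  raised <- prof$raw
  raised["P-1", "G"] <- raised["P-1", "G"] + 50
  after <- lob_score(toy_profile(raised), windows)
  expect_true(all(after >= before))
})

test_that("proteome scoring normalizes, ranks with min-rank ties, and is order-invariant", {
  prof <- toy_profile(matrix(c(1:6, 7:12, 13:18), 6, 3))
  prot <- c(a = "AAAKAAAGAGASKSGSAAA", b = "SSSKSSS", c = "GAGKGAG")
  res <- score_proteome(prof, prot)
  expect_equal(max(res$norm_score, na.rm = TRUE), 1)
  expect_equal(res$rank[1], 1L)
  expect_true(all(diff(res$rank[!res$excluded]) >= 0))
  # min-rank ties: k tied motifs at the top all get rank 1, next gets k+1
  tied <- res[!res$excluded, ]
  for (r in unique(tied$rank)) {
    expect_equal(r, sum(tied$lob_score > tied$lob_score[tied$rank == r][1]) + 1)
  }
  # permuting the record order leaves the table unchanged
  res2 <- score_proteome(prof, prot[c(3, 1, 2)])
  expect_equal(res2, res)

  # scale invariance: normalized profile gives identical rankings
  resn <- score_proteome(kme_profile(prof$norm, "toy", 3), prot)
  expect_equal(resn$rank, res$rank)
  expect_equal(resn$norm_score, res$norm_score, tolerance = 1e-12)

  expect_error(score_proteome(toy_profile(matrix(0, 6, 3)), prot),
               "no binding signal")
})

test_that("optimal and worst sequence predictions are per-position extremes", {
  # unique maxima spelling GAG(K)STG over alphabet {A,G,S,T}
  vals <- matrix(1, 6, 4, dimnames = list(sprintf("P%+d", c(-3, -2, -1, 1, 2, 3)),
                                          c("A", "G", "S", "T")))
  vals["P-3", "G"] <- 9; vals["P-2", "A"] <- 9; vals["P-1", "G"] <- 9
  vals["P+1", "S"] <- 9; vals["P+2", "T"] <- 9; vals["P+3", "G"] <- 9
  prof <- kme_profile(vals, "toy", 3)
  expect_equal(predict_optimal_sequence(prof)$window, "GAGKSTG")

  # worst: argmin verified by exhaustive lookup over all 4^6 windows
  worst <- predict_worst_sequence(prof)$window
  grid <- expand.grid(rep(list(c("A", "G", "S", "T")), 6),
                      stringsAsFactors = FALSE)
  all_windows <- apply(grid, 1, function(r)
    paste0(paste(r[1:3], collapse = ""), "K", paste(r[4:6], collapse = "")))
  all_scores <- vapply(all_windows, function(w) brute_lob(vals, w), numeric(1))
  expect_equal(lob_score(prof, worst), min(all_scores))

  # ties resolved lexicographically and reported exhaustively
  tie <- vals
  tie["P-3", "A"] <- 9 # A and G now tie at P-3
  ptie <- predict_optimal_sequence(kme_profile(tie, "toy", 3))
  expect_equal(substr(ptie$window, 1, 1), "A")
  expect_equal(ptie$per_position[[1]]$residues, c("A", "G"))

  # uniform profile: every position unconstrained
  flat <- predict_optimal_sequence(toy_profile(matrix(3, 6, 3)))
  expect_true(all(vapply(flat$per_position, `[[`, logical(1),
                         "unconstrained")))
})

test_that("count_at_or_above matches exhaustive comparison and excludes the reference", {
  set.seed(55)
  prof <- toy_profile(matrix(runif(18, 1, 100), 6, 3))
  # sequences over the toy alphabet with isolated central lysines
  prot <- stats::setNames(replicate(4, {
    chars <- sample(c("A", "G", "S"), 60, replace = TRUE)
    chars[seq(5, 55, by = 8)] <- "K"
    paste(chars, collapse = "")
  }), paste0("p", 1:4))
  res <- score_proteome(prof, prot)
  scored <- res[!res$excluded, ]
  top <- scored[scored$rank == 1, ][1, ]
  n_top <- count_at_or_above(res, top$protein_id, top$k_position)
  expect_equal(n_top, sum(scored$lob_score >= top$lob_score) - 1)

  ref <- scored[ceiling(nrow(scored) / 2), ]
  expect_equal(count_at_or_above(res, ref$protein_id, ref$k_position),
               sum(scored$lob_score >= ref$lob_score) - 1)

  # uniform profile: everything ties
  flat <- score_proteome(toy_profile(matrix(2, 6, 3)),
                         c(q = "AAAKAAAGGGKGGGA"))
  fs <- flat[!flat$excluded, ]
  expect_equal(count_at_or_above(flat, fs$protein_id[1], fs$k_position[1]),
               nrow(fs) - 1)
  expect_error(count_at_or_above(res, "absent", 99), "not found")
})

test_that("abundance annotation reproduces fold ratios and flags gaps", {
  abund <- data.frame(protein_id = c("H3-1", "SFXN4"),
                      copy_number = c(33e6, 29e3), sd = c(4.3e6, 6.5e3))
  res <- data.frame(protein_id = c("SFXN4", "H3-1", "NOPE"),
                    k_position = c(10L, 4L, 7L))
  ann <- annotate_with_abundance(res, abund, "H3-1")
  expect_equal(signif(ann$fold_abundance[1], 2), 1100)
  expect_equal(ann$fold_abundance[2], 1.0)
  expect_true(ann$abundance_missing[3])
  expect_true(is.na(ann$fold_abundance[3]))
  expect_error(annotate_with_abundance(res, abund, "H2B"), "reference")
})

test_that("FASTA and TSV I/O round-trips proteomes and results", {
  pr <- generate_proteome(5, length_range = c(40L, 60L),
                          planted_motifs = "KAKKTGK", seed = 9)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(pr$records, fa)
  back <- read_proteome_fasta(fa)
  expect_equal(back, pr$records)

  res <- score_proteome(toy_profile(matrix(1:18, 6, 3)),
                        c(x = "AAAKAAAGGGKGGGA"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_lob_results(res, out)
  expect_equal(read.delim(out)$lob_score, res$lob_score)
})
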