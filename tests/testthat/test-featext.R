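test_that("positional one-hot encoding marks exactly the observed residues", {
  v <- encode_positional_identity("MKS")
  expect_equal(sum(v), 3)
  expect_equal(v[["aa_identity[-1][M]"]], 1)
  expect_equal(v[["aa_identity[0][K]"]], 1)
  expect_equal(v[["aa_identity[+1][S]"]], 1)

  v2 <- encode_positional_identity("-KS")
  expect_equal(sum(v2[grepl("\\[-1\\]", names(v2))]), 0)
  expect_equal(sum(v2), 2)

  # sum equals the number of non-gap positions, X counts as no residue
  v3 <- encode_positional_identity("XK-")
  expect_equal(sum(v3), 1)
})

test_that("group encoding follows the reduced alphabet", {
  v <- encode_positional_groups("IVL")
  expect_equal(v[["aa_group[-1][IVLM]"]], 1)
  expect_equal(v[["aa_group[0][IVLM]"]], 1)
  expect_equal(v[["aa_group[+1][IVLM]"]], 1)

  v2 <- encode_positional_groups("-K-")
  expect_equal(sum(v2), 1) # only center K -> RKH
  expect_equal(v2[["aa_group[0][RKH]"]], 1)
  # per-position sums never exceed 1
  for (p in c("[-1]", "[0]", "[+1]")) {
    expect_lte(sum(v2[grepl(p, names(v2), fixed = TRUE)]), 1)
  }
})

test_that("composition counts cover non-gap symbols consistently", {
  v <- composition_counts("MKS")
  expect_equal(v[["aa_count[M]"]], 1)
  expect_equal(v[["aa_count[K]"]], 1)
  expect_equal(v[["aa_count[S]"]], 1)
  expect_equal(sum(v[startsWith(names(v), "aa_count")]), 3)
  expect_equal(sum(v[startsWith(names(v), "group_count")]), 3)

  v2 <- composition_counts("--K--")
  expect_equal(sum(v2[startsWith(names(v2), "aa_count")]), 1)

  # grouped count equals the sum of member counts
  v3 <- composition_counts("IVKML")
  expect_equal(
    v3[["group_count[IVLM]"]],
    sum(v3[c("aa_count[I]", "aa_count[V]", "aa_count[L]", "aa_count[M]")])
  )
})

test_that("composition ratios compare window and protein frequencies", {
  v <- composition_ratio("AKA", "AAAAKAAAAA")
  expect_equal(v[["aa_ratio[K]"]], (1 / 3) / (1 / 10))
  expect_equal(v[["aa_ratio[A]"]], (2 / 3) / (9 / 10))
  expect_equal(v[["aa_ratio[W]"]], 0) # absent from protein

  v2 <- composition_ratio("AAA", "AAAA")
  expect_equal(v2[["aa_ratio[A]"]], 1)
  # absent from window but present in protein -> 0
  v3 <- composition_ratio("AKA", "AKAW")
  expect_equal(v3[["aa_ratio[W]"]], 0)
})

test_that("PSSM window features pull matrix rows with gap zero-fill", {
  m <- matrix(0, 5, 20, dimnames = list(NULL, neddly:::AA_LETTERS))
  expect_true(all(pssm_window_features(m, 3, 2) == 0))

  m[2, "K"] <- 7
  v <- pssm_window_features(m, 3, 2)
  expect_equal(v[["pssm[-1][K]"]], 7)

  # window at sequence start: upstream rows are zero
  v2 <- pssm_window_features(m, 1, 2)
  expect_true(all(v2[grepl("\\[-1\\]|\\[-2\\]", names(v2))] == 0))
  expect_equal(v2[["pssm[+1][K]"]], 7)
})

test_that("secondary-structure terminus flag follows the 15% rule", {
  # 10-residue helix inside coil
  states <- c(rep("C", 3), rep("H", 10), rep("C", 5))
  helix_start <- 4L
  for (pos_in_el in 1:10) {
    v <- ss_features(states, helix_start + pos_in_el - 1L)
    expect_equal(unname(v["ss_H"]), 1)
    expect_equal(unname(v["ss_terminus"]),
                 ss_terminus_oracle(10, pos_in_el),
                 label = paste("helix position", pos_in_el))
  }
  # ceil(1.5) = 2 -> offsets 0 and 1 qualify
  expect_equal(unname(ss_features(states, helix_start)["ss_terminus"]), 1)
  expect_equal(unname(ss_features(states, helix_start + 4L)["ss_terminus"]),
               0)
  # single-residue element is all terminus
  v1 <- ss_features(c("C", "E", "C"), 2)
  expect_equal(unname(v1["ss_E"]), 1)
  expect_equal(unname(v1["ss_terminus"]), 1)
})

test_that("solvent accessibility is a passthrough of the central call", {
  expect_equal(unname(solvent_accessibility_feature(c(0L, 1L, 0L), 2)), 1)
  expect_equal(unname(solvent_accessibility_feature(c(1L, 0L), 2)), 0)
  expect_error(solvent_accessibility_feature(c(1L, 0L), 5), "no accessibility")
})

test_that("flexibility features implement the confidence-ratio rule", {
  prof <- tibble::tibble(
    position = 1:5, residue = "A",
    call = rep("F", 5), confidence = rep(0.5, 5)
  )
  v <- flexibility_features(prof, 3, 2)
  expect_equal(unname(v), c(1, 1))

  # equal confidence sums: ratio exactly 1 still satisfies >= 1
  prof2 <- tibble::tibble(
    position = 1:4, residue = "A",
    call = c("F", "F", "R", "R"), confidence = c(2, 2, 2, 2)
  )
  expect_equal(unname(flexibility_features(prof2, 2, 2)["conf_rat"]), 1)

  # 2 weak flexible vs 5 strong rigid
  prof3 <- tibble::tibble(
    position = 1:7, residue = "A",
    call = c("F", "F", rep("R", 5)),
    confidence = c(0.1, 0.1, rep(1, 5))
  )
  v3 <- flexibility_features(prof3, 4, 3)
  expect_equal(unname(v3), c(0, 0))

  # randomized profiles against the direct oracle
  for (s in 1:50) {
    neddly:::with_local_seed(1000 + s, {
      L <- sample(5:15, 1)
      calls <- sample(c("F", "R"), L, replace = TRUE)
      conf <- round(stats::runif(L), 3)
    })
    prof <- tibble::tibble(position = seq_len(L), residue = "A",
                           call = calls, confidence = conf)
    got <- flexibility_features(prof, center = (L + 1) %/% 2, n = L)
    expect_equal(unname(got["conf_rat"]), conf_rat_oracle(calls, conf),
                 label = paste("profile", s))
  }
})

test_that("disorder features use an inclusive 0.5 cutoff on the mean", {
  prof <- function(x) tibble::tibble(position = seq_along(x), residue = "A",
                                     tendency = x)
  expect_equal(unname(disorder_features(prof(rep(0.6, 5)), 3, 2)),
               c(0.6, 1))
  expect_equal(unname(disorder_features(prof(rep(0.4, 5)), 3, 2)),
               c(0.4, 0))
  expect_equal(
    unname(disorder_features(prof(c(0.4, 0.6, 0.4, 0.6, 0.5)), 3, 2)),
    c(0.5, 1)
  )
})

test_that("hydropathy means decompose over sub-windows", {
  hw <- hopp_woods_scale()
  v <- hydropathy_features("RRRRR")
  expect_equal(unname(v), rep(hw[["R"]], 3))

  v2 <- hydropathy_features("--KAS")
  expect_equal(unname(v2["hydropathy_pre"]), 0)

  # window mean equals the count-weighted combination of parts
  w <- "MI-KSTW"
  chars <- strsplit(w, "")[[1]]
  pre <- chars[1:3]; post <- chars[5:7]
  n_pre <- sum(pre != "-"); n_post <- sum(post != "-")
  v3 <- hydropathy_features(w)
  manual <- (v3[["hydropathy_pre"]] * n_pre + hw[["K"]] +
               v3[["hydropathy_post"]] * n_post) / (n_pre + n_post + 1)
  expect_equal(unname(v3["hydropathy_window"]), unname(manual))
})

test_that("volume features sum Kharakoz residue volumes per sub-window", {
  kv <- kharakoz_volumes()
  v <- volume_features("AAKAA")
  expect_equal(unname(v["volume_diff"]), 0)
  expect_equal(unname(v["volume_pre"]), 2 * kv[["A"]])

  v2 <- volume_features("--KAS")
  expect_equal(unname(v2["volume_pre"]), 0)
  expect_equal(unname(v2["volume_post"]), kv[["A"]] + kv[["S"]])
  expect_equal(unname(v2["volume_diff"]), -(kv[["A"]] + kv[["S"]]))
})

test_that("termini features implement the inclusive 10% boundary", {
  expect_equal(unname(termini_features(100, 5)), c(1, -100))
  expect_equal(unname(termini_features(100, 50)), c(0, 100))
  expect_equal(unname(termini_features(100, 10)[1]), 1) # boundary included
  expect_equal(unname(termini_features(100, 11)[1]), 0)
  expect_equal(unname(termini_features(100, 91)[1]), 1)
  expect_equal(unname(termini_features(100, 90)[1]), 0)
  # exhaustive scan of the ceil rule at an odd length
  L <- 33; edge <- ceiling(0.1 * L)
  for (p in seq_len(L)) {
    expect_equal(
      unname(termini_features(L, p)[1]),
      as.numeric(p <= edge || p >= L - edge + 1)
    )
  }
})

test_that("assembled vectors have the documented width and stable names", {
  cfg <- tiny_fixture_config(seed = 31)
  proteins <- generate_proteins(cfg)
  profiles <- generate_profiles(proteins, cfg)
  windows <- enumerate_lysine_windows(proteins$sequences,
                                      proteins$annotations, n = 10)
  feats <- assemble_features(windows, proteins$sequences, profiles)
  cols <- feature_columns(feats)
  expect_length(cols, 1150)
  expect_false(anyDuplicated(cols) > 0)
  expect_identical(cols, feature_names(10))
  expect_identical(rlang::hash(cols), rlang::hash(feature_names(10)))

  # identical windows produce identical vectors
  dup <- feats[c(1, 1), ]
  expect_identical(dup[1, cols], dup[2, cols])

  # missing profile tracks zero-fill with a warning
  expect_warning(
    nofeat <- assemble_features(windows, proteins$sequences, NULL),
    "zero-filled"
  )
  expect_true(all(nofeat$disorder_mean == 0))
  expect_error(
    assemble_features(windows, proteins$sequences, NULL,
                      missing_profiles = "error"),
    "missing"
  )
})

test_that("encodings ignore protein context except ratios and termini", {
  win <- "MASTKGLIVWQ"
  seq_a <- paste0("MMMM", win, "GGGG")
  seq_b <- paste0("WWWWWWWWWWWW", win, "C")
  seqs <- tibble::tibble(
    id = c("a", "b"),
    sequence = c(seq_a, seq_b),
    length = nchar(c(seq_a, seq_b))
  )
  windows <- tibble::tibble(
    protein_id = c("a", "b"),
    center = c(9L, 17L),
    label = "negative",
    window = win,
    n = 5L
  )
  suppressWarnings(feats <- assemble_features(windows, seqs, NULL))
  cols <- feature_columns(feats)
  context_free <- cols[!grepl("^(aa_ratio|group_ratio|termini)", cols)]
  expect_identical(feats[1, context_free], feats[2, context_free])
  expect_false(isTRUE(all.equal(feats$`termini_signed`[1],
                                feats$`termini_signed`[2])))
})
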