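random_sequence <- function(n) {
  paste(sample(phoptima:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

test_that("composition vector is 25-dimensional with unit block sums", {
  v <- aa_composition("MKVLAAGWREHDSTNQCFYI")
  expect_length(v, 25L)
  expect_equal(sum(v[1:20]), 1)
  expect_equal(sum(v[21:25]), 1)

  # property: both blocks sum to 1 for random sequences
  set.seed(11)
  for (rep in 1:10) {
    v <- aa_composition(random_sequence(sample(5:200, 1)))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-12)
    expect_equal(sum(v[21:25]), 1, tolerance = 1e-12)
  }
})

test_that("composition matches hand counts on degenerate sequences", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v["f_A"]), 1)
  expect_equal(sum(v[1:20] > 0), 1L)
  expect_equal(unname(v["grp_nonpolar"]), 1)

  v2 <- aa_composition("DEKR")
  expect_equal(unname(v2["grp_acidic"]), 0.5)
  expect_equal(unname(v2["grp_basic"]), 0.5)
  expect_equal(unname(v2["grp_aromatic"]), 0)
  expect_equal(unname(v2["grp_polar"]), 0)
  expect_equal(unname(v2["grp_nonpolar"]), 0)

  expect_error(aa_composition(""), "empty")
  expect_error(aa_composition("AXB"), "non-canonical")
})

test_that("molecular weight matches the residue-mass table and is additive", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 0.01)
  expect_error(molecular_weight("AB"), "'B'")

  set.seed(5)
  for (rep in 1:8) {
    s1 <- random_sequence(sample(3:40, 1))
    s2 <- random_sequence(sample(3:40, 1))
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("pI is the root of a strictly decreasing charge function", {
  set.seed(9)
  for (rep in 1:10) {
    s <- random_sequence(sample(3:60, 1))
    pi_val <- isoelectric_point(s)
    if (pi_val > 0 && pi_val < 14) {
      expect_lt(abs(phoptima:::protein_net_charge(s, pi_val)), 1e-2)
    }
    # strict monotonicity of Q on a pH grid
    q <- phoptima:::protein_net_charge(s, seq(0, 14, by = 0.5))
    expect_true(all(diff(q) < 0))
  }
  expect_gt(isoelectric_point("K"), 7)
  expect_lt(isoelectric_point("D"), 7)
})

test_that("pI agrees with an exhaustive pH-grid oracle", {
  for (s in c("GG", "MKVLAAG", "DDEEKKRR", "ACDEFGHIKLMNPQRSTVWY")) {
    expect_equal(isoelectric_point(s), grid_pi(s), tolerance = 2e-3)
  }
})

test_that("sequon scanning finds N-X-[S/T] with X != P", {
  expect_equal(nglyc_feature("ANGSA"),
               list(feature = 1L, positions = 2L))
  expect_equal(nglyc_feature("ANPSA"),
               list(feature = 0L, positions = integer(0)))
  expect_equal(nglyc_feature("NGSANFTA")$positions, c(1L, 5L))

  # exhaustive window-scan oracle on random sequences
  set.seed(13)
  for (rep in 1:10) {
    s <- paste(sample(c("N", "S", "T", "P", "A", "G"), 30,
                      replace = TRUE), collapse = "")
    chars <- strsplit(s, "")[[1]]
    expected <- Filter(function(i) {
      chars[i] == "N" && chars[i + 1] != "P" &&
        chars[i + 2] %in% c("S", "T")
    }, seq_len(28))
    expect_equal(nglyc_feature(s)$positions, as.integer(expected))
  }
})

test_that("secondary-structure percentages sum to 100", {
  prof <- data.frame(index = 1:10, residue = "A",
                     state = c(rep("C", 7), "H", "H", "E"),
                     p_coil = 1, p_helix = 0, p_strand = 0)
  expect_equal(ss_fractions(prof), c(coil = 70, helix = 20, strand = 10))
  all_c <- data.frame(index = 1:4, residue = "A", state = "C",
                      p_coil = 1, p_helix = 0, p_strand = 0)
  expect_equal(ss_fractions(all_c), c(coil = 100, helix = 0, strand = 0))
  expect_equal(sum(ss_fractions(prof)), 100, tolerance = 1e-9)
})

test_that("encoding one-hots categoricals and sentinels missing numerics", {
  schema <- feature_schema(
    name = c("mw", "docking_rank", "habitat"),
    kind = c("numeric", "numeric", "categorical"),
    feature_type = c("biochemical", "biochemical", "host"),
    categories = list(NULL, NULL, c("wood", "soil", "litter")))
  raw <- data.frame(id = c("a", "b", "c"),
                    mw = c(100, 200, 300),
                    docking_rank = c(1, NA, 3),
                    habitat = c("soil", NA, "wood"),
                    stringsAsFactors = FALSE)
  ft <- encode_feature_table(raw, schema)
  expect_equal(colnames(ft$matrix),
               c("mw", "docking_rank", "habitat=wood", "habitat=soil",
                 "habitat=litter"))
  expect_equal(ft$matrix["b", "docking_rank"], -1)
  expect_equal(unname(ft$matrix["a", 3:5]), c(0, 1, 0))
  expect_equal(unname(ft$matrix["b", 3:5]), c(0, 0, 0))
  expect_false(anyNA(ft$matrix))
  # one-hot rows sum to 1 for observed, 0 for missing
  expect_equal(unname(rowSums(ft$matrix[, 3:5])), c(1, 0, 1))
  # deterministic re-encoding
  expect_identical(encode_feature_table(raw, schema)$matrix, ft$matrix)

  bad <- raw
  bad$habitat[1] <- "lake"
  expect_error(encode_feature_table(bad, schema), "outside vocabulary")
  dup <- raw
  dup$id[2] <- "a"
  expect_error(encode_feature_table(dup, schema), "duplicate row id")
})

test_that("schema invariants are enforced", {
  expect_error(feature_schema("a", "numeric", "nope"), "feature_type")
  expect_error(feature_schema(c("a", "a"), rep("numeric", 2),
                              rep("biochemical", 2)), "duplicate")
  expect_error(
    feature_schema("h", "categorical", "host", list("only-one")),
    ">= 2 categories")
})

test_that("records with ambiguity codes are excluded from sequence features", {
  recs <- protein_records(c("ok", "amb"), c("MKVLA", "MKXLA"))
  expect_warning(raw <- build_raw_features(recs), "amb")
  expect_false(anyNA(raw[raw$id == "ok",
                         c("f_A", "mw", "pi", "nglyc")]))
  expect_true(all(is.na(raw[raw$id == "amb", c("f_A", "mw", "pi")])))
  ft <- encode_feature_table(raw, default_feature_schema())
  expect_equal(unname(ft$matrix["amb", "mw"]), -1)
})
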