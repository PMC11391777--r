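pred_matrix <- function(rows, models = paste0("m", seq_len(ncol(rows)))) {
  matrix(t(rows), nrow = nrow(rows), byrow = FALSE,
         dimnames = list(rownames(rows), models))
}

test_that("consensus requires enough learners at or above the threshold", {
  pm <- rbind(c1 = c(7.5, 8.0, 6.9, 7.1, 5.0),
              c2 = c(6.0, 6.5, 6.9, 5.5, 5.0),
              c3 = c(7.0, 7.0, 7.0, 6.0, 6.0))
  colnames(pm) <- paste0("m", 1:5)
  out <- consensus_candidates(pm)
  expect_equal(out$pass_count, c(3L, 0L, 3L))
  expect_equal(out$consensus, c(TRUE, FALSE, TRUE))
  # threshold is inclusive: exactly 7.0 passes
  expect_true(out$consensus[out$id == "c3"])

  # invariant to model column order
  out2 <- consensus_candidates(pm[, c(4, 2, 5, 1, 3)])
  expect_equal(out2$pass_count, out$pass_count)
})

test_that("the cophenetic window is strict and compares reference sets", {
  cd <- matrix(0, 4, 4,
               dimnames = list(c("cand", "alk", "neu", "other"),
                               c("cand", "alk", "neu", "other")))
  set_d <- function(m, a, b, v) {
    m[a, b] <- v
    m[b, a] <- v
    m
  }
  cd <- set_d(cd, "cand", "alk", 1.2)
  cd <- set_d(cd, "cand", "neu", 1.8)
  cd <- set_d(cd, "alk", "neu", 2.0)
  out <- cophenetic_filter("cand", cd, "alk", "neu")
  expect_true(out$pass)
  expect_equal(out$min_cd_alkaline, 1.2)
  expect_equal(out$min_cd_neutral, 1.8)

  # below the lower bound fails (strict)
  cd2 <- set_d(cd, "cand", "alk", 1.0)
  expect_false(cophenetic_filter("cand", cd2, "alk", "neu")$pass)
  cd2b <- set_d(cd, "cand", "alk", 1.1)
  expect_false(cophenetic_filter("cand", cd2b, "alk", "neu")$pass)
  cd2c <- set_d(cd, "cand", "alk", 1.5)
  expect_false(cophenetic_filter("cand", cd2c, "alk", "neu")$pass)

  # closer to the neutral references than the alkaline ones fails
  cd3 <- set_d(cd, "cand", "alk", 1.3)
  cd3 <- set_d(cd3, "cand", "neu", 1.2)
  expect_false(cophenetic_filter("cand", cd3, "alk", "neu")$pass)
  # ... unless the comparative clause is disabled
  cfg <- candidate_filter_config(require_closer_than_neutral = FALSE)
  expect_true(cophenetic_filter("cand", cd3, "alk", "neu", cfg)$pass)
  # ... or the neutral set is empty
  expect_true(cophenetic_filter("cand", cd3, "alk")$pass)

  expect_error(cophenetic_filter("ghost", cd, "alk"), "absent")
  expect_error(cophenetic_filter("cand", cd, c("alk", "cand")),
               "disjoint")
})

test_that("verdict distributions summarize per-candidate predictions", {
  pm <- rbind(u = c(8, 9, 10), v = c(6, 8, 9))
  colnames(pm) <- paste0("m", 1:3)
  out <- verdict_distribution(pm)
  expect_equal(out$min, c(8, 6))
  expect_equal(out$median, c(9, 8))
  expect_equal(out$max, c(10, 9))
  expect_equal(out$unanimous, c(TRUE, FALSE))

  even <- matrix(c(7, 8, 9, 12), 1, dimnames = list("w", NULL))
  expect_equal(verdict_distribution(even)$median, 8.5)

  oor <- matrix(c(15.2, 8, 8), 1, dimnames = list("z", NULL))
  expect_true(verdict_distribution(oor)$out_of_range)
  expect_true(verdict_distribution(oor)$unanimous)
})

test_that("tightening any filter bound never adds candidates", {
  set.seed(17)
  n <- 30
  pm <- matrix(stats::runif(n * 5, 4, 10), n, 5,
               dimnames = list(paste0("c", 1:n), paste0("m", 1:5)))
  tree <- ape::rtree(n + 4, tip.label = c(paste0("c", 1:n),
                                          "alk1", "alk2", "neu1", "neu2"))
  cd <- cophenetic_distances(tree)
  base_cfg <- candidate_filter_config()
  base <- select_candidates(pm, cd, c("alk1", "alk2"),
                            c("neu1", "neu2"), base_cfg)
  tighter <- list(
    candidate_filter_config(ph_threshold = 7.5),
    candidate_filter_config(min_learners = 4),
    candidate_filter_config(cd_lower = 1.2, cd_upper = 1.4))
  for (cfg in tighter) {
    res <- select_candidates(pm, cd, c("alk1", "alk2"),
                             c("neu1", "neu2"), cfg)
    expect_true(all(res$id[res$final] %in% base$id[base$final]))
  }
})

test_that("end-to-end selection returns exactly the enumerated pass set", {
  # constructed tree: candidates at controlled distances from references
  tree <- ape::read.tree(text = paste0(
    "((candA:0.6,alkRef:0.6):0.3,((candB:0.2,neuRef:0.2):0.5,",
    "(candC:1.4,candD:0.05):0.1):0.2);"))
  cd <- cophenetic_distances(tree)
  # candA-alkRef = 1.2 (in window), candA-neuRef = 1.8 (clause holds);
  # candB-alkRef = 1.8 (outside window); candC-alkRef = 2.6 (outside);
  # candD-alkRef = 1.25 in window but candD-neuRef = 0.85 fails clause
  pm <- rbind(candA = c(7.2, 7.5, 8.0, 6.0, 9.0),
              candB = c(7.2, 7.5, 8.0, 8.0, 9.0),
              candC = c(9.0, 9.0, 9.0, 9.0, 9.0),
              candD = c(7.1, 7.1, 7.1, 5.0, 5.0))
  colnames(pm) <- paste0("m", 1:5)
  verdicts <- select_candidates(pm, cd, "alkRef", "neuRef")

  # oracle: exhaustive evaluation of every rule for every candidate
  cfg <- candidate_filter_config()
  expected <- vapply(rownames(pm), function(id) {
    cons <- sum(pm[id, ] >= cfg$ph_threshold) >= cfg$min_learners
    alk <- cd[id, "alkRef"]
    neu <- cd[id, "neuRef"]
    cons && alk > cfg$cd_lower && alk < cfg$cd_upper && neu > alk
  }, TRUE)
  expect_equal(stats::setNames(verdicts$final, verdicts$id), expected)
  expect_equal(verdicts$id[verdicts$final], "candA")
  # candD failed on consensus (only 3 needed, has 3) or distance?
  expect_true(verdicts$consensus[verdicts$id == "candD"])
  expect_false(verdicts$closer_pass[verdicts$id == "candD"])
})
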