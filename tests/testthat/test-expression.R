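ann <- default_subtypes()

make_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- ann$subtype_id
  m
}

test_that("expression calls are inclusive at the threshold", {
  expect_false(is_expressed(0, 0.1))
  expect_true(is_expressed(0.1, 0.1))       # boundary: inclusive
  expect_true(all(is_expressed(c(5, 0.2), 0.1)))
  expect_error(is_expressed(0.5, -1), class = "invalid-argument")
  expect_error(is_expressed(-0.5, 0.1), class = "invalid-argument")
})

test_that("restriction requires a CGRP on-call and no LTMR/proprioceptor expression", {
  m <- make_matrix(list(
    good = c(1, 0, 0, 0,  0, 0, 0, 0,  0, 0),      # one CGRP subtype only
    broad = c(1, 1, 1, 1,  0, 0, 0, 0,  0, 0),     # all CGRP subtypes
    ltmr_only = c(0, 0, 0, 0,  1, 0, 0, 0,  0, 0),
    proprio = c(0, 0, 0, 0,  0, 0, 0, 1,  0, 0),
    leaky = c(1, 0, 0, 0,  0.5, 0, 0, 0,  0, 0),   # CGRP + LTMR -> fails
    other_ok = c(1, 0, 0, 0,  0, 0, 0, 0,  1, 0))) # "other" does not disqualify
  res <- restriction_screen(m, ann, on_threshold = 0.1)
  expect_equal(res$restricted,
               c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$breadth[res$gene == "broad"], 4L)
  expect_equal(res$breadth[res$gene == "ltmr_only"], 0L)
  expect_equal(res$off_violations[res$gene == "leaky"], "Ab-LTMR")
  # strict mode adds "other" subtypes to the exclusion classes
  strict <- restriction_screen(m, ann, strict_other = TRUE)
  expect_false(strict$restricted[strict$gene == "other_ok"])
})

test_that("screen recovers exactly the planted genes on synthetic matrices", {
  planted <- sprintf("g%04d", 1:10)
  sim <- simulate_expression_matrix(200, ann, planted, n_decoys = 20,
                                    seed = 11)
  res <- restriction_screen(sim$matrix, ann, on_threshold = 0.1)
  expect_setequal(res$gene[res$restricted], planted)
  # no planted set -> nothing restricted at these thresholds
  sim0 <- simulate_expression_matrix(50, ann, character(), n_decoys = 5,
                                     seed = 12)
  res0 <- restriction_screen(sim0$matrix, ann, on_threshold = 0.1)
  expect_equal(sum(res0$restricted), 0L)
})

test_that("raising on_threshold never enlarges the restricted set", {
  sim <- simulate_expression_matrix(100, ann, sprintf("g%04d", 1:8),
                                    n_decoys = 10, seed = 13)
  sets <- lapply(c(0.05, 0.1, 0.5, 1.0, 1.5), function(on) {
    res <- restriction_screen(sim$matrix, ann, on_threshold = on,
                              off_threshold = 0.05)
    res$gene[res$restricted]
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("screen output is invariant to row and column permutation", {
  sim <- simulate_expression_matrix(40, ann, sprintf("g%04d", 1:5),
                                    n_decoys = 5, seed = 14)
  m <- sim$matrix
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  a <- restriction_screen(m, ann)
  b <- restriction_screen(perm, ann)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$restricted, b$restricted)
  expect_equal(a$breadth, b$breadth)
})

test_that("binary matrices with equal thresholds match brute-force set logic", {
  set.seed(42)
  m <- matrix(rbinom(30 * 10, 1, 0.3), nrow = 30,
              dimnames = list(sprintf("b%02d", 1:30), ann$subtype_id))
  res <- restriction_screen(m, ann, on_threshold = 1, off_threshold = 1)
  cgrp <- ann$subtype_id[ann$class == "CGRP"]
  off <- ann$subtype_id[ann$class %in% c("LTMR", "proprioceptor")]
  oracle <- apply(m, 1, function(row)
    any(row[cgrp] == 1) && all(row[off] == 0))
  expect_equal(res$restricted, unname(oracle))
})

test_that("breadth profile partitions the restricted genes", {
  sim <- simulate_expression_matrix(60, ann, sprintf("g%04d", 1:10),
                                    planted_broad_k = rep(c(1L, 4L), 5),
                                    n_decoys = 0, seed = 15)
  res <- restriction_screen(sim$matrix, ann)
  prof <- breadth_profile(res)
  expect_equal(sum(prof$n_genes), sum(res$restricted))
  expect_equal(prof$n_genes[prof$breadth == 1], 5L)
  expect_equal(prof$n_genes[prof$breadth == 4], 5L)
  empty <- restriction_screen(
    matrix(0, 2, 10, dimnames = list(c("x", "y"), ann$subtype_id)), ann)
  expect_equal(nrow(breadth_profile(empty)), 0L)
})

test_that("degenerate inputs are rejected", {
  m <- matrix(1, 2, 10, dimnames = list(c("a", "a"), ann$subtype_id))
  expect_error(restriction_screen(m, ann), class = "invalid-argument")
  expect_error(restriction_screen(matrix(1, 0, 10), ann),
               class = "invalid-argument")
  good <- matrix(1, 1, 10, dimnames = list("a", ann$subtype_id))
  expect_error(restriction_screen(good, ann, off_threshold = 0.5,
                                  on_threshold = 0.1),
               class = "invalid-argument")
})
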