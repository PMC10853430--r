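test_that("composition counts unique formulas and reports percentages", {
  f <- formula_frame(  # 5 lignin/CRAM, 3 tannins, 2 lipids
    C = c(10, 11, 12, 13, 14, 10, 11, 12, 18, 19),
    H = c(10, 10, 12, 12, 14, 10, 10, 12, 34, 36),
    O = c( 3,  3,  4,  4,  5,  8,  9,  9,  2,  2))
  ann <- classify_table(f)
  cp <- composition(ann, "s")
  expect_equal(cp$n_formulas, 10)
  expect_equal(unname(cp$class_pct["lignin_cram"]), 50)
  expect_equal(unname(cp$class_pct["tannins"]), 30)
  expect_equal(unname(cp$class_pct["lipids"]), 20)
  expect_equal(sum(cp$class_pct), 100)
  expect_equal(sum(cp$group_pct), 100)

  # duplicated formula counted once; row order irrelevant
  dup <- ann[c(1, 1, 2:10), ]
  expect_equal(composition(dup, "s")$n_formulas, 10)
  shuf <- ann[sample.int(10), ]
  expect_equal(composition(shuf, "s")$class_pct, cp$class_pct)
})

test_that("empty samples warn and report zero formulas", {
  ann <- classify_table(formula_frame(integer(0), integer(0)))
  expect_warning(cp <- composition(ann, "empty"), "no assigned formulas")
  expect_equal(cp$n_formulas, 0)
})

test_that("two-condition comparison performs exact set algebra", {
  base <- classify_table(random_valid_formulas(5))
  a <- base[1:3, ]
  b <- base[2:5, ]
  cmp <- compare_two(a, b)
  expect_equal(unname(cmp$counts), c(1L, 2L, 2L))
  expect_equal(unname(cmp$overall_pct), c(20, 40, 40))

  same <- compare_two(a, a)
  expect_equal(unname(same$overall_pct), c(0, 100, 0))

  expect_error(compare_two(a[0, ], a[0, ]), "empty")
})

test_that("per-class rows report D/R/P within the pooled class membership", {
  set.seed(10)
  tan <- classify_table(sample_formula_in_class("tannins", 4, window = c(210, 900)))
  lig <- classify_table(sample_formula_in_class("lignin_cram", 3, window = c(210, 900)))
  cmp <- compare_two(rbind(tan, lig), lig)  # all tannins only in A
  row <- cmp$per_class[cmp$per_class$feature == "tannins", ]
  expect_equal(row$pct_degraded, 100)
  expect_equal(row$n_total, 4)
})

test_that("comparison respects swap symmetry and union identities", {
  set.seed(11)
  pool <- classify_table(random_valid_formulas(400))
  pool <- pool[!duplicated(formula_key(pool)), ]
  for (i in 1:20) {
    a <- pool[sample.int(nrow(pool), 80), ]
    b <- pool[sample.int(nrow(pool), 120), ]
    ab <- compare_two(a, b); ba <- compare_two(b, a)
    expect_equal(ab$counts[["degraded"]], ba$counts[["produced"]])
    expect_equal(ab$counts[["remaining"]], ba$counts[["remaining"]])
    na <- length(unique(formula_key(a)))
    nb <- length(unique(formula_key(b)))
    expect_equal(ab$counts[["degraded"]] + ab$counts[["remaining"]], na)
    expect_equal(ab$counts[["remaining"]] + ab$counts[["produced"]], nb)
    expect_equal(sum(ab$overall_pct), 100, tolerance = 1e-9)
  }
})

test_that("venn percentages reproduce printed partitions exactly", {
  expect_equal(unname(venn_percentages(56, 613, 97)), c(7.31, 80.03, 12.66))
  expect_equal(unname(venn_percentages(0, 10, 0)), c(0, 100, 0))
  expect_equal(unname(venn_percentages(1, 1, 1)), c(33.33, 33.33, 33.33))
  expect_error(venn_percentages(0, 0, 0), "empty")
  expect_error(venn_percentages(-1, 2, 3), ">= 0")
})

test_that("taxon Venn partitions respect the presence threshold", {
  a <- data.frame(genus = c("g1", "g2"), s1 = c(5, 0))
  b <- data.frame(genus = c("g2", "g3"), s1 = c(3, 1))
  expect_equal(unname(build_venn_from_tables(a, b)), c(1L, 0L, 2L))
  expect_equal(unname(build_venn_from_tables(a, a)), c(0L, 1L, 0L))

  thr <- data.frame(genus = c("g1", "g2"), s1 = c(5, 3))
  v <- build_venn_from_tables(thr, thr, presence_threshold = 4)
  expect_equal(unname(v), c(0L, 1L, 0L))

  dupd <- data.frame(genus = c("g1", "g1"), s1 = c(1, 2))
  expect_error(build_venn_from_tables(dupd, b), "duplicated")
})
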