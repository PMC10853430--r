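test_that("class-box sampling round-trips through classification", {
  set.seed(30)
  for (cl in vk_classes()$class) {
    f <- sample_formula_in_class(cl, 100,
                                 n_atoms = sample(0:3, 100, replace = TRUE),
                                 s_atoms = sample(0:1, 100, replace = TRUE),
                                 window = c(210, 1000))
    expect_true(all(as.character(classify_formula(f)) == cl), label = cl)
    m <- exact_neutral_mass(f)
    expect_true(all(m >= 210 & m <= 1000), label = cl)
    expect_true(all(formula_is_valid(f)), label = cl)
  }
})

test_that("sampled ratios respect the margin-shrunk box", {
  set.seed(31)
  f <- sample_formula_in_class("carbohydrates", 200, window = c(210, 1000))
  r <- elemental_ratios(f)
  expect_true(all(r$o_c >= 0.68 & r$o_c <= 1.19))
  expect_true(all(r$h_c >= 1.51 & r$h_c <= 2.29))
})

test_that("infeasible boxes raise an infeasible-configuration error", {
  expect_error(sample_formula_in_class("lipids", 5, window = c(10, 12)),
               "infeasible")
})

test_that("a noiseless sample is recovered perfectly by assignment", {
  cfg <- scenario_config(formulas_per_sample = 150, mass_error_sd_ppm = 0,
                         noise_fraction = 0, low_snr_fraction = 0, seed = 32)
  set.seed(cfg$seed)
  g <- generate_sample(1, cfg)
  a <- assign_peaklist(g$peaks, quiet = TRUE)
  expect_equal(nrow(a), 150)
  got <- sort(formula_key(a[, c("C", "H", "O", "N", "S")]))
  want <- sort(formula_key(g$truth))
  expect_identical(got, want)
})

test_that("the configured low-S/N fraction is removed by peak filtering", {
  cfg <- scenario_config(formulas_per_sample = 2000, noise_fraction = 0,
                         low_snr_fraction = 0.1, seed = 33)
  set.seed(cfg$seed)
  g <- generate_sample(1, cfg)
  kept <- nrow(filter_peaks(g$peaks))
  expect_equal(1 - kept / 2000, 0.1, tolerance = 0.25)
})

test_that("noise peaks are never assignable at the default tolerance", {
  cfg <- scenario_config(formulas_per_sample = 200, noise_fraction = 0.5,
                         mass_error_sd_ppm = 0, seed = 34)
  set.seed(cfg$seed)
  g <- generate_sample(1, cfg)
  truth_mz <- mz_from_neutral_mass(exact_neutral_mass(g$truth))
  is_noise <- !(g$peaks$mz %in% truth_mz)
  noise <- g$peaks[is_noise, , drop = FALSE]
  noise <- noise[noise$snr >= 4, , drop = FALSE]
  a <- assign_peaklist(noise, quiet = TRUE)
  expect_true(all(is.na(a$C)))
})

test_that("the same seed reproduces the whole study exactly", {
  cfg <- small_scenario(seed = 35)
  expect_identical(generate_study(cfg), generate_study(cfg))
})

test_that("truth compositions track the configured mixtures", {
  cfg <- scenario_config(seed = 36)
  st <- generate_study(cfg)
  for (ci in c(1, 4)) {
    sel <- st$samples$condition == cfg$conditions[ci]
    pct <- rowMeans(vapply(st$truth$formulas[sel], function(tt)
      100 * as.numeric(table(tt$compound_class))[1:7] / nrow(tt), numeric(7)))
    expect_true(all(abs(pct - cfg$class_mixture[ci, ]) < 1.5))
  }
})

test_that("degraded/remaining/produced are all realised between end conditions", {
  cfg <- small_scenario(seed = 37, n = 1500)
  st <- generate_study(cfg)
  first <- st$samples$condition == "CC1Y"
  last <- st$samples$condition == "CC7Y"
  ann <- lapply(st$truth$formulas, function(tt) tt)
  cmp <- compare_two(do.call(rbind, ann[first]), do.call(rbind, ann[last]),
                     labels = c("CC1Y", "CC7Y"))
  expect_true(all(cmp$counts > 0))
  expect_equal(sum(cmp$overall_pct), 100, tolerance = 0.1)
})

test_that("the copula coupling hits its target rank correlation", {
  set.seed(38)
  x <- rnorm(3000)
  y <- couple_to_feature(x, 0.95)
  expect_equal(cor(x, y, method = "spearman"), 0.95, tolerance = 0.03)
  yn <- couple_to_feature(x, -0.9)
  expect_equal(cor(x, yn, method = "spearman"), -0.9, tolerance = 0.04)
})

test_that("planted genus couplings surface as signed network edges", {
  cfg <- small_scenario(seed = 39, n = 1200)
  st <- generate_study(cfg)
  net <- build_network(st$features$x, st$features$meta)
  e <- net$edges
  hit <- (e$node_a == "Methylobacter" & e$node_b == "aliphatic_proteins") |
         (e$node_b == "Methylobacter" & e$node_a == "aliphatic_proteins")
  expect_true(any(hit))
  expect_equal(e$sign[hit], "positive")
})
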