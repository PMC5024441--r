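test_that("generators are pure functions of scenario and seed", {
  sc <- spectrum_scenario("mannanase", n_decoys = 10)
  s1 <- gen_spectrum(sc, seed = 99)
  s2 <- gen_spectrum(sc, seed = 99)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))
  expect_false(identical(s1$peaks, gen_spectrum(sc, seed = 100)$peaks))

  es <- expression_scenario(n_genes = 50)
  expect_identical(gen_expression(es, 5)$values, gen_expression(es, 5)$values)

  bs <- biochem_scenario()
  expect_identical(as.data.frame(gen_biochem(bs, 6)),
                   as.data.frame(gen_biochem(bs, 6)))

  # the global RNG stream is left untouched
  set.seed(1); before <- .Random.seed
  invisible(gen_spectrum(sc, seed = 42))
  expect_identical(.Random.seed, before)
})

test_that("noise-free spectra sit exactly on the sodiated masses", {
  sc <- spectrum_scenario("mannanase",
                          abundances = c(Hex4a1 = 10, XXXG = 5),
                          jitter_sd = 0, noise_cv = 0)
  sp <- gen_spectrum(sc, seed = 1)
  expect_equal(sp$peaks$mz, c(731.2222, 1085.3385), tolerance = 1e-4)
  expect_equal(sp$peaks$intensity, c(10, 5))
})

test_that("spectrum scenarios must include the digest reference ion", {
  expect_error(spectrum_scenario("glucanase",
                                 abundances = c(Hex4a1 = 10)),
               "reference ion")
  expect_error(spectrum_scenario("mannanase",
                                 abundances = c(BadCode = 1)),
               "malformed")
  expect_error(spectrum_scenario("mannanase",
                                 abundances = c(Hex4a1 = -1)),
               "positive")
})

test_that("planted ions are recovered and decoys never steal their codes", {
  sc <- spectrum_scenario("mannanase", jitter_sd = 0.05, n_decoys = 20)
  sp <- gen_spectrum(sc, seed = 314)
  truth <- attr(sp, "truth")
  ann <- annotate_spectrum(sp, tol = 0.3)
  planted <- which(!is.na(truth$code))
  for (i in planted) {
    codes <- ann$annotations[[i]]$code
    expect_true(any(vapply(codes, function(cc)
      parse_oligo_code(cc) == parse_oligo_code(truth$code[i]), TRUE)),
      label = paste("recovery of", truth$code[i]))
  }
  # decoys are generated >= 1 Da from every planted mass, so within the
  # 0.3 Da tolerance none can be assigned a planted composition
  planted_keys <- vapply(lapply(truth$code[planted], parse_oligo_code),
                         comp_key, "")
  for (i in which(is.na(truth$code))) {
    codes <- ann$annotations[[i]]$code
    if (length(codes))
      expect_false(any(vapply(lapply(codes, parse_oligo_code),
                              comp_key, "") %in% planted_keys))
  }
})

test_that("expression generator plants the early/late cluster design", {
  es <- expression_scenario(n_genes = 100, frac_a = 0.2, frac_b = 0.2,
                            effect = 3, residual_sd = 0.1)
  ex <- gen_expression(es, seed = 11)
  expect_identical(dim(ex$values), c(100L, 80L))  # 5 stages x 8 geno x 2 plots
  expect_identical(as.integer(table(ex$labels)[c("A", "B", "null")]),
                   c(20L, 20L, 60L))
  early <- ex$meta$stage %in% c("60DAF", "110DAF")
  a_contrast <- rowMeans(ex$values[ex$labels == "A", early]) -
    rowMeans(ex$values[ex$labels == "A", !early])
  b_contrast <- rowMeans(ex$values[ex$labels == "B", early]) -
    rowMeans(ex$values[ex$labels == "B", !early])
  expect_true(all(a_contrast > 2.5))
  expect_true(all(b_contrast < -2.5))

  # null scenario: selection stays at the type-I rate
  es0 <- expression_scenario(n_genes = 2000, frac_a = 0, frac_b = 0)
  ex0 <- gen_expression(es0, seed = 12)
  sel_cols <- ex0$meta$stage %in% c("60DAF", "2M")
  res <- moderated_ttest(ex0$values[, sel_cols], ex0$meta$stage[sel_cols])
  expect_lt(select_differential(res, 0.01)$n_selected / 2000, 0.025)
})

test_that("planted clusters are exactly recovered from stage means", {
  skip_if_not_installed("mclust")
  es <- expression_scenario(n_genes = 60, frac_a = 0.3, frac_b = 0.3,
                            effect = 2, residual_sd = 0.1)
  ex <- gen_expression(es, seed = 13)
  stage_means <- vapply(unique(ex$meta$stage), function(s)
    rowMeans(ex$values[, ex$meta$stage == s, drop = FALSE]),
    numeric(nrow(ex$values)))
  planted <- ex$labels != "null"
  cl <- hierarchical_cluster(stage_means[planted, ], k = 2)$clusters
  ari <- mclust::adjustedRandIndex(cl, ex$labels[planted])
  expect_equal(ari, 1)
})

test_that("biochemical templates interpolate the published stage trends", {
  bs <- biochem_scenario()
  noise_free <- biochem_scenario(
    analytes = transform(bs$analytes, noise_sd = 0))
  tab <- gen_biochem(noise_free, seed = 1)
  tmpl <- attr(tab, "templates")
  # endpoints equal the published 60DAF and 2M values
  expect_equal(unname(tmpl$gal[c("60DAF", "2M")]), c(18.7, 7.2))
  expect_equal(unname(tmpl$ua[c("60DAF", "2M")]), c(22.4, 29.0))
  # galactose declines monotonically, xylose rises
  expect_true(all(diff(tmpl$gal) < 0))
  expect_true(all(diff(tmpl$xyl) > 0))
  # noise-free replicates sit exactly on the template
  expect_equal(tab$gal, unname(tmpl$gal[match(tab$stage, names(tmpl$gal))]))
  # generated values never negative (resampling, not clipping)
  tight <- biochem_scenario(analytes = data.frame(
    analyte = "fuc", start = 0.1, end = 0.1, noise_sd = 0.15))
  many <- gen_biochem(tight, seed = 2)
  expect_true(all(many$fuc >= 0))
})
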