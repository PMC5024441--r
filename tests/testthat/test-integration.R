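test_that("PCA agrees with an eigendecomposition oracle", {
  set.seed(13)
  x <- matrix(rnorm(40 * 6), 40)
  res <- fingerprint_pca(x)
  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(res$sdev^2, ev$values[seq_along(res$sdev)],
               tolerance = 1e-8)
  for (k in 1:6) {
    # loadings agree up to sign
    expect_lt(min(sum(abs(res$loadings[, k] - ev$vectors[, k])),
                  sum(abs(res$loadings[, k] + ev$vectors[, k]))), 1e-8)
  }
  # loadings orthonormal; explained variances non-increasing, sum 1
  expect_equal(crossprod(res$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_equal(sum(res$explained), 1)
  # full-rank reconstruction
  centered <- sweep(x, 2, res$center)
  expect_equal(res$scores %*% t(res$loadings), centered, tolerance = 1e-8)
})

test_that("PCA degenerate and structured inputs behave as expected", {
  # collinear 2-D points: PC1 explains everything
  x <- cbind(1:10, 2 * (1:10) + 3)
  res <- fingerprint_pca(x)
  expect_equal(res$explained[1], 1, tolerance = 1e-12)
  # isotropic cloud: roughly equal explained variances
  set.seed(14)
  iso <- matrix(rnorm(4000), ncol = 4)
  expect_lt(diff(range(fingerprint_pca(iso)$explained)), 0.1)
  # zero-variance column with scaling requested errors, naming the column
  bad <- cbind(ion1 = rnorm(5), ion2 = rep(2, 5))
  expect_error(fingerprint_pca(bad, scale = TRUE), "ion2")
})

test_that("stage-shifted fingerprints separate along PC1", {
  set.seed(15)
  sc_early <- spectrum_scenario("glucanase")
  ab <- sc_early$abundances
  # mature-stage pattern: xyloglucan ions up, hexo/pento ions down
  xygo <- grepl("^X|^G", names(ab))
  ab_late <- ab * ifelse(xygo, 3, 0.3)
  ab_late["XXXG"] <- ab[["XXXG"]]
  sc_late <- spectrum_scenario("glucanase", abundances = ab_late)
  specs <- c(
    lapply(1:6, function(i) gen_spectrum(sc_early, seed = i,
                                         sample_id = "early", stage = "60DAF",
                                         replicate = i)),
    lapply(1:6, function(i) gen_spectrum(sc_late, seed = 100 + i,
                                         sample_id = "late", stage = "2M",
                                         replicate = i)))
  specs <- lapply(specs, normalize_to_reference)
  mat <- build_intensity_matrix(specs, apple_ion_roster("glucanase"))
  pc <- fingerprint_pca(mat, scale = FALSE)
  s1 <- pc$scores[1:6, 1]; s2 <- pc$scores[7:12, 1]
  # group silhouette on PC1: clean separation
  sep <- abs(mean(s1) - mean(s2)) / (sd(s1) + sd(s2))
  expect_gt(sep, 2)
})

test_that("genotype pooling averages member genotypes per stage", {
  es <- expression_scenario(n_genes = 20, residual_sd = 0)
  ex <- gen_expression(es, seed = 2)
  pooled <- pool_genotypes(ex$values, ex$meta)
  expect_identical(dim(pooled), c(20L, 15L))  # 5 stages x 3 pools
  # noise-free: pooled equals any member's value
  one <- ex$values[, ex$meta$stage == "60DAF" & ex$meta$genotype == "V034"]
  expect_equal(pooled[, "60DAF.Pool1"], one[, 1])
  # hand-check one cell against the member mean
  sel <- ex$meta$stage == "H" & ex$meta$genotype %in% c("H074", "I016")
  expect_equal(pooled[, "H.Pool3"], rowMeans(ex$values[, sel]))
  # single-genotype pool is the identity
  p1 <- pool_genotypes(ex$values, ex$meta, scheme = list(Only = "W029"))
  selw <- ex$meta$stage == "2M" & ex$meta$genotype == "W029"
  expect_equal(p1[, "2M.Only"], rowMeans(ex$values[, selw]))
  expect_error(pool_genotypes(ex$values, ex$meta,
                              scheme = list(P = c("V034", "ZZZ"))), "ZZZ")
})

test_that("pearson_with_p matches cor.test and its closed form", {
  set.seed(16)
  x <- rnorm(20); y <- x + rnorm(20)
  res <- pearson_with_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_identical(res$n, 20L)
  # y = x: r = 1, p = 0
  perfect <- pearson_with_p(1:5, 1:5)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  # the study's r > 0.7, n = 16 edge clears the p < 0.01 gate
  tt <- 0.7 * sqrt(14) / sqrt(1 - 0.49)
  expect_equal(2 * pt(-tt, 14), 0.0026, tolerance = 0.02)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "constant")
})

test_that("null correlation p-values are uniform", {
  set.seed(17)
  pvals <- replicate(2000, pearson_with_p(rnorm(10), rnorm(10))$p)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.01) - 0.01), 0.01)
})

test_that("correlation networks admit only threshold-passing edges", {
  set.seed(18)
  # near-identical profiles: complete graph, one 5-node component
  base <- rnorm(10)
  prof <- t(replicate(5, base + rnorm(10, 0, 1e-4)))
  rownames(prof) <- paste0("g", 1:5)
  net <- build_network(prof)
  expect_identical(nrow(net$edges), 10L)
  expect_identical(unname(net$component_sizes[1]), 5L)
  expect_true(all(net$edges$r > 0.7 & net$edges$p < 0.01))
  # r_min above 1: empty edge set, all singleton components
  empty <- build_network(prof, r_min = 1.01, signed_mode = "absolute")
  expect_identical(nrow(empty$edges), 0L)
  expect_true(all(empty$component_sizes == 1))
  # symmetric in input order
  net_rev <- build_network(prof[5:1, ])
  expect_identical(nrow(net_rev$edges), 10L)
  expect_identical(sort(unname(net$components)),
                   sort(unname(net_rev$components)))
})

test_that("a planted co-expression module is recovered with few false edges", {
  set.seed(19)
  n_obs <- 40  # observations per profile (genotype x plot stage series)
  template <- rnorm(n_obs)
  module <- t(replicate(10, template + rnorm(n_obs, 0, 0.3)))
  noise <- matrix(rnorm(90 * n_obs), 90)
  prof <- rbind(module, noise)
  rownames(prof) <- c(paste0("mod", 1:10), paste0("bg", 1:90))
  net <- build_network(prof)
  in_mod <- grepl("^mod", net$edges$node1) & grepl("^mod", net$edges$node2)
  false_edges <- sum(!in_mod)
  comp_of_mod <- net$components[paste0("mod", 1:10)]
  biggest <- as.integer(names(which.max(table(comp_of_mod))))
  expect_gte(sum(comp_of_mod == biggest), 9)
  expect_lte(false_edges, 2)
})

test_that("signed modes gate negative correlations differently", {
  x <- 1:10 + rnorm(10, 0, 0.01)
  prof <- rbind(up = x, down = -x)
  pos <- build_network(prof, signed_mode = "positive")
  expect_identical(nrow(pos$edges), 0L)
  abs_net <- build_network(prof, signed_mode = "absolute")
  expect_identical(nrow(abs_net$edges), 1L)
  expect_lt(abs_net$edges$r, -0.9)
})

test_that("network export writes edge lists and GraphML", {
  set.seed(20)
  base <- rnorm(8)
  prof <- t(replicate(3, base + rnorm(8, 0, 0.01)))
  rownames(prof) <- c("a", "b", "c")
  net <- build_network(prof)
  tsv <- tempfile(fileext = ".tsv")
  write_network(net, tsv)
  back <- read.delim(tsv)
  expect_identical(names(back), c("node1", "node2", "r", "p"))
  expect_identical(nrow(back), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
})

test_that("biochemistry-transcript correlation pairs by stage and index", {
  es <- expression_scenario(n_genes = 30, residual_sd = 0.2)
  ex <- gen_expression(es, seed = 23)
  pooled <- pool_genotypes(ex$values, ex$meta)
  bio <- gen_biochem(biochem_scenario(), seed = 24)
  analytes <- c("gal", "ua", "xyl", "man", "fuc")
  bm <- t(as.matrix(bio[, analytes]))
  colnames(bm) <- paste(bio$stage, bio$replicate, sep = ".")
  bt <- correlate_biochem_transcript(bm, bio[, c("stage", "replicate")],
                                     pooled)
  expect_identical(nrow(bt), 30L * 5L)
  expect_true(all(bt$n == 15))
  # a gene profile equal to the galactose profile correlates perfectly
  fake <- matrix(bm["gal", ], 1, dimnames = list("fake", colnames(pooled)))
  res <- correlate_biochem_transcript(bm, bio[, c("stage", "replicate")],
                                      fake,
                                      expr_meta = data.frame(
                                        stage = bio$stage,
                                        pool = bio$replicate))
  gal_row <- res[res$analyte == "gal", ]
  expect_equal(gal_row$r, 1, tolerance = 1e-12)
  expect_true(gal_row$significant)
  # axis mismatch errors
  expect_error(correlate_biochem_transcript(
    bm[, 1:12], bio[1:12, c("stage", "replicate")], pooled), "axes")
})
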