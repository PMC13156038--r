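test_that("QC filter reproduces the annotation-table counts", {
  ann <- receptor_annotation()
  expect_equal(nrow(ann), 38)
  # every listed gene passes the published thresholds (inclusive at the
  # table's printed precision)
  expect_length(qc_filter(ann, qc_thresholds(0.2, 0.2, 0.1)), 38)
  # strict thresholds: oracle is a direct brute-force count
  oracle <- sum(ann$mean_intensity > 0.2 & ann$rnaseq_correlation > 0.2 &
                  ann$differential_stability > 0.5)
  got <- qc_filter(ann, qc_thresholds(0.2, 0.2, 0.5, inclusive = FALSE))
  expect_length(got, oracle)
  expect_length(qc_filter(ann, qc_thresholds(1, 1, 1, inclusive = FALSE)),
                0)
  # order preserved
  expect_identical(got, ann$gene[ann$gene %in% got])
})

test_that("QC filter is monotone in its thresholds", {
  ann <- receptor_annotation()
  set.seed(1)
  for (i in 1:20) {
    th <- runif(3, 0, 0.9)
    base <- qc_filter(ann, qc_thresholds(th[1], th[2], th[3]))
    bump <- th
    j <- sample(3, 1)
    bump[j] <- min(1, bump[j] + runif(1, 0, 0.3))
    raised <- qc_filter(ann, qc_thresholds(bump[1], bump[2], bump[3]))
    expect_true(all(raised %in% base))
  }
})

test_that("QC filter demands complete metrics", {
  ann <- receptor_annotation()
  ann$differential_stability[5] <- NA
  expect_error(qc_filter(ann),
               paste0("gene ", receptor_annotation()$gene[5],
                      ".*differential_stability"))
})

test_that("robust sigmoid normalization matches its closed form", {
  x <- c(1, 2, 3)
  iqr <- IQR(x)
  z <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  expected <- (z - min(z)) / (max(z) - min(z))
  got <- robust_sigmoid_normalize(matrix(x, ncol = 1))
  expect_equal(drop(got), expected)
  expect_equal(got[1], 0)
  expect_equal(got[3], 1)
  expect_true(got[2] > 0 && got[2] < 1)
})

test_that("robust sigmoid is affine-invariant and order-preserving", {
  set.seed(2)
  x <- rnorm(40)
  m <- matrix(x, ncol = 1)
  expect_equal(robust_sigmoid_normalize(5.5 * m + 3),
               robust_sigmoid_normalize(m))
  out <- drop(robust_sigmoid_normalize(m))
  expect_identical(order(out), order(x))
})

test_that("zero-IQR slices follow the configured policy", {
  m <- cbind(a = c(1, 1, 1, 1, 5), b = 1:5)
  expect_error(robust_sigmoid_normalize(m), "interquartile")
  out <- robust_sigmoid_normalize(m, zero_iqr = "constant")
  expect_equal(unname(out[, "a"]), rep(0.5, 5))
})

test_that("within-region axis normalizes rows", {
  m <- matrix(rnorm(60), 6, 10)
  out <- robust_sigmoid_normalize(m, axis = "within_region")
  expect_equal(unname(apply(out, 1, min)), rep(0, 6))
  expect_equal(unname(apply(out, 1, max)), rep(1, 6))
})

test_that("differential stability equals the mean pairwise correlation", {
  atl <- tiny_atlas(3)
  set.seed(3)
  donors <- lapply(1:3, function(i) {
    regional_matrix(matrix(rnorm(9), 3, dimnames = list(NULL,
                                                        c("g1", "g2", "g3"))),
                    atl)
  })
  ds <- differential_stability(donors)
  oracle <- vapply(1:3, function(j) {
    mean(c(cor(donors[[1]]$values[, j], donors[[2]]$values[, j]),
           cor(donors[[1]]$values[, j], donors[[3]]$values[, j]),
           cor(donors[[2]]$values[, j], donors[[3]]$values[, j])))
  }, numeric(1))
  expect_equal(unname(ds), oracle)
  # two donors: the single pairwise correlation
  two <- differential_stability(donors[1:2])
  expect_equal(unname(two),
               vapply(1:3, function(j) cor(donors[[1]]$values[, j],
                                           donors[[2]]$values[, j]),
                      numeric(1)))
  # identical donors give 1 everywhere
  expect_equal(unname(differential_stability(list(donors[[1]],
                                                  donors[[1]]))),
               rep(1, 3))
})

test_that("zero-variance donor columns are skipped with a warning", {
  atl <- tiny_atlas(4)
  m1 <- regional_matrix(cbind(g = c(1, 1, 1, 1)), atl)
  m2 <- regional_matrix(cbind(g = c(1, 2, 3, 4)), atl)
  m3 <- regional_matrix(cbind(g = c(2, 1, 4, 3)), atl)
  expect_warning(ds <- differential_stability(list(m1, m2, m3)),
                 "skipped")
  expect_equal(unname(ds), cor(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_warning(ds0 <- differential_stability(list(m1, m1)), "skipped")
  expect_true(is.na(ds0))
})

test_that("donor aggregation averages with explicit missingness", {
  atl <- tiny_atlas(2)
  d0 <- regional_matrix(cbind(g = c(0, 0)), atl)
  d1 <- regional_matrix(cbind(g = c(1, 1)), atl)
  expect_equal(unname(aggregate_donors(list(d0, d1))$values[, 1]),
               c(0.5, 0.5))
  expect_identical(aggregate_donors(list(d1)), d1)
  dm <- regional_matrix(cbind(g = c(NA, 4)), atl)
  got <- aggregate_donors(list(d0, d1, dm))$values[, 1]
  expect_equal(unname(got), c(0.5, 5 / 3))
  all_na <- regional_matrix(cbind(g = c(NA, 1)), atl)
  got2 <- aggregate_donors(list(all_na, all_na))$values[, 1]
  expect_true(is.na(got2[1]))
  expect_equal(unname(got2[2]), 1)
})

test_that("stratified summaries match direct arithmetic", {
  atl <- region_atlas(data.frame(
    region_id = 1:3, name = c("a", "b", "c"),
    structure = c("cortex", "cortex", "subcortex"),
    stratum = c("visual", "visual", "thalamus"),
    hemisphere = "L", x = 1:3, y = 0, z = 0))
  m <- regional_matrix(cbind(g1 = c(1, 3, 10), g2 = c(2, 2, 2)), atl)
  s <- suppressWarnings(stratified_summary(m, atl))
  expect_equal(s$stratum_means["visual", ], c(g1 = 2, g2 = 2))
  expect_equal(s$stratum_means["thalamus", ], c(g1 = 10, g2 = 2))
  expect_equal(s$structure_medians["cortex", ], c(g1 = 2, g2 = 2))
  # constant map: every stratum mean equals the constant
  expect_equal(unname(suppressWarnings(
    stratified_summary(regional_matrix(cbind(k = rep(4, 3)), atl),
                       atl))$stratum_means[, 1]),
    c(4, 4))
  # single-stratum atlas: stratum mean equals the global mean
  atl1 <- region_atlas(data.frame(
    region_id = 1:4, name = letters[1:4], structure = "cortex",
    stratum = "visual", hemisphere = "L", x = 1:4, y = 0, z = 0))
  m1 <- regional_matrix(cbind(g = c(1, 2, 3, 8)), atl1)
  s1 <- suppressWarnings(stratified_summary(m1, atl1))
  expect_equal(unname(s1$stratum_means[1, 1]), mean(c(1, 2, 3, 8)))
})

test_that("receptor ordering comes from profile clustering", {
  atl <- make_atlas(20, 6, TRUE, seed = 21)
  set.seed(22)
  vals <- cbind(a = rnorm(27), b = rnorm(27))
  vals <- cbind(vals, a2 = vals[, "a"] + rnorm(27, sd = 0.01))
  s <- stratified_summary(regional_matrix(vals, atl), atl)
  ord <- colnames(vals)[s$order]
  # near-duplicate columns end up adjacent
  expect_equal(abs(which(ord == "a") - which(ord == "a2")), 1)
})

test_that("probe filtering implements both readings of the rule", {
  intensity <- rbind(p1 = c(5, 5, 5, 5, 5),
                     p2 = c(1, 1, 1, 5, 5),
                     p3 = c(1, 5, 5, 5, 5))
  kept_sensible <- filter_probes(intensity, background = 2, frac = 0.2)
  expect_identical(kept_sensible, c("p1", "p3"))
  kept_literal <- filter_probes(intensity, background = 2, frac = 0.2,
                                reading = "below_in_less")
  expect_identical(kept_literal, c("p2", "p3"))
})

test_that("probe selection keeps the probe most correlated with RNA-seq", {
  samples <- paste0("s", 1:6)
  ref <- rbind(gA = c(1, 2, 3, 4, 5, 6))
  colnames(ref) <- samples
  intensity <- rbind(pA1 = c(6, 5, 4, 3, 2, 1),
                     pA2 = c(1.1, 2.2, 2.9, 4.3, 4.8, 6.1))
  colnames(intensity) <- samples
  sel <- select_probes(intensity, c(pA1 = "gA", pA2 = "gA"), ref)
  expect_identical(unname(sel["gA"]), "pA2")
})
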