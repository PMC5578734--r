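make_peptides <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], peptide_id = r[[2]],
               intensity = r[[3]], is_unique = r[[4]])))
}

test_that("top-3 quantification sums the three strongest unique peptides", {
  pep <- make_peptides(
    list("A", "p1", 5, TRUE), list("A", "p2", 4, TRUE),
    list("A", "p3", 3, TRUE), list("A", "p4", 2, TRUE),
    list("B", "p5", 7, TRUE), list("B", "p6", 1, TRUE),
    list("C", "p7", 9, FALSE))
  prof <- suppressMessages(quantify_top3(pep))
  expect_equal(unname(prof$abundances["A"]), 12)   # top 3 of 5,4,3,2
  expect_equal(unname(prof$abundances["B"]), 8)    # fewer than 3: sum all
  expect_false("C" %in% names(prof$abundances))    # no unique peptide
  expect_identical(attr(prof, "dropped"), "C")
})

test_that("top-3 quantification matches a brute-force oracle on random tables", {
  withr::with_seed(7, {
    for (i in 1:10) {
      pep <- data.frame(
        protein_id = sample(LETTERS[1:6], 60, replace = TRUE),
        peptide_id = paste0("p", 1:60),
        intensity = rlnorm(60, 3, 1),
        is_unique = runif(60) < 0.8)
      got <- suppressMessages(quantify_top3(pep))$abundances
      want <- top3_oracle(pep)
      expect_equal(got[sort(names(got))], want[sort(names(want))])
    }
  })
})

test_that("fraction normalisation is a scale-invariant partition of unity", {
  p <- proteome_profile(c(a = 3, b = 1))
  f <- to_fractions(p)
  expect_equal(unname(f$abundances), c(0.75, 0.25))
  expect_equal(sum(f$abundances), 1, tolerance = 1e-12)
  p7 <- proteome_profile(p$abundances * 7)
  expect_equal(to_fractions(p7)$abundances, f$abundances)
  expect_error(to_fractions(proteome_profile(c(a = 0, b = 0))), "all-zero")
})

test_that("reference calibration applies a single median factor", {
  ab <- withr::with_seed(31, setNames(rlnorm(60, 5, 1), paste0("P", 1:60)))
  prof <- proteome_profile(ab)
  expect_equal(attr(calibrate_to_reference(prof, ab), "factor"), 1)
  expect_equal(attr(calibrate_to_reference(prof, ab * 2), "factor"), 2)
  # heterogeneous ratios: factor is the median ratio
  ratios <- seq(1.5, 4.5, length.out = 60)
  cal <- calibrate_to_reference(prof, ab * ratios)
  expect_equal(attr(cal, "factor"), median(ratios))
  expect_equal(cal$abundances, ab * median(ratios))
  expect_error(calibrate_to_reference(prof, ab[1:10]), "10 shared")
})

test_that("group fractions are linear and conserve total mass", {
  sim <- simulate_proteome(growth_rates = c(0.2, 0.5), noise_cv = 0.05,
                           n_replicates = 1, seed = 5)
  p <- sim$profiles[[1]]
  map <- sim$group_map
  all_grp <- data.frame(protein_id = names(p$abundances), group = "all")
  expect_equal(group_fraction(p, all_grp, "all"), 1, tolerance = 1e-9)
  expect_error(group_fraction(p, map, "nonexistent"), "unknown group")
  # additivity over disjoint groups and conservation over the partition
  fr <- group_fractions(p, map, residual = NULL)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  ab <- group_fraction(p, map, "ribosome") + group_fraction(p, map, "glycolysis")
  merged <- map
  merged$group[merged$group %in% c("ribosome", "glycolysis")] <- "both"
  expect_equal(group_fraction(p, merged, "both"), ab, tolerance = 1e-12)
})

test_that("overlapping assignments report duplicated mass independently", {
  p <- to_fractions(proteome_profile(c(a = 1, b = 1, c = 2)))
  map <- data.frame(protein_id = c("a", "b", "b", "c"),
                    group = c("g1", "g1", "g2", "g2"))
  expect_equal(group_fraction(p, map, "g1"), 0.5)
  expect_equal(group_fraction(p, map, "g2"), 0.75)  # b counted in both
})

test_that("correlation matrix is symmetric with unit diagonal", {
  sim <- simulate_proteome(growth_rates = c(0.2, 0.4, 0.6),
                           n_replicates = 2, seed = 9)
  m <- proteome_correlation(sim$profiles)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("duplicate profiles correlate at 1 and permuted profiles near 0", {
  withr::with_seed(13, {
    ab <- setNames(rlnorm(2000, -7, 1.5), paste0("P", 1:2000))
    ab <- ab / sum(ab)
    p1 <- proteome_profile(ab, "c1", "1", fractional = TRUE)
    p2 <- proteome_profile(ab, "c1", "2", fractional = TRUE)
    perm <- proteome_profile(setNames(sample(ab), names(ab)), "c2", "1",
                             fractional = TRUE)
    m <- proteome_correlation(list(p1, p2, perm))
    expect_equal(m[1, 2], 1)
    expect_lt(abs(m[1, 3]), 0.1)
  })
})

test_that("distinct sector tilt regimes produce correlation blocks", {
  rules_b <- default_tilt_rules()
  rules_b$intercept[rules_b$group == "mitochondria"] <- 0.02
  rules_b$slope[rules_b$group == "mitochondria"] <- 0.25
  rules_b$intercept[rules_b$group == "glycolysis"] <- 0.30
  xs <- seq(0.2, 0.6, length.out = 4)
  block_a <- simulate_proteome(growth_rates = xs, n_replicates = 1, seed = 21)
  block_b <- simulate_proteome(growth_rates = xs, n_replicates = 1, seed = 21,
                               tilt_rules = rules_b)
  m <- proteome_correlation(c(block_a$profiles, block_b$profiles))
  ia <- 1:4; ib <- 5:8
  within <- c(m[ia, ia][upper.tri(diag(4))], m[ib, ib][upper.tri(diag(4))])
  between <- as.vector(m[ia, ib])
  expect_gt(mean(within), mean(between))
})

test_that("mean-normalised log2 matrix has unit row means on the 2^ scale", {
  sim <- simulate_proteome(growth_rates = c(0.2, 0.4, 0.6), n_replicates = 1,
                           seed = 17)
  m <- log2_mean_normalized(sim$profiles)
  expect_equal(unname(rowMeans(2^m)), rep(1, nrow(m)), tolerance = 1e-9)
  # constant protein gives a zero row; a doubled condition gives log2(2m/mean)
  profs <- list(
    proteome_profile(c(k = 2, d = 2), "c1"),
    proteome_profile(c(k = 2, d = 1), "c2"),
    proteome_profile(c(k = 2, d = 1), "c3"))
  m2 <- log2_mean_normalized(profs)
  expect_equal(unname(m2["k", ]), rep(0, 3))
  expect_equal(unname(m2["d", 1]), log2(2 / mean(c(2, 1, 1))))
})
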