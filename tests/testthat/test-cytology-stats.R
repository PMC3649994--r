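test_that("equal-length zone assignment handles boundaries", {
  pos <- (seq_len(100) - 0.5) / 100
  z <- assign_zones(pos, 5)
  expect_equal(as.vector(table(z)), rep(20L, 5))
  expect_equal(assign_zones(0, 5), 1L)
  expect_equal(assign_zones(1, 5), 5L)
  expect_error(assign_zones(c(0.5, 1.2), 5), class = "netrack_invalid_input")
  # floor-arithmetic oracle on random positions
  set.seed(2)
  p <- stats::runif(200)
  expect_equal(assign_zones(p, 6), pmin(floor(p * 6) + 1L, 6L))
})

test_that("pairing scores follow the one-focus criterion", {
  expect_equal(score_pairing(matrix(c(1, 1, 1), 1)), "paired")
  two_far <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(score_pairing(two_far, 0.75), "unpaired")
  at_threshold <- rbind(c(0, 0, 0), c(0.75, 0, 0))
  expect_equal(score_pairing(at_threshold, 0.75), "paired")   # inclusive
  expect_warning(flagged <- score_pairing(matrix(0, 3, 3)), "3 signals")
  expect_true(is.na(flagged))
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  expect_equal(pairing_contingency_test(5, 10, 5, 10), 1)
  expect_equal(pairing_contingency_test(10, 10, 0, 10),
               fisher_enum_p(10, 10, 0, 10), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:50) {
    n_a <- sample(1:10, 1); n_b <- sample(1:10, 1)
    a <- sample(0:n_a, 1); b <- sample(0:n_b, 1)
    expect_equal(pairing_contingency_test(a, n_a, b, n_b),
                 fisher_enum_p(a, n_a, b, n_b), tolerance = 1e-9)
    # two-sided: invariant to swapping the groups
    expect_equal(pairing_contingency_test(a, n_a, b, n_b),
                 pairing_contingency_test(b, n_b, a, n_a), tolerance = 1e-12)
  }
  expect_error(pairing_contingency_test(1, 0, 0, 5),
               class = "netrack_invalid_config")
})

test_that("DAPI-body to bivalent conversion reproduces the karyotype identity", {
  expect_equal(bivalents_from_bodies(7.2), 4.8)
  expect_equal(bivalents_from_bodies(11.9), 0.1)
  expect_equal(bivalents_from_bodies(8.2), 3.8)
  expect_equal(bivalents_from_bodies(10.2), 1.8)
  expect_equal(bivalents_from_bodies(6), 6)
  expect_equal(bivalents_from_bodies(12), 0)
  # involution: bodies(bivalents(m)) = m
  for (m in seq(6, 12, 0.3))
    expect_equal(bodies_from_bivalents(bivalents_from_bodies(m)), m)
  expect_error(bivalents_from_bodies(5), class = "netrack_invalid_input")
  expect_error(bivalents_from_bodies(12.5), class = "netrack_invalid_input")
})

test_that("Mann-Whitney p-values match exact enumeration on small samples", {
  expect_equal(compare_body_counts(c(6, 6, 6), c(6, 6, 6))$p.value, 1)
  # all 20 arrangements of {6,6,6} vs {12,12,12}
  expect_equal(compare_body_counts(c(6, 6, 6), c(12, 12, 12))$p.value,
               mw_enum_p(c(6, 6, 6), c(12, 12, 12)), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(6:12, n1, replace = TRUE)
    b <- sample(6:12, n2, replace = TRUE)
    expect_equal(compare_body_counts(a, b)$p.value, mw_enum_p(a, b),
                 tolerance = 1e-12)
  }
  # untied data agree with the reference exact rank-sum distribution
  for (i in 1:10) {
    a <- sample(1:100, 5); b <- setdiff(sample(1:100, 12), a)[1:5]
    expect_equal(compare_body_counts(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(compare_body_counts(numeric(0), 1:3),
               class = "netrack_invalid_input")
})

test_that("large tied samples use the corrected normal approximation", {
  set.seed(9)
  a <- sample(6:12, 52, replace = TRUE, prob = stats::dbinom(6:0, 6, 0.8))
  b <- sample(6:12, 30, replace = TRUE, prob = stats::dbinom(6:0, 6, 0.02))
  got <- compare_body_counts(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE)$p.value)
  expect_equal(got$p.value, ref, tolerance = 1e-6)
  expect_match(got$method, "normal approximation")
  expect_lt(got$p.value, 0.001)
})

test_that("per-zone count histograms tally and normalize correctly", {
  zt <- data.frame(nucleus_id = 1:6, zone = c(1, 1, 1, 2, 2, 2),
                   focus_count = c(0, 0, 0, 6, 7, 10))
  h <- count_category_histogram(zt, "sun1_focus")
  z1 <- h[h$zone == 1, ]
  expect_equal(z1$percent[z1$bin == "0"], 100)
  z2 <- h[h$zone == 2, ]
  expect_equal(z2$percent[z2$bin == "6-10"], 100)
  for (z in 1:2) expect_equal(sum(h$percent[h$zone == z]), 100)
  # RAD-51 stretches form their own category
  zr <- data.frame(nucleus_id = 1:4, zone = 1,
                   rad51_count = c(0, 2, 5, 0),
                   stretch = c(FALSE, FALSE, FALSE, TRUE))
  hr <- count_category_histogram(zr, "rad51", breaks = c(0, 1, 4))
  expect_equal(hr$percent[hr$bin == "stretch"], 25)
  expect_equal(sum(hr$percent), 100)
})

test_that("mutant-like focus counts concentrate in the 6-10 bin", {
  zt <- simulate_zone_scores(cyto_config(
    foci_count_dist = list(focus_lambda = 7.5, patch_lambda = 0.5),
    n_per_zone = 200, seed = 11))
  h <- count_category_histogram(zt[zt$zone == 3, ], "sun1_focus")
  modal <- h$bin[which.max(h$percent)]
  expect_equal(modal, "6-10")
  expect_gt(max(h$percent), 45)
})

test_that("synapsis association classes follow the four-way scheme", {
  sc1 <- cbind(y = seq(0, 2, 0.5), x = 0)
  sc2 <- cbind(y = seq(0, 2, 0.5), x = 2)
  # two signals, each near a different SC stretch
  r <- classify_synapsis_association(rbind(c(0.5, 0.05), c(1.0, 1.95)),
                                     list(sc1, sc2), 0.3)
  expect_equal(r$association_class, "both-on-different-SC")
  # one paired signal on one stretch
  r1 <- classify_synapsis_association(rbind(c(1, 0.1)), list(sc1, sc2), 0.3)
  expect_equal(r1$association_class, "single-SC-paired")
  r2 <- classify_synapsis_association(rbind(c(0.5, 0.05), c(1.0, 1.0)),
                                      list(sc1, sc2), 0.3)
  expect_equal(r2$association_class, "one-on-SC")
  r3 <- classify_synapsis_association(rbind(c(0.5, 1.0)), list(sc1, sc2), 0.3)
  expect_equal(r3$association_class, "none-on-SC")
  # constructed 40-nucleus population with a 37/3 split is tallied exactly
  nuclei <- c(
    replicate(37, list(him8_coords = rbind(c(0.5, 0.05), c(1.0, 1.95)),
                       sc_polylines = list(sc1, sc2)), simplify = FALSE),
    replicate(3, list(him8_coords = rbind(c(0.5, 0.05), c(1.0, 1.0)),
                      sc_polylines = list(sc1, sc2)), simplify = FALSE))
  tab <- summarize_synapsis_associations(nuclei)
  expect_equal(unname(tab[["both-on-different-SC"]]), 37L)
  expect_equal(unname(tab[["one-on-SC"]]), 3L)
})

test_that("respiration rates normalize per worm and compare by t-test", {
  rec <- data.frame(well_id = 1:2, genotype = c("a", "b"),
                    worms_in_well = c(55, 50))
  for (i in 1:7) rec[[paste0("m", i)]] <- c(550, 500)
  out <- normalize_respiration(rec)
  expect_equal(out$per_well$per_worm_rate, c(10, 10))
  # identical group distributions give p near 1
  set.seed(14)
  base <- stats::rnorm(10, 10, 1)
  rec2 <- data.frame(well_id = 1:20,
                     genotype = rep(c("a", "b"), each = 10),
                     worms_in_well = 50)
  for (i in 1:7) rec2[[paste0("m", i)]] <- rep(base, 2) * 50
  out2 <- normalize_respiration(rec2)
  expect_gt(out2$p.value, 0.99)
  expect_equal(nrow(out2$by_genotype), 2L)
  # clearly separated groups are significant in nearly all draws
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    rates <- c(stats::rnorm(10, 10, 0.5), stats::rnorm(10, 7.5, 0.5))
    rec3 <- rec2
    for (i in 1:7) rec3[[paste0("m", i)]] <- rates * 50
    if (normalize_respiration(rec3)$p.value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  rec_bad <- rec; rec_bad$worms_in_well[1] <- 0
  expect_error(normalize_respiration(rec_bad), class = "netrack_invalid_input")
})
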