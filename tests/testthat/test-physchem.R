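test_that("property scales have the canonical values", {
  ch <- property_scale("charge")
  expect_identical(unname(ch[c("K", "R", "D", "E", "A", "H")]),
                   c(1, 1, -1, -1, 0, 0))
  expect_true(all(ch %in% c(-1, 0, 1)))
  ch_h <- property_scale("charge", histidine_charge = 1)
  expect_identical(unname(ch_h["H"]), 1)

  kd <- property_scale("hydropathy")
  expect_identical(unname(kd[c("I", "R", "A", "W")]),
                   c(4.5, -4.5, 1.8, -0.9))
  expect_length(kd, 20L)
})

test_that("property values map residues and missing data", {
  aln <- amino_alignment(c(a = "KDA-X", b = "IRAAA"))
  ch <- property_values(aln, property_scale("charge"))
  expect_identical(unname(ch["a", ]), c(1, -1, 0, NA, NA))
  kd <- property_values(aln, property_scale("hydropathy"))
  expect_identical(unname(kd["b", 1:2]), c(4.5, -4.5))

  # unknown residue (bypassing the constructor) names taxon and column
  fake <- structure(list(taxa = c("a", "b"),
                         sequences = c(a = "KZA", b = "AAA"),
                         n_sites = 3L),
                    class = "amino_alignment")
  expect_error(property_values(fake, property_scale("charge")),
               "'Z'.*'a'.*column 2")
})

test_that("group delta profile: hand computation, symmetry, NA policy", {
  aln <- amino_alignment(c(r1 = "KKA", r2 = "KDA", n1 = "EKA",
                           n2 = "DK-"))
  g <- taxon_groups(c("r1", "r2"), c("n1", "n2"))
  vals <- property_values(aln, property_scale("charge"))
  prof <- group_delta_profile(vals, g)
  # site 1: resistant mean (+1+1)/2 = 1, non-resistant (-1-1)/2 = -1
  expect_equal(prof$delta[1], 2)
  expect_equal(prof$abs_delta[1], 2)
  # site 2: (1 + -1)/2 - (1+1)/2 = -1
  expect_equal(prof$delta[2], -1)
  # site 3: gap excluded, means over informative residues only
  expect_identical(prof$n_non_resistant[3], 1L)
  expect_equal(prof$delta[3], 0)

  # swapping groups flips the sign, |delta| invariant
  prof_sw <- group_delta_profile(vals,
                                 taxon_groups(c("n1", "n2"),
                                              c("r1", "r2")))
  expect_equal(prof_sw$delta, -prof$delta)
  expect_equal(prof_sw$abs_delta, prof$abs_delta)

  # identical groups -> all zero
  aln_id <- amino_alignment(c(r1 = "KDA", r2 = "KDA", n1 = "KDA",
                              n2 = "KDA"))
  vals_id <- property_values(aln_id, property_scale("charge"))
  prof_id <- group_delta_profile(vals_id, g)
  expect_true(all(prof_id$delta == 0))

  # a group with no informative residue at a site -> NA
  aln_na <- amino_alignment(c(r1 = "-KA", r2 = "XKA", n1 = "KKA",
                              n2 = "KKA"))
  prof_na <- group_delta_profile(
    property_values(aln_na, property_scale("charge")), g)
  expect_true(is.na(prof_na$delta[1]))
})

test_that("rank-sum test: separation, symmetry, exact vs enumeration", {
  # complete separation: all of a below b
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(rs$W, 0)
  expect_equal(rs$p_value, 0.1, tolerance = 1e-12)  # 2/C(6,3)*2... exact

  # identical multisets: W = n1 n2 / 2
  rs2 <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rs2$W, 4.5)

  # W bounds
  expect_true(rs$W >= 0 && rs$W <= rs$n1 * rs$n2)

  # exact p agrees with exhaustive enumeration for untied samples
  set.seed(5)
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      x <- sample(seq_len(50), n1 + n2)  # distinct -> no ties
      a <- x[seq_len(n1)]
      b <- x[-seq_len(n1)]
      got <- rank_sum_test(a, b)
      ora <- oracle_rank_sum(a, b)
      expect_equal(got$W, ora$W)
      expect_equal(got$p_value, ora$p, tolerance = 1e-10,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("G-test: reference counts, invariances, degenerate tables", {
  g <- g_test(c(3, 9, 4, 189))
  expect_equal(round(g$G, 2), 8.61)
  expect_identical(g$df, 1L)

  # transpose invariance
  tab <- matrix(c(3, 9, 4, 189), 2, 2, byrow = TRUE)
  expect_equal(g_test(t(tab))$G, g$G, tolerance = 1e-12)

  # proportional rows -> G = 0
  expect_equal(g_test(c(10, 10, 5, 5))$G, 0, tolerance = 1e-12)
  expect_equal(g_test(c(2, 6, 5, 15))$G, 0, tolerance = 1e-12)

  # zero cells contribute zero but zero margins are errors
  expect_gt(g_test(c(0, 10, 5, 5))$G, 0)
  expect_error(g_test(c(0, 0, 5, 5)), "zero margin")
})

test_that("sliding window: identity, constants, truncated edges", {
  expect_identical(sliding_window(c(4, 2, 7), 1L), c(4, 2, 7))
  expect_equal(sliding_window(rep(3, 10), 5L), rep(3, 10))
  expect_equal(sliding_window(c(0, 3, 0), 3L), c(1.5, 1.0, 1.5))
  expect_equal(sliding_window(c(1, NA, 4), 3L), c(1, 2.5, 4))
  expect_error(sliding_window(1:10, 4L), "odd")
})

test_that("distance to binding sites matches a brute-force oracle", {
  aln <- amino_alignment(c(Mus = strrep("A", 200),
                           Other = strrep("A", 200)))
  coord <- build_coordinate_map(aln, "Mus", 524)
  b <- binding_sites()
  d <- distance_to_binding(coord, b)
  expect_identical(d$distance[coord$ref_pos == 628], 0L)
  expect_identical(d$distance[coord$ref_pos == 648], 5L)
  brute <- vapply(coord$ref_pos, function(p) {
    min(abs(p - as.integer(b)))
  }, numeric(1))
  expect_identical(d$distance, as.integer(brute))
})

test_that("permutation slope test: trivial nulls, determinism, signal", {
  x <- c(0, 1, 2, 3, 4, 5, 8, 13, 21)
  # constant response: observed and every null slope are zero
  res <- permutation_slope_test(rep(2, 9), x, n_perm = 50, seed = 1)
  expect_equal(res$observed_slope, 0, tolerance = 1e-12)
  expect_true(all(abs(res$null_slopes) < 1e-12))
  expect_false(res$significant)

  # deterministic under a fixed seed
  y <- c(5, 4, 3.5, 3, 2, 1.5, 1, 0.5, 0.2)
  r1 <- permutation_slope_test(y, x, n_perm = 200, seed = 11)
  r2 <- permutation_slope_test(y, x, n_perm = 200, seed = 11)
  expect_identical(r1$null_slopes, r2$null_slopes)

  # strong decreasing structure is detected
  expect_true(r1$significant)
  expect_lt(r1$observed_slope, r1$ci[1])

  # binding-site exclusion drops the flagged rows
  bf <- c(TRUE, rep(FALSE, 8))
  r3 <- permutation_slope_test(y, x, binding_flag = bf, n_perm = 50,
                               include_binding = FALSE, seed = 2)
  expect_identical(r3$n_sites, 8L)
  expect_error(permutation_slope_test(y, rep(3, 9), n_perm = 10),
               "slope undefined")
  expect_error(permutation_slope_test(y[1:2], x[1:2], n_perm = 10),
               "fewer than 3")
})
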