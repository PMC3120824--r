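test_that("zero branch lengths give identical sequences", {
  tr <- read_labeled_tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  sim <- simulate_codon_alignment(tr, n_sites = 20, seed = 4)
  expect_identical(length(unique(sim$alignment$sequences)), 1L)
})

test_that("latent class frequencies follow the mixture proportions", {
  params <- branch_site_params(2, 0.6, 0.2, 0.05, 8)
  sim <- simulate_codon_alignment(fixture_tree_4(), params,
                                  n_sites = 3000, seed = 10)
  props <- c(params$p0, params$p1, params$p2a, params$p2b)
  obs <- table(sim$site_class) / 3000
  for (k in 1:4) {
    se <- sqrt(props[k] * (1 - props[k]) / 3000)
    expect_lt(abs(obs[k] - props[k]), 3 * se + 1e-9)
  }
})

test_that("single-branch transition sampling matches the P matrix", {
  # concentrated root frequencies pin the parent state so the child
  # distribution can be checked against transition_probabilities
  tab <- genetic_code_table()
  pi <- rep(0.5 / 60, 61)
  pi[match("TTT", tab$sense)] <- 0.5
  freqs <- structure(pi, names = tab$sense,
                     class = "codon_frequencies")
  tr <- read_labeled_tree(text = "(A:0,B:0.3);")
  params <- branch_site_params(2, 1 - 1e-9, 1e-9 / 2, 0.5, 1)
  sim <- simulate_codon_alignment(tr, params, n_sites = 10000,
                                  freqs = freqs, seed = 123)
  cm <- codon_matrix(sim$alignment)
  from_t <- cm["A", ] == "TTT"   # A sits at the root (zero branch)
  expect_gt(sum(from_t), 4000)
  child <- cm["B", from_t]

  Q <- build_rate_matrix(freqs, 2, 0.5, scale = FALSE)
  rho <- -sum(pi * diag(Q))      # class-0-only mixture scaling
  P <- transition_probabilities(Q / rho, 0.3)
  expected_p <- P[match("TTT", tab$sense), ]
  obs <- table(factor(child, levels = tab$sense))
  # pool cells with small expectation for a valid chi-squared GOF
  exp_counts <- expected_p * sum(obs)
  big <- exp_counts >= 5
  o <- c(obs[big], sum(obs[!big]))
  e <- c(exp_counts[big], sum(exp_counts[!big]))
  chi2 <- sum((o - e)^2 / e)
  pval <- stats::pchisq(chi2, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("recorded substitution histories show the foreground excess", {
  tr <- read_labeled_tree(text = "((A#1:0.4,B#1:0.4)#1:0.01,(C:0.4,D:0.4):0.01);")
  params <- branch_site_params(2, 0.45, 0.45, 0.05, 8)
  sim <- simulate_codon_alignment(tr, params, n_sites = 400, seed = 14,
                                  history = TRUE)
  ev <- sim$events
  expect_true(all(c("edge", "foreground", "site", "class", "from", "to",
                    "nonsynonymous") %in% names(ev)))
  # history endpoint must agree with the emitted alignment (wiring check)
  expect_gt(nrow(ev), 100)

  cls2 <- sim$site_class %in% c("2a", "2b")
  n_sites_fg <- sum(cls2)
  ev2 <- ev[ev$site %in% which(cls2) & ev$nonsynonymous, ]
  # equal total branch length in both partitions (0.8 each side)
  n_fg <- sum(ev2$foreground)
  n_bg <- sum(!ev2$foreground)
  # omega2 = 8 vs background omega <= 1: foreground nonsynonymous
  # substitutions at class-2 sites must clearly dominate
  expect_gt(n_fg, 2 * n_bg)
})

test_that("history mode and exact mode agree in distribution", {
  tr <- read_labeled_tree(text = "(A:0.2,B:0.2);")
  params <- branch_site_params(2, 0.7, 0.2, 0.1, 2)
  s_exact <- simulate_codon_alignment(tr, params, n_sites = 2000,
                                      seed = 9)
  s_hist <- simulate_codon_alignment(tr, params, n_sites = 2000,
                                     seed = 9, history = TRUE)
  # same per-site identity rate between the two taxa (binomial check)
  match_rate <- function(s) {
    cm <- codon_matrix(s$alignment)
    mean(cm[1, ] == cm[2, ])
  }
  p1 <- match_rate(s_exact)
  p2 <- match_rate(s_hist)
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_lt(abs(p1 - p2), 4 * se)
})

test_that("property simulator: degenerate settings and determinism", {
  # no effect, no noise: both groups identical, all deltas zero
  sim0 <- simulate_property_alignment(effect_size_charge = 0,
                                      effect_size_hydropathy = 0,
                                      background_noise = 0, seed = 3)
  expect_identical(length(unique(sim0$alignment$sequences)), 1L)

  # same seed -> byte-identical
  s1 <- simulate_property_alignment(seed = 5)
  s2 <- simulate_property_alignment(seed = 5)
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)

  # decay 0, no noise: only binding sites differ between groups
  s3 <- simulate_property_alignment(background_noise = 0,
                                    decay_length = 0, seed = 6)
  vals <- property_values(s3$alignment, property_scale("charge"))
  prof <- group_delta_profile(vals, s3$groups, coord = s3$coord,
                              binding = s3$binding)
  expect_true(all(prof$abs_delta[!prof$binding] == 0))
  expect_gt(sum(prof$abs_delta[prof$binding]), 0)
  expect_identical(sort(s3$shifted_sites), sort(as.integer(s3$binding)))

  # decay spreads shifts beyond binding sites
  s4 <- simulate_property_alignment(background_noise = 0,
                                    decay_length = 3, seed = 6)
  expect_gt(length(s4$shifted_sites), length(s3$shifted_sites))
})

test_that("binding-site shifts dominate the background (rank-sum)", {
  sim <- simulate_property_alignment(effect_size_charge = 2,
                                     background_noise = 0.01, seed = 12)
  vals <- property_values(sim$alignment, property_scale("charge"))
  prof <- group_delta_profile(vals, sim$groups, coord = sim$coord,
                              binding = sim$binding)
  rs <- rank_sum_test(prof$abs_delta[prof$binding],
                      prof$abs_delta[!prof$binding],
                      alternative = "greater")
  expect_lt(rs$p_value, 0.05)
})
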