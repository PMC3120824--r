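params_default <- branch_site_params(2, 0.6, 0.2, 0.1, 3)

test_that("single-leaf likelihood is the codon's equilibrium frequency", {
  tr <- read_labeled_tree(text = "(A:0);")
  aln <- codon_alignment(c(A = "TTT"))
  sl <- site_likelihoods(aln, tr, params_default,
                         uniform_codon_frequencies())
  expect_equal(unname(sl$class_lik[, 1]), rep(1 / 61, 4),
               tolerance = 1e-12)
})

test_that("an all-missing column has mixture likelihood 1", {
  tr <- fixture_tree_4()
  aln <- codon_alignment(c(A = "TTTNNN", B = "TTC---", C = "TTGNNN",
                           D = "TTANNN"))
  sl <- site_likelihoods(aln, tr, params_default)
  expect_equal(sl$mixture_lik[2], 1, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on the 4-taxon tree", {
  sim <- fixture_alignment(n_sites = 6, seed = 7)
  aln <- sim$alignment
  tr <- fixture_tree_4()
  freqs <- estimate_f3x4(aln)
  sl <- site_likelihoods(aln, tr, params_default, freqs)
  for (site in c(1, 3, 5)) {
    for (k in 1:4) {
      cls <- c("0", "1", "2a", "2b")[k]
      bf <- oracle_site_likelihood(aln, tr, params_default, freqs,
                                   site, cls)
      expect_equal(unname(sl$class_loglik[k, site]), log(bf),
                   tolerance = 1e-10,
                   label = sprintf("site %d class %s", site, cls))
    }
  }
})

test_that("pruning equals enumeration on random trees up to 5 leaves", {
  # 3-5 leaves; the 5-leaf case uses a polytomy so the enumeration
  # oracle stays at three internal nodes (61^3 assignments)
  topologies <- c(
    "((A:0.3,B:0.1)#1:0.2,C:0.4);",
    "((A:0.1,B:0.2,C:0.3)#1:0.1,(D:0.2,E:0.25):0.15);",
    "((A:0.15,B#1:0.2):0.1,(C:0.3,D:0.1):0.2);")
  par_sets <- list(branch_site_params(1.5, 0.5, 0.3, 0.2, 2),
                   branch_site_params(4, 0.8, 0.1, 0.03, 9))
  for (nwk in topologies) {
    tr <- read_labeled_tree(text = nwk)
    sim <- simulate_codon_alignment(tr, par_sets[[1]], n_sites = 4,
                                    seed = 99)
    freqs <- estimate_f3x4(sim$alignment)
    for (params in par_sets) {
      sl <- site_likelihoods(sim$alignment, tr, params, freqs)
      for (site in c(1, 4)) {
        for (k in 1:4) {
          cls <- c("0", "1", "2a", "2b")[k]
          bf <- oracle_site_likelihood(sim$alignment, tr, params,
                                       freqs, site, cls)
          expect_equal(unname(sl$class_loglik[k, site]), log(bf),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("null-model structure: class 2b collapses to class 1, and the
           mixture is labeling-invariant when class 2 is empty", {
  # Under omega2 = 1 the null model *retains* the foreground/background
  # partition through class 2a (omega0 on background, 1 on foreground),
  # so lnL0 legitimately depends on the labeling -- the reference
  # analysis reports different lnL0 for its two schemes.  What is
  # invariant: class 2b equals class 1 exactly, and with no class-2 mass
  # (p0 + p1 = 1) the whole mixture ignores the labeling.
  sim <- fixture_alignment(n_sites = 25, seed = 3)
  aln <- sim$alignment
  null_params <- branch_site_params(2, 0.6, 0.2, 0.1, omega2 = 1)
  labelings <- list(
    fixture_tree_4(),
    read_labeled_tree(
      text = "((A#1:0.2,B:0.3):0.1,(C:0.25,D#1:0.15)#1:0.05);"))
  for (tr in labelings) {
    sl <- site_likelihoods(aln, tr, null_params)
    expect_equal(unname(sl$class_loglik["2b", ]),
                 unname(sl$class_loglik["1", ]), tolerance = 1e-12)
  }
  # no class-2 mass: labeling cannot matter
  flat <- branch_site_params(2, 0.75, 0.25, 0.1, omega2 = 1)
  lls <- vapply(labelings, function(tr) {
    sum(site_likelihoods(aln, tr, flat)$mixture_loglik)
  }, numeric(1))
  expect_equal(lls[2], lls[1], tolerance = 1e-10)
})

test_that("mixture proportions always sum to one", {
  for (p in list(c(0.6, 0.2), c(0.9, 0.05), c(0.1, 0.85), c(0.5, 0.5))) {
    bp <- branch_site_params(2, p[1], p[2], 0.1, 2)
    expect_equal(bp$p0 + bp$p1 + bp$p2a + bp$p2b, 1, tolerance = 1e-12)
  }
  expect_error(branch_site_params(2, 0.7, 0.4, 0.1, 2))
  expect_error(branch_site_params(2, 0.6, 0.2, 1.2, 2))
})

test_that("taxon mismatch between alignment and tree is caught", {
  aln <- codon_alignment(c(A = "TTT", B = "TTC", Z = "TTG"))
  expect_error(
    site_likelihoods(aln, read_labeled_tree(text = "(A:0.1,(B:0.1,C:0.1):0.1);"),
                     params_default),
    "mismatch")
})
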