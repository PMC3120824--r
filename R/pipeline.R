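#' Write / read a branch-site fit as JSON
#'
#' Persists parameter MLEs, log-likelihood, convergence flag and the
#' fitted tree (Newick with foreground tags) so every downstream report
#' number is reproducible from the fit files alone.
#'
#' @param fit A `branch_site_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "branch_site_fit"))
  obj <- list(
    model = fit$model,
    lnL = fit$lnL,
    converged = fit$converged,
    n_free_params = fit$n_free_params,
    n_sites = fit$n_sites,
    params = fit$params[c("kappa", "p0", "p1", "p2a", "p2b", "omega0",
                          "omega1", "omega2")],
    rho = fit$rho,
    freqs = as.list(stats::setNames(as.numeric(fit$freqs),
                                    names(fit$freqs))),
    tree = write_labeled_tree(fit$tree)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @param path Path of a fit JSON written by [write_fit_json()].
#' @return `read_fit_json`: a `branch_site_fit` (without engine state).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- branch_site_params(obj$params$kappa, obj$params$p0,
                               obj$params$p1, obj$params$omega0,
                               obj$params$omega2)
  freqs <- structure(as.numeric(obj$freqs), names = names(obj$freqs),
                     class = "codon_frequencies")
  structure(
    list(params = params, lnL = obj$lnL, converged = obj$converged,
         n_free_params = obj$n_free_params, model = obj$model,
         tree = read_labeled_tree(text = obj$tree), freqs = freqs,
         rho = obj$rho, n_sites = obj$n_sites),
    class = "branch_site_fit"
  )
}

#' Branch-site selection scan over one or two foreground schemes
#'
#' For each foreground scheme: fit the null model (branch lengths
#' optimized jointly unless `fix_blens = TRUE`), fix its branch lengths
#' and fit the alternative, run the LRT, and compute BEB site posteriors.
#' Output mirrors the usual branch-site report: a per-scheme parameter
#' table (site-class proportions and omegas under both models) and a site
#' table of BEB posteriors restricted to `p_selected > report_threshold`.
#'
#' @param aln A `codon_alignment`.
#' @param trees Named list of `selection_tree`s, one per foreground
#'   scheme (e.g. with and without the untested aquatic lineage).
#' @param coord Optional `coordinate_map` on `translate_alignment(aln)`.
#' @param binding Optional [binding_sites()] for the enrichment counts.
#' @param fix_blens Fix branch lengths at the input tree's values for the
#'   null fit too (default FALSE).
#' @param thresholds Posterior thresholds used for flags/counts
#'   (default `c(0.50, 0.95)`).
#' @param report_threshold Sites enter the site table when
#'   `p_selected` exceeds this (default 0.50).
#' @param n_restarts,seed,control Passed to [fit_branch_site()].
#' @param out_dir Optional directory: writes per-scheme fit JSONs, a
#'   `model_table.tsv` and `sites_<scheme>.tsv`.
#' @return A list per scheme: `fit_null`, `fit_alt`, `lrt`, `posteriors`,
#'   `model_table`, `site_table`, and (when `coord` and `binding` are
#'   given) `enrichment` (counts plus [g_test()] at each threshold).
#' @export
run_selection_scan <- function(aln, trees, coord = NULL, binding = NULL,
                               fix_blens = FALSE,
                               thresholds = c(0.50, 0.95),
                               report_threshold = 0.50,
                               n_restarts = 5, seed = 2011,
                               control = list(), out_dir = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), is.list(trees))
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    stop("'trees' must be a named list of foreground schemes")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  freqs <- estimate_f3x4(aln)
  results <- list()
  for (scheme in names(trees)) {
    tree <- trees[[scheme]]
    fit0 <- fit_branch_site(aln, tree, model = "null", freqs = freqs,
                            fix_blens = fix_blens,
                            n_restarts = n_restarts, seed = seed,
                            control = control)
    tree_fixed <- update_branch_lengths(tree, fit0)
    fitA <- fit_branch_site(aln, tree_fixed, model = "alternative",
                            freqs = freqs, fix_blens = TRUE,
                            n_restarts = n_restarts, seed = seed,
                            control = control)
    if (fitA$lnL < fit0$lnL - 1e-6) {
      # restart the alternative from the null solution
      fitA2 <- fit_branch_site(
        aln, tree_fixed, model = "alternative", freqs = freqs,
        fix_blens = TRUE, n_restarts = 0, seed = seed,
        start = list(kappa = fit0$params$kappa, p0 = fit0$params$p0,
                     p1 = fit0$params$p1, omega0 = fit0$params$omega0,
                     omega2 = 1.0001),
        control = control)
      if (fitA2$lnL > fitA$lnL) fitA <- fitA2
    }
    lrt <- likelihood_ratio_test(fit0, fitA)
    post <- tryCatch(
      beb_site_posteriors(aln, tree_fixed, fitA, coord = coord),
      error = function(e) {
        warning("BEB failed for scheme '", scheme, "': ",
                conditionMessage(e))
        NULL
      })
    model_table <- .model_table(fit0, fitA)
    site_table <- NULL
    enrichment <- NULL
    if (!is.null(post)) {
      site_table <- post[post$p_selected > report_threshold, ,
                         drop = FALSE]
      for (th in thresholds) {
        site_table[[sprintf("flag_%s", format(th))]] <-
          site_table$p_selected >= th
      }
      if (!is.null(coord) && !is.null(binding) &&
          "ref_pos" %in% names(post)) {
        enrichment <- lapply(stats::setNames(thresholds,
                                             format(thresholds)),
                             function(th) {
          counts <- count_selected_sites(post, th, binding,
                                         region = attr(coord,
                                                       "a1_bounds"))
          list(counts = counts, g = tryCatch(g_test(counts$table),
                                             error = function(e) NULL))
        })
      }
    }
    res <- list(scheme = scheme, fit_null = fit0, fit_alt = fitA,
                lrt = lrt, posteriors = post,
                model_table = model_table, site_table = site_table,
                enrichment = enrichment)
    if (!is.null(out_dir)) {
      write_fit_json(fit0, file.path(out_dir,
                                     paste0("fit_null_", scheme,
                                            ".json")))
      write_fit_json(fitA, file.path(out_dir,
                                     paste0("fit_alt_", scheme,
                                            ".json")))
      utils::write.table(model_table,
                         file.path(out_dir, paste0("model_table_",
                                                   scheme, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(site_table)) {
        utils::write.table(site_table,
                           file.path(out_dir, paste0("sites_", scheme,
                                                     ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    results[[scheme]] <- res
  }
  results
}

.model_table <- function(fit0, fitA) {
  row <- function(fit, model_label) {
    p <- fit$params
    data.frame(
      model = model_label,
      site_class = c("0", "1", "2a", "2b"),
      proportion = c(p$p0, p$p1, p$p2a, p$p2b),
      omega_background = c(p$omega0, 1, p$omega0, 1),
      omega_foreground = c(p$omega0, 1, p$omega2, p$omega2),
      kappa = p$kappa,
      lnL = fit$lnL
    )
  }
  rbind(row(fit0, "null (omega2 = 1)"),
        row(fitA, "alternative (omega2 >= 1)"))
}

#' Physicochemical divergence scan
#'
#' Runs the full comparative analysis on an amino-acid alignment: charge
#' and hydropathy change profiles between resistant and non-resistant
#' groups, binding vs non-binding rank-sum tests (both group
#' orientations), sliding-window smoothing, and the four
#' permutation-regression tests (two properties x with/without binding
#' sites).  Optionally a G-test of selected-site enrichment when a
#' posterior table is supplied.
#'
#' @param aln An `amino_alignment`.
#' @param groups A [taxon_groups()].
#' @param coord A `coordinate_map` for `aln`.
#' @param binding A [binding_sites()] set.
#' @param region Reference-coordinate bounds to analyze (default
#'   [A1_BOUNDS] clipped to the mapped range).
#' @param window Sliding-window width (odd; default 5).
#' @param n_perm Permutations for the slope tests (default 1000).
#' @param seed RNG seed (default 2011).
#' @param out_dir Optional output directory (profile and test TSV/JSON).
#' @return A list: `profiles` (per property: `property_profile` with
#'   `smoothed` column), `rank_sum` (per property, binding-first and
#'   nonbinding-first orientations), `slope_tests` (per property, with
#'   and without binding sites), `distances`.
#' @export
run_physchem_scan <- function(aln, groups, coord, binding,
                              region = NULL, window = 5L,
                              n_perm = 1000L, seed = 2011L,
                              out_dir = NULL) {
  stopifnot(inherits(aln, "amino_alignment"),
            inherits(coord, "coordinate_map"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (is.null(region)) region <- attr(coord, "a1_bounds")
  dists <- distance_to_binding(coord, binding)
  in_region <- !is.na(coord$ref_pos) & coord$ref_pos >= region[1] &
    coord$ref_pos <= region[2]
  out <- list(profiles = list(), rank_sum = list(), slope_tests = list(),
              distances = dists, region = region, seed = seed)
  for (prop in c("charge", "hydropathy")) {
    scale <- property_scale(prop)
    vals <- property_values(aln, scale)
    prof <- group_delta_profile(vals, groups, coord = coord,
                                binding = binding)
    prof$smoothed_delta <- sliding_window(prof$delta, window)
    prof$in_region <- in_region
    d <- prof[in_region, , drop = FALSE]
    bind_vals <- d$abs_delta[d$binding]
    nonbind_vals <- d$abs_delta[!d$binding]
    out$rank_sum[[prop]] <- list(
      binding_first = rank_sum_test(bind_vals, nonbind_vals),
      nonbinding_first = rank_sum_test(nonbind_vals, bind_vals)
    )
    dist_region <- dists$distance[in_region]
    out$slope_tests[[prop]] <- list(
      with_binding = permutation_slope_test(
        d$abs_delta, dist_region, binding_flag = d$binding,
        n_perm = n_perm, include_binding = TRUE, seed = seed),
      without_binding = permutation_slope_test(
        d$abs_delta, dist_region, binding_flag = d$binding,
        n_perm = n_perm, include_binding = FALSE, seed = seed)
    )
    out$profiles[[prop]] <- prof
    if (!is.null(out_dir)) {
      utils::write.table(prof,
                         file.path(out_dir, paste0("profile_", prop,
                                                   ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    tests <- list(seed = seed, n_perm = n_perm, region = region)
    for (prop in c("charge", "hydropathy")) {
      rs <- out$rank_sum[[prop]]$binding_first
      st_w <- out$slope_tests[[prop]]$with_binding
      st_wo <- out$slope_tests[[prop]]$without_binding
      tests[[prop]] <- list(
        rank_sum_W = rs$W, rank_sum_p = rs$p_value,
        slope_with_binding = st_w$observed_slope,
        slope_with_binding_ci = st_w$ci,
        slope_with_binding_significant = st_w$significant,
        slope_without_binding = st_wo$observed_slope,
        slope_without_binding_ci = st_wo$ci,
        slope_without_binding_significant = st_wo$significant)
    }
    jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
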