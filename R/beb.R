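#' Bayes-Empirical-Bayes site posteriors for the branch-site model
#'
#' Computes, for every alignment column, the posterior probability of the
#' four site classes (0, 1, 2a, 2b) under the alternative branch-site
#' model, integrating parameter uncertainty over a discrete prior grid:
#' `(p0, p1)` uniform over the probability triangle (category midpoints,
#' `ngrid` per axis), `omega0` uniform on (0, 1) (`ngrid` midpoints) and
#' `omega2` uniform on (1, 11) (`ngrid` midpoints).  `kappa` and branch
#' lengths stay at their MLEs, as does the mixture rate scaling.  The
#' plug-in alternative (`method = "neb"`) evaluates the posterior at the
#' MLEs only.
#'
#' `P_selected = P(2a) + P(2b)` is the posterior probability that the site
#' belongs to a class that allows positive selection on the foreground
#' lineages.
#'
#' @param aln A `codon_alignment`.
#' @param tree The `selection_tree` used for the fit.
#' @param fit A converged alternative-model `branch_site_fit`.
#' @param method `"beb"` (default) or `"neb"`.
#' @param ngrid Grid categories per integrated dimension (default 10).
#' @param coord Optional `coordinate_map` built on
#'   `translate_alignment(aln)`; adds `ref_pos` and reference residue
#'   columns.
#' @return An object of class `site_posteriors`: a data.frame with one row
#'   per alignment column (`site`, optionally `ref_pos`/`residue`,
#'   `post_0`, `post_1`, `post_2a`, `post_2b`, `p_selected`).
#' @export
beb_site_posteriors <- function(aln, tree, fit, method = c("beb", "neb"),
                                ngrid = 10L, coord = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "branch_site_fit"))
  if (fit$model != "alternative") {
    stop("site posteriors require an alternative-model fit")
  }
  if (!isTRUE(fit$converged)) {
    stop("refusing to compute site posteriors from a non-converged fit")
  }
  engine <- .make_engine(aln, fit$tree, fit$freqs)
  mle <- fit$params
  w <- engine$weights
  npat <- engine$n_pat

  if (method == "neb") {
    cl <- .class_loglik_matrix(engine, mle$kappa, mle$p0, mle$p1,
                               mle$omega0, mle$omega2)
    props <- .class_props(mle)
    post <- .class_posterior(cl$logL, props)
    return(.format_posteriors(post, engine, aln, coord))
  }

  mids <- (seq_len(ngrid) - 0.5) / ngrid
  pgrid <- expand.grid(p0 = mids, p1 = mids)
  pgrid <- pgrid[pgrid$p0 + pgrid$p1 < 1, ]
  w0_grid <- mids                      # omega0 in (0, 1)
  w2_grid <- 1 + 10 * mids             # omega2 in (1, 11)

  # class log-likelihoods depend on (omega0, omega2) only; scaling and
  # branch lengths are held at the MLE so grid cells stay comparable
  t_mle <- engine$phy$edge.length / fit$rho
  fr <- .engine_freqs(engine)
  dec_w1 <- .decompose_reversible(
    build_rate_matrix(fr, mle$kappa, 1, scale = FALSE))
  dec_w0 <- lapply(w0_grid, function(w)
    .decompose_reversible(build_rate_matrix(fr, mle$kappa, w,
                                            scale = FALSE)))
  dec_w2 <- lapply(w2_grid, function(w)
    .decompose_reversible(build_rate_matrix(fr, mle$kappa, w,
                                            scale = FALSE)))
  fg <- engine$fg
  role <- function(bg, fgdec) {
    decs <- list(bg = bg, fg = fgdec)
    .prune_class(engine, decs, ifelse(fg, "fg", "bg"), t_mle)
  }
  L0 <- lapply(dec_w0, function(d) role(d, d))          # class 0
  L1 <- role(dec_w1, dec_w1)                            # class 1
  L2b <- lapply(dec_w2, function(d) role(dec_w1, d))    # class 2b
  L2a <- lapply(seq_len(ngrid), function(i)
    lapply(seq_len(ngrid), function(j) role(dec_w0[[i]], dec_w2[[j]])))

  # two passes over the grid: first the marginal data likelihood per
  # cell (for the grid-cell posterior weights), then the weighted
  # accumulation of within-cell class posteriors.  Prior weight is equal
  # per admissible cell.
  prop_grid <- lapply(seq_len(nrow(pgrid)), function(k) {
    bp <- branch_site_params(mle$kappa, pgrid$p0[k], pgrid$p1[k],
                             0.5, 2)  # omegas irrelevant to proportions
    .class_props(bp)
  })
  cell_mix <- function(logL, props) {
    m <- apply(logL, 2L, max)
    log(colSums(exp(sweep(logL, 2L, m, "-")) * props)) + m
  }
  n_cells <- nrow(pgrid) * ngrid * ngrid
  log_marg <- numeric(n_cells)
  cell <- 0L
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      logL <- rbind(L0[[i]], L1, L2a[[i]][[j]], L2b[[j]])
      for (k in seq_len(nrow(pgrid))) {
        cell <- cell + 1L
        log_marg[cell] <- sum(cell_mix(logL, prop_grid[[k]]) * w)
      }
    }
  }
  gw <- exp(log_marg - max(log_marg))
  gw <- gw / sum(gw)
  post_num <- matrix(0, 4L, npat)
  cell <- 0L
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      logL <- rbind(L0[[i]], L1, L2a[[i]][[j]], L2b[[j]])
      for (k in seq_len(nrow(pgrid))) {
        cell <- cell + 1L
        if (gw[cell] < 1e-12) next
        props <- prop_grid[[k]]
        mix <- cell_mix(logL, props)
        post_num <- post_num +
          gw[cell] * (exp(sweep(logL, 2L, mix, "-")) * props)
      }
    }
  }
  post <- sweep(post_num, 2L, colSums(post_num), "/")
  .format_posteriors(post, engine, aln, coord)
}

.class_posterior <- function(logL, props) {
  m <- apply(logL, 2L, max)
  mix <- log(colSums(exp(sweep(logL, 2L, m, "-")) * props)) + m
  exp(sweep(logL, 2L, mix, "-")) * props
}

.format_posteriors <- function(post_pat, engine, aln, coord) {
  post <- post_pat[, engine$pat_index, drop = FALSE]
  out <- data.frame(
    site = seq_len(engine$n_sites),
    post_0 = post[1, ], post_1 = post[2, ],
    post_2a = post[3, ], post_2b = post[4, ],
    p_selected = post[3, ] + post[4, ]
  )
  if (!is.null(coord)) {
    stopifnot(inherits(coord, "coordinate_map"))
    if (nrow(coord) != engine$n_sites) {
      stop("coordinate map length does not match the codon alignment")
    }
    aa <- residue_matrix(translate_alignment(aln))
    ref <- attr(coord, "reference_taxon")
    out$ref_pos <- coord$ref_pos
    if (ref %in% rownames(aa)) out$residue <- aa[ref, ]
  }
  structure(out, class = c("site_posteriors", "data.frame"))
}

#' Cross-classify selected sites against a binding-site annotation
#'
#' Restricts sites to a reference-coordinate region, flags each as
#' selected (`p_selected >= threshold`) or not and as binding or not, and
#' returns the 2x2 counts that feed the enrichment G-test.
#'
#' @param posteriors A `site_posteriors` with a `ref_pos` column, or any
#'   data.frame with `ref_pos` and `p_selected`.
#' @param threshold Posterior-probability cutoff (e.g. 0.95 or 0.50).
#' @param binding A [binding_sites()] set.
#' @param region Inclusive reference-coordinate bounds, e.g. [A1_BOUNDS];
#'   `NULL` keeps every mapped site.
#' @return A list: `table` (2x2 matrix, rows binding/non-binding, columns
#'   selected/not), `binding_selected`, `binding_total`,
#'   `nonbinding_selected`, `nonbinding_total`.
#' @export
count_selected_sites <- function(posteriors, threshold, binding,
                                 region = NULL) {
  stopifnot(is.data.frame(posteriors),
            all(c("ref_pos", "p_selected") %in% names(posteriors)))
  d <- posteriors[!is.na(posteriors$ref_pos), , drop = FALSE]
  if (!is.null(region)) {
    d <- d[d$ref_pos >= region[1] & d$ref_pos <= region[2], ,
           drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no sites in the requested region")
  is_binding <- d$ref_pos %in% as.integer(binding)
  sel <- !is.na(d$p_selected) & d$p_selected >= threshold
  tab <- matrix(c(sum(is_binding & sel), sum(is_binding & !sel),
                  sum(!is_binding & sel), sum(!is_binding & !sel)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("binding", "non_binding"),
                                c("selected", "not_selected")))
  list(table = tab,
       binding_selected = tab[1, 1], binding_total = sum(tab[1, ]),
       nonbinding_selected = tab[2, 1], nonbinding_total = sum(tab[2, ]))
}
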