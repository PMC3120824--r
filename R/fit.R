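#' Fit the branch-site model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood of the branch-site model over
#' `kappa`, `p0`, `p1`, `omega0`, branch lengths (optionally), and
#' `omega2` (alternative model only; fixed at 1 under the null).
#' Optimization runs on transformed parameters (log kappa, multinomial
#' logit for the proportions, scaled logit for omega0 in (1e-4, 1),
#' omega2 untransformed with box \[1, 999\] so the boundary omega2 = 1
#' is reachable without a log-scale crawl) with bounded quasi-Newton
#' ([stats::nlminb()]), from one fixed default start plus `n_restarts`
#' random restarts.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `selection_tree`; the alternative model requires at least
#'   one foreground branch.
#' @param model `"null"` (omega2 fixed at 1) or `"alternative"`.
#' @param freqs Codon frequencies (default: F3x4 estimated from `aln`).
#' @param fix_blens If `TRUE`, branch lengths are fixed at the tree's
#'   values; if `FALSE` they are optimized jointly.  Default: `FALSE` for
#'   the null model, `TRUE` for the alternative (fit the null first, then
#'   fix its branch lengths via [update_branch_lengths()]).
#' @param start Optional named list overriding the default start
#'   (`kappa`, `p0`, `p1`, `omega0`, `omega2`).
#' @param n_restarts Number of random restarts beyond the default start
#'   (default 5).
#' @param seed Seed for restart draws (default 2011).
#' @param control List: `rel_tol` (convergence tolerance on the
#'   log-likelihood, default 1e-8), `max_iter` (default 500).
#' @return An object of class `branch_site_fit`: `params`
#'   ([branch_site_params()] MLEs), `lnL`, `converged`, `n_free_params`,
#'   `model`, `blens` (branch lengths used, on the postorder edge order of
#'   `tree$phy` after reordering), `tree` (with fitted branch lengths),
#'   `freqs`, `rho`, `n_sites`, and optimizer diagnostics.
#' @export
fit_branch_site <- function(aln, tree, model = c("alternative", "null"),
                            freqs = NULL, fix_blens = NULL, start = NULL,
                            n_restarts = 5, seed = 2011,
                            control = list()) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(tree, "selection_tree"))
  if (model == "alternative" && n_foreground(tree) == 0L) {
    stop("alternative model requires at least one foreground branch")
  }
  if (is.null(freqs)) freqs <- estimate_f3x4(aln)
  if (is.null(fix_blens)) fix_blens <- (model == "alternative")
  rel_tol <- control$rel_tol %||% 1e-8
  max_iter <- control$max_iter %||% 500L

  engine <- .make_engine(aln, tree, freqs)
  alt <- model == "alternative"
  nb <- if (fix_blens) 0L else length(engine$phy$edge.length)

  # parameter vector: [log kappa, a0, a1, logit-ish omega0,
  #                    omega2 (alt only, box-bounded), log blens...]
  unpack <- function(x) {
    kappa <- exp(x[1])
    e0 <- exp(x[2]); e1 <- exp(x[3])
    s <- 1 + e0 + e1
    p0 <- e0 / s; p1 <- e1 / s
    omega0 <- 1e-4 + (1 - 2e-4) * stats::plogis(x[4])
    omega2 <- if (alt) x[5] else 1
    blens <- if (nb) exp(x[(length(x) - nb + 1L):length(x)]) else
      engine$phy$edge.length
    list(kappa = kappa, p0 = p0, p1 = p1, omega0 = omega0,
         omega2 = omega2, blens = blens)
  }
  reuse_env <- new.env(parent = emptyenv())
  reuse_env$last <- NULL
  reuse_env$n_evals <- 0L
  negll <- function(x) {
    reuse_env$n_evals <- reuse_env$n_evals + 1L
    p <- unpack(x)
    # keep proportions off the exact boundary for the derived classes
    tot <- p$p0 + p$p1
    if (tot < 1e-8) return(1e10)
    cl <- tryCatch(
      .class_loglik_matrix(engine, p$kappa, p$p0, p$p1, p$omega0,
                           p$omega2, blens = p$blens,
                           reuse01 = reuse_env$last),
      error = function(e) NULL)
    if (is.null(cl)) return(1e10)
    reuse_env$last <- cl$reuse01
    props <- .class_props(branch_site_params(p$kappa, p$p0, p$p1,
                                             p$omega0, max(1, p$omega2)))
    ll <- .mixture_loglik(cl$logL, props, engine$weights)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  pack_start <- function(s) {
    p2 <- max(1e-3, 1 - s$p0 - s$p1)
    # invert the multinomial logit with reference = 1 - p0 - p1
    x <- c(log(s$kappa), log(s$p0 / p2), log(s$p1 / p2),
           stats::qlogis(min(1 - 1e-6, max(
             1e-6, (s$omega0 - 1e-4) / (1 - 2e-4)))))
    if (alt) x <- c(x, min(999, max(1, s$omega2)))
    if (nb) x <- c(x, log(pmax(engine$phy$edge.length, 1e-6)))
    x
  }
  default_start <- list(kappa = 2, p0 = 0.7, p1 = 0.2, omega0 = 0.1,
                        omega2 = 2)
  if (!is.null(start)) default_start <- utils::modifyList(default_start,
                                                          start)
  starts <- list(pack_start(default_start))
  if (n_restarts > 0) {
    rng <- .seeded_rng(seed)
    for (r in seq_len(n_restarts)) {
      p0r <- rng$runif(1, 0.1, 0.9)
      p1r <- rng$runif(1, 0.02, 1 - p0r)
      s <- list(kappa = exp(rng$runif(1, log(0.5), log(8))),
                p0 = p0r, p1 = p1r,
                omega0 = rng$runif(1, 0.01, 0.5),
                omega2 = 1 + exp(rng$runif(1, log(0.1), log(16))))
      starts[[r + 1L]] <- pack_start(s)
    }
  }

  np <- 4L + as.integer(alt) + nb
  lower <- c(log(1e-3), -15, -15, -30,
             if (alt) 1, rep(log(1e-8), nb))
  upper <- c(log(1e3), 15, 15, 30,
             if (alt) 999, rep(log(50), nb))
  best <- NULL
  any_ok <- FALSE
  for (x0 in starts) {
    res <- tryCatch(
      stats::nlminb(x0, negll, lower = lower, upper = upper,
                    control = list(rel.tol = rel_tol,
                                   iter.max = max_iter,
                                   eval.max = 4L * max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$convergence == 0 && res$objective < 1e9
    any_ok <- any_ok || ok
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    stop("branch-site optimization failed from every start")
  }
  if (!any_ok) {
    warning("branch-site optimization did not converge; result flagged")
  }
  p <- unpack(best$par)
  params <- branch_site_params(p$kappa, p$p0, p$p1, p$omega0,
                               max(1, p$omega2))
  fitted_tree <- tree
  if (nb) {
    # carry optimized lengths back onto the original edge order
    phy_po <- engine$phy
    phy_po$edge.length <- p$blens
    key_in <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
    key_po <- paste(phy_po$edge[, 1], phy_po$edge[, 2])
    fitted_tree$phy$edge.length <- p$blens[match(key_in, key_po)]
  }
  cl <- .class_loglik_matrix(engine, params$kappa, params$p0, params$p1,
                             params$omega0, params$omega2,
                             blens = p$blens)
  structure(
    list(params = params, lnL = -best$objective,
         converged = any_ok && best$convergence == 0,
         n_free_params = np, model = model, fix_blens = fix_blens,
         tree = fitted_tree, freqs = freqs, rho = cl$rho,
         n_sites = engine$n_sites,
         optim = list(message = best$message,
                      iterations = best$iterations,
                      n_evals = reuse_env$n_evals)),
    class = "branch_site_fit"
  )
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf("branch_site_fit (%s model): lnL = %.4f%s\n", x$model,
              x$lnL, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  invisible(x)
}

#' Copy fitted branch lengths onto a tree
#'
#' Convenience for the default protocol: optimize branch lengths under the
#' null model, then fix them for the alternative fit.
#'
#' @param tree A `selection_tree`.
#' @param fit A `branch_site_fit` whose `tree` carries fitted lengths.
#' @return `tree` with `fit`'s branch lengths (foreground flags kept).
#' @export
update_branch_lengths <- function(tree, fit) {
  stopifnot(inherits(tree, "selection_tree"),
            inherits(fit, "branch_site_fit"))
  key_a <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
  key_b <- paste(fit$tree$phy$edge[, 1], fit$tree$phy$edge[, 2])
  tree$phy$edge.length <- fit$tree$phy$edge.length[match(key_a, key_b)]
  tree
}

#' Likelihood-ratio test of the branch-site models
#'
#' The statistic is `max(0, 2 (lnL_alt - lnL_null))`, referred to the
#' chi-squared distribution with one degree of freedom (deliberately
#' unmodified, i.e. not the 50:50 boundary mixture, which makes the test
#' slightly conservative).
#'
#' @param fit_null,fit_alt `branch_site_fit` objects (or bare
#'   log-likelihood numbers) for the nested null/alternative pair.
#' @return An object of class `lrt_result`: `statistic`, `df = 1`,
#'   `p_value`, `lnL_null`, `lnL_alt`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  l0 <- if (inherits(fit_null, "branch_site_fit")) fit_null$lnL else
    as.numeric(fit_null)
  la <- if (inherits(fit_alt, "branch_site_fit")) fit_alt$lnL else
    as.numeric(fit_alt)
  stat <- 2 * (la - l0)
  if (stat < -1e-6) {
    warning("alternative log-likelihood below null (optimizer failure); ",
            "statistic clipped to 0")
  }
  stat <- max(0, stat)
  structure(
    list(statistic = stat, df = 1L,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         lnL_null = l0, lnL_alt = la),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*delta-lnL = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# small self-contained RNG wrapper so package routines never disturb the
# caller's .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    s
  })
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          }
        } else {
          assign(".Random.seed", old, globalenv())
        }
      })
      f(...)
    }
  }
  list(runif = with_state(stats::runif),
       sample_int = with_state(function(n, size, replace = FALSE,
                                        prob = NULL) {
         sample.int(n, size, replace = replace, prob = prob)
       }),
       rbinom = with_state(stats::rbinom),
       rexp = with_state(stats::rexp))
}
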