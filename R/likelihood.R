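#' Branch-site model parameters
#'
#' Parameters of the branch-site "model A" mixture: site-class proportions
#' `p0` (purifying, omega0 on all branches), `p1` (neutral, omega = 1
#' everywhere), and the derived foreground classes
#' `p2a = (1 - p0 - p1) p0 / (p0 + p1)` and
#' `p2b = (1 - p0 - p1) p1 / (p0 + p1)`, which keep the background omega of
#' classes 0/1 but take `omega2` on foreground branches.  The null model
#' fixes `omega2 = 1`.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param p0,p1 Proportions in \[0, 1\] with `p0 + p1 <= 1` and
#'   `p0 + p1 > 0`.
#' @param omega0 Background purifying ratio in (0, 1).
#' @param omega2 Foreground ratio (>= 1; 1 under the null).
#' @return An object of class `branch_site_params`.
#' @export
branch_site_params <- function(kappa, p0, p1, omega0, omega2 = 1) {
  stopifnot(kappa > 0, p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12,
            p0 + p1 > 0, omega0 > 0, omega0 < 1, omega2 >= 1)
  rest <- max(0, 1 - p0 - p1)
  p2a <- rest * p0 / (p0 + p1)
  p2b <- rest * p1 / (p0 + p1)
  structure(
    list(kappa = kappa, p0 = p0, p1 = p1, p2a = p2a, p2b = p2b,
         omega0 = omega0, omega1 = 1, omega2 = omega2),
    class = "branch_site_params"
  )
}

#' @export
print.branch_site_params <- function(x, ...) {
  cat(sprintf(
    "branch_site_params: kappa=%.4g  p=(%.4g, %.4g, %.4g, %.4g)  ",
    x$kappa, x$p0, x$p1, x$p2a, x$p2b))
  cat(sprintf("omega0=%.4g  omega2=%.4g\n", x$omega0, x$omega2))
  invisible(x)
}

.class_props <- function(params) {
  c(params$p0, params$p1, params$p2a, params$p2b)
}

# ---------------------------------------------------------------------------
# Likelihood engine: preprocessed alignment/tree bundle for repeated
# evaluations during optimization, BEB and simulation checks.

.make_engine <- function(aln, tree, freqs) {
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(tree, "selection_tree"),
            inherits(freqs, "codon_frequencies"))
  .check_taxon_match(aln$taxa, tree)
  phy <- ape::reorder.phylo(tree$phy, "postorder")
  # foreground flags must follow the edge reordering
  key_in <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
  key_po <- paste(phy$edge[, 1], phy$edge[, 2])
  fg <- tree$foreground[match(key_po, key_in)]
  states <- .codon_states(aln)
  states <- states[match(phy$tip.label, aln$taxa), , drop = FALSE]
  key <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_states <- states[, upat, drop = FALSE]
  pat_index <- match(key, key[upat])
  weights <- tabulate(pat_index, nbins = sum(upat))
  pi <- pmax(as.numeric(freqs), 0)
  # the reversible decomposition needs strictly positive frequencies;
  # clamp structural zeros (e.g. F3x4 with an unobserved nucleotide)
  pi[pi < 1e-10] <- 1e-10
  pi <- pi / sum(pi)
  # nodes with a foreground edge somewhere below them: their partials
  # differ between the class pairs (0, 2a) and (1, 2b); all other
  # subtrees can be shared within one likelihood evaluation
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  fg_below <- rep(FALSE, nnode)
  for (e in seq_len(nrow(phy$edge))) {  # postorder: children first
    parent <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    if (fg[e] || (child > ntip && fg_below[child])) {
      fg_below[parent] <- TRUE
    }
  }
  list(
    phy = phy, fg = fg, ntip = ntip, scratch = new.env(parent = emptyenv()),
    root = ntip + 1L, fg_below = fg_below,
    n_sites = ncol(states), pat_states = pat_states,
    pat_index = pat_index, weights = weights, n_pat = sum(upat),
    pi = pi, freqs = freqs
  )
}

# Pruning pass for one site class.  `decs` is a list of reversible
# decompositions keyed by omega role; `which_dec` maps each edge to one of
# them.  Returns per-pattern log-likelihood.
#
# `cache` (an environment) shares the partials of subtrees that contain no
# foreground edge between the two classes with the same background omega
# (`bg_role`): such subtrees see identical rate matrices in both classes.
.prune_class <- function(engine, decs, which_dec, blens, cache = NULL,
                         bg_role = NULL, pcache = NULL) {
  phy <- engine$phy
  npat <- engine$n_pat
  nnode <- engine$ntip + phy$Nnode
  partial <- vector("list", nnode)
  logsc <- vector("list", nnode)
  edge <- phy$edge
  use_cache <- !is.null(cache) && !is.null(bg_role)
  cacheable <- function(node) {
    use_cache && node > engine$ntip && !engine$fg_below[node]
  }
  resolved <- rep(FALSE, nnode)
  if (use_cache) {
    for (node in seq_len(nnode)) {
      if (cacheable(node) &&
          !is.null(cache[[paste0(node, ":", bg_role)]])) {
        hit <- cache[[paste0(node, ":", bg_role)]]
        partial[[node]] <- hit$partial
        logsc[[node]] <- hit$logsc
        resolved[node] <- TRUE
      }
    }
  }
  # skip every edge strictly inside a cache-resolved subtree (top-down
  # cover: a child of a covered node is covered)
  covered <- resolved
  for (e in rev(seq_len(nrow(edge)))) {
    if (covered[edge[e, 1]]) covered[edge[e, 2]] <- TRUE
  }
  skip <- covered[edge[, 1]]
  for (e in seq_len(nrow(edge))) {
    if (skip[e]) next
    parent <- edge[e, 1]
    child <- edge[e, 2]
    if (is.null(pcache)) {
      P <- .pmat_from_decomp(decs[[which_dec[e]]], blens[e])
    } else {
      pkey <- paste0(which_dec[e], e)
      P <- pcache[[pkey]]
      if (is.null(P)) {
        P <- .pmat_from_decomp(decs[[which_dec[e]]], blens[e])
        pcache[[pkey]] <- P
      }
    }
    if (child <= engine$ntip) {
      st <- engine$pat_states[child, ]
      contrib <- P[, st, drop = FALSE]
      if (anyNA(st)) contrib[, is.na(st)] <- 1
      sc <- 0
    } else {
      contrib <- P %*% partial[[child]]
      sc <- logsc[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
      logsc[[parent]] <- sc
    } else {
      pp <- partial[[parent]] * contrib
      # rescale by column sums (cheap underflow guard)
      cs <- .colSums(pp, nrow(pp), ncol(pp))
      cs[cs < 1e-300] <- 1
      partial[[parent]] <- pp * rep(1 / cs, each = nrow(pp))
      logsc[[parent]] <- logsc[[parent]] + sc + log(cs)
    }
  }
  if (use_cache) {
    for (node in seq_len(nnode)) {
      if (cacheable(node) && !resolved[node] &&
          !is.null(partial[[node]])) {
        cache[[paste0(node, ":", bg_role)]] <-
          list(partial = partial[[node]], logsc = logsc[[node]])
      }
    }
  }
  root <- engine$root
  lik <- colSums(engine$pi * partial[[root]])
  sc <- logsc[[root]]
  if (length(sc) == 1L && sc[1] == 0) sc <- rep(0, npat)
  log(lik) + sc
}

# Per-class per-pattern log-likelihoods under the 4-class branch-site
# mixture.  blens = NULL uses tree branch lengths; scaling follows the
# mixture rule: expected rate averaged over classes with background omegas
# equals 1.
.class_loglik_matrix <- function(engine, kappa, p0, p1, omega0, omega2,
                                 blens = NULL, reuse01 = NULL) {
  if (is.null(blens)) blens <- engine$phy$edge.length
  fr <- .engine_freqs(engine)
  Q0 <- build_rate_matrix(fr, kappa, omega0, scale = FALSE)
  Q1 <- build_rate_matrix(fr, kappa, 1, scale = FALSE)
  r0 <- .expected_rate(Q0)
  r1 <- .expected_rate(Q1)
  params <- branch_site_params(kappa, p0, p1, omega0, max(1, omega2))
  props <- .class_props(params)
  rho <- (props[1] + props[3]) * r0 + (props[2] + props[4]) * r1
  if (rho <= 0) rho <- 1
  t_eff <- blens / rho
  dcache <- engine$scratch
  get_dec <- function(omega, Q = NULL) {
    key <- paste0("d", kappa, ":", omega)
    d <- dcache[[key]]
    if (is.null(d)) {
      if (is.null(Q)) Q <- build_rate_matrix(fr, kappa, omega,
                                             scale = FALSE)
      d <- .decompose_reversible(Q)
      if (length(ls(dcache)) > 60) rm(list = ls(dcache), envir = dcache)
      dcache[[key]] <- d
    }
    d
  }
  dec0 <- get_dec(omega0, Q0)
  dec1 <- get_dec(1, Q1)
  dec2 <- if (omega2 == omega0) dec0 else if (omega2 == 1) dec1 else
    get_dec(omega2)
  decs <- list(w0 = dec0, w1 = dec1, w2 = dec2)
  fg <- engine$fg
  assign_for <- function(bg, fgrole) ifelse(fg, fgrole, bg)
  cache <- new.env(parent = emptyenv())
  pcache <- new.env(parent = emptyenv())
  # the same (omega role, edge) P matrix recurs across classes; the pcache
  # keys by role and edge index, valid within this evaluation only
  # classes 0 and 1 do not involve omega2: reuse them across optimizer
  # steps that only moved omega2 (same kappa, omega0, proportions-scaling
  # and branch lengths)
  key01 <- paste(kappa, omega0, rho, sum(blens), length(blens))
  reuse <- !is.null(reuse01) && identical(reuse01$key, key01)
  L2a <- .prune_class(engine, decs, assign_for("w0", "w2"), t_eff,
                      cache = cache, bg_role = "w0", pcache = pcache)
  L0 <- if (reuse) reuse01$L0 else
    .prune_class(engine, decs, assign_for("w0", "w0"), t_eff,
                 cache = cache, bg_role = "w0", pcache = pcache)
  L2b <- if (omega2 == 1) NULL else
    .prune_class(engine, decs, assign_for("w1", "w2"), t_eff,
                 cache = cache, bg_role = "w1", pcache = pcache)
  L1 <- if (reuse) reuse01$L1 else
    .prune_class(engine, decs, assign_for("w1", "w1"), t_eff,
                 cache = cache, bg_role = "w1", pcache = pcache)
  if (is.null(L2b)) L2b <- L1  # omega2 = 1: class 2b degenerates to 1
  out <- rbind(`0` = L0, `1` = L1, `2a` = L2a, `2b` = L2b)
  list(logL = out, rho = rho, reuse01 = list(key = key01, L0 = L0,
                                             L1 = L1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.engine_freqs <- function(engine) {
  structure(engine$pi, names = names(engine$freqs),
            class = "codon_frequencies")
}

# total log-likelihood from a class log-lik matrix and proportions
.mixture_loglik <- function(logL, props, weights) {
  m <- apply(logL, 2L, max)
  mix <- log(colSums(exp(sweep(logL, 2L, m, "-")) * props)) + m
  sum(mix * weights)
}

#' Per-site class and mixture likelihoods under the branch-site model
#'
#' For each alignment column and each site class (0, 1, 2a, 2b), the
#' pruning likelihood with the class-appropriate omega on background and
#' foreground branches, together with the mixture likelihood
#' `sum_c prop_c L_c`.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `selection_tree` (taxa must match the alignment).
#' @param params A [branch_site_params()].
#' @param freqs Codon frequencies; default [estimate_f3x4()] on `aln`.
#' @return A list: `class_loglik` (4 x n_sites matrix, rows
#'   `0, 1, 2a, 2b`), `mixture_loglik` (length n_sites),
#'   `class_lik`, `mixture_lik` (raw space), and `rho` (mixture rate
#'   scaling applied to branch lengths).
#' @export
site_likelihoods <- function(aln, tree, params, freqs = NULL) {
  stopifnot(inherits(params, "branch_site_params"))
  if (is.null(freqs)) freqs <- estimate_f3x4(aln)
  engine <- .make_engine(aln, tree, freqs)
  cl <- .class_loglik_matrix(engine, params$kappa, params$p0, params$p1,
                             params$omega0, params$omega2)
  logL <- cl$logL[, engine$pat_index, drop = FALSE]
  props <- .class_props(params)
  m <- apply(logL, 2L, max)
  mix <- log(colSums(exp(sweep(logL, 2L, m, "-")) * props)) + m
  list(class_loglik = logL, mixture_loglik = mix,
       class_lik = exp(logL), mixture_lik = exp(mix), rho = cl$rho)
}
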