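#' Per-residue physicochemical scales
#'
#' `"charge"` assigns +1 to Lys and Arg, -1 to Asp and Glu and 0 to every
#' other residue (His is treated as neutral at physiological pH;
#' set `histidine_charge = 1` for the protonated alternative).
#' `"hydropathy"` is the Kyte-Doolittle scale.
#'
#' @param name `"charge"` or `"hydropathy"`.
#' @param histidine_charge Charge assigned to His (0, the default, or 1).
#' @return An object of class `property_scale`: a named numeric vector
#'   over the 20 residues with a `name` attribute.
#' @export
property_scale <- function(name = c("charge", "hydropathy"),
                           histidine_charge = 0) {
  name <- match.arg(name)
  if (name == "charge") {
    stopifnot(histidine_charge %in% c(0, 1))
    v <- stats::setNames(rep(0, 20), AA_ALPHABET)
    v[c("K", "R")] <- 1
    v[c("D", "E")] <- -1
    v["H"] <- histidine_charge
  } else {
    v <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)
    v <- v[AA_ALPHABET]
  }
  structure(v, class = "property_scale", scale_name = name)
}

#' Per-taxon, per-site property values
#'
#' @param aln An `amino_alignment`.
#' @param scale A [property_scale()].
#' @return Numeric taxa x site matrix; gaps and `X` give `NA`.
#' @export
property_values <- function(aln, scale) {
  stopifnot(inherits(aln, "amino_alignment"),
            inherits(scale, "property_scale"))
  m <- residue_matrix(aln)
  known <- matrix(m %in% c(names(scale), "-", "X"), nrow(m))
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("unknown residue symbol '", m[bad[1], bad[2]], "' in taxon '",
         rownames(m)[bad[1]], "' at column ", bad[2])
  }
  v <- matrix(unname(scale[m]), nrow(m), ncol(m),
              dimnames = dimnames(m))
  v
}

#' Group change profile for a physicochemical property
#'
#' Per site: the mean property value over venom-resistant taxa, the mean
#' over non-resistant taxa (gaps/X excluded), their difference
#' `delta = resistant - non_resistant` and `|delta|`.  Sites where either
#' group has no informative residue are `NA` and are excluded from all
#' downstream tests.
#'
#' @param values Matrix from [property_values()].
#' @param groups A [taxon_groups()]; labels must match rownames exactly.
#' @param coord Optional `coordinate_map` (adds `ref_pos`).
#' @param binding Optional [binding_sites()] (adds the `binding` flag,
#'   via `coord`).
#' @return An object of class `property_profile`: data.frame with columns
#'   `site`, optionally `ref_pos`/`binding`, `mean_resistant`,
#'   `mean_non_resistant`, `delta`, `abs_delta`, `n_resistant`,
#'   `n_non_resistant`.
#' @export
group_delta_profile <- function(values, groups, coord = NULL,
                                binding = NULL) {
  stopifnot(is.matrix(values), inherits(groups, "taxon_groups"))
  miss <- setdiff(c(groups$resistant, groups$non_resistant),
                  rownames(values))
  if (length(miss)) {
    stop("group taxa not in the value matrix: ",
         paste(miss, collapse = ", "))
  }
  vr <- values[groups$resistant, , drop = FALSE]
  vn <- values[groups$non_resistant, , drop = FALSE]
  nr <- as.integer(colSums(!is.na(vr)))
  nn <- as.integer(colSums(!is.na(vn)))
  mr <- ifelse(nr > 0, colMeans(vr, na.rm = TRUE), NA_real_)
  mn <- ifelse(nn > 0, colMeans(vn, na.rm = TRUE), NA_real_)
  delta <- mr - mn
  out <- data.frame(
    site = seq_len(ncol(values)),
    mean_resistant = mr, mean_non_resistant = mn,
    delta = delta, abs_delta = abs(delta),
    n_resistant = nr, n_non_resistant = nn
  )
  if (!is.null(coord)) {
    stopifnot(nrow(coord) == ncol(values))
    out$ref_pos <- coord$ref_pos
    if (!is.null(binding)) {
      out$binding <- !is.na(out$ref_pos) &
        out$ref_pos %in% as.integer(binding)
    }
  }
  structure(out, class = c("property_profile", "data.frame"))
}

#' Wilcoxon rank-sum (Mann-Whitney) test with midranks
#'
#' Reports the Mann-Whitney U statistic of the first sample computed with
#' midranks for ties (so W can be fractional).  The p-value uses the
#' exact null distribution when there are no ties and `n1 * n2 <= 10000`,
#' and otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped); `values_a` is
#'   the first-listed group.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An object of class `rank_sum_result`: `W` (U of the first
#'   sample), `W_other` (`n1 n2 - W`), `p_value`, `n1`, `n2`, `method`,
#'   `ties`.
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two.sided", "less",
                                          "greater")) {
  alternative <- match.arg(alternative)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 * n2 <= 10000) {
    method <- "exact"
    p <- switch(alternative,
      two.sided = {
        if (W > n1 * n2 / 2) {
          min(1, 2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(W, n1, n2))
        }
      },
      less = stats::pwilcox(W, n1, n2),
      greater = stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE))
  } else {
    method <- "normal approximation, tie-corrected"
    mu <- n1 * n2 / 2
    nties <- table(r)
    n <- n1 + n2
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z <- W - mu
    cc <- switch(alternative, two.sided = sign(z) * 0.5, less = -0.5,
                 greater = 0.5)
    z <- (z - cc) / sigma
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
  }
  structure(
    list(W = W, W_other = n1 * n2 - W, p_value = p, n1 = n1, n2 = n2,
         method = method, ties = ties, alternative = alternative),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("rank-sum: W = %.4g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$W, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' G-test of independence on a 2x2 table
#'
#' `G = 2 sum O log(O / E)` over the four cells with expectations from the
#' margins; zero cells contribute zero.  One degree of freedom; p-value
#' from chi-squared.  No Williams correction by default.
#'
#' @param table 2x2 matrix of nonnegative counts (or length-4 vector,
#'   filled by row); all margins must be positive.
#' @param williams Apply the Williams continuity correction
#'   (default FALSE).
#' @return An object of class `g_test_result`: `G`, `df = 1`, `p_value`,
#'   `table`, `expected`.
#' @export
g_test <- function(table, williams = FALSE) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero margin in contingency table")
  }
  E <- outer(rs, cs) / n
  terms <- ifelse(table > 0, table * log(table / E), 0)
  G <- 2 * sum(terms)
  if (williams) {
    q <- 1 + ((n / rs[1] + n / rs[2] - 1) *
                (n / cs[1] + n / cs[2] - 1)) / (6 * n)
    G <- G / q
  }
  structure(
    list(G = G, df = 1L,
         p_value = stats::pchisq(G, df = 1, lower.tail = FALSE),
         table = table, expected = E, williams = williams),
    class = "g_test_result"
  )
}

#' @export
print.g_test_result <- function(x, ...) {
  cat(sprintf("G-test: G = %.4g, df = %d, p = %.4g\n", x$G, x$df,
              x$p_value))
  invisible(x)
}

#' Centered sliding-window average
#'
#' Moving average with an odd window, ignoring NAs; windows are truncated
#' at the profile edges (the divisor is the number of non-NA values
#' actually in the window).
#'
#' @param profile Numeric vector of per-site values.
#' @param window Odd integer window width, `1 <= window <= length`.
#' @return Numeric vector of smoothed values (NA where a window holds no
#'   data).
#' @export
sliding_window <- function(profile, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window width must be odd")
  stopifnot(window >= 1L, window <= length(profile))
  h <- (window - 1L) %/% 2L
  n <- length(profile)
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    v <- profile[lo:hi]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Distance to the nearest binding site
#'
#' Linear distance in residues (reference coordinates, not alignment
#' columns) from each mapped site to the nearest annotated binding
#' position; binding sites get 0.  Unmapped columns get NA.
#'
#' @param coord A `coordinate_map`.
#' @param binding A [binding_sites()] set; every position must be inside
#'   the mapped coordinate range.
#' @return data.frame with `column`, `ref_pos`, `distance`.
#' @export
distance_to_binding <- function(coord, binding) {
  stopifnot(inherits(coord, "coordinate_map"))
  b <- as.integer(binding)
  if (!length(b)) stop("binding-site set is empty")
  mapped <- range(coord$ref_pos, na.rm = TRUE)
  out_of_range <- b[b < mapped[1] | b > mapped[2]]
  if (length(out_of_range)) {
    stop("binding position(s) outside mapped range [", mapped[1], ", ",
         mapped[2], "]: ", paste(out_of_range, collapse = ", "))
  }
  dist <- vapply(coord$ref_pos, function(p) {
    if (is.na(p)) NA_real_ else min(abs(p - b))
  }, numeric(1))
  data.frame(column = coord$column, ref_pos = coord$ref_pos,
             distance = as.integer(dist))
}

#' Permutation test for the slope of |delta| on distance-to-binding-site
#'
#' The observed statistic is the ordinary least-squares slope of the
#' per-site change magnitude on linear distance to the nearest binding
#' site.  The null distribution comes from `n_perm` uniform permutations
#' of the change magnitudes across the analyzed sites (distances held
#' fixed); the 95% interval is the 2.5/97.5 percentile pair of the null
#' slopes, and the observed slope is called significant when it falls
#' outside that interval.  With `include_binding = FALSE`, binding-site
#' rows are dropped before both the observed and the null fits.
#'
#' @param abs_delta Per-site |delta| values.
#' @param distances Per-site distances (same length).
#' @param binding_flag Logical per-site binding indicator (required when
#'   `include_binding = FALSE`).
#' @param n_perm Number of permutations (default 1000).
#' @param include_binding Keep binding-site rows (default TRUE).
#' @param seed RNG seed (default 2011).
#' @return An object of class `permutation_regression_result`:
#'   `observed_slope`, `null_slopes`, `ci` (2.5/97.5 percentiles),
#'   `significant`, `n_sites`, `include_binding`, `seed`.
#' @export
permutation_slope_test <- function(abs_delta, distances,
                                   binding_flag = NULL, n_perm = 1000L,
                                   include_binding = TRUE, seed = 2011L) {
  stopifnot(length(abs_delta) == length(distances), n_perm >= 1)
  keep <- !is.na(abs_delta) & !is.na(distances)
  if (!include_binding) {
    if (is.null(binding_flag)) {
      stop("binding_flag is required when include_binding = FALSE")
    }
    stopifnot(length(binding_flag) == length(abs_delta))
    keep <- keep & !binding_flag
  }
  y <- abs_delta[keep]
  x <- distances[keep]
  if (length(y) < 3L) stop("fewer than 3 informative sites")
  if (stats::var(x) == 0) {
    stop("all distances equal; slope undefined")
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope_of <- function(yy) sum(xc * yy) / sxx
  observed <- slope_of(y)
  rng <- .seeded_rng(seed)
  null_slopes <- vapply(seq_len(n_perm), function(i) {
    slope_of(y[rng$sample_int(length(y), length(y))])
  }, numeric(1))
  ci <- stats::quantile(null_slopes, c(0.025, 0.975), names = FALSE)
  structure(
    list(observed_slope = observed, null_slopes = null_slopes,
         ci = ci, significant = observed < ci[1] || observed > ci[2],
         n_sites = length(y), include_binding = include_binding,
         n_perm = n_perm, seed = seed),
    class = "permutation_regression_result"
  )
}

#' @export
print.permutation_regression_result <- function(x, ...) {
  cat(sprintf(
    "permutation slope test: observed = %.4g, null 95%% = [%.4g, %.4g]%s\n",
    x$observed_slope, x$ci[1], x$ci[2],
    if (x$significant) "  *outside*" else ""))
  invisible(x)
}
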