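#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are counted over all
#' unambiguous nucleotides at each of the three codon positions; the codon
#' frequency is the product of its three positional nucleotide
#' frequencies, with stop codons removed and the rest renormalized to
#' sum to one.
#'
#' @param aln A `codon_alignment`.
#' @return An object of class `codon_frequencies`: a named numeric vector
#'   over the sense codons.
#' @export
estimate_f3x4 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cm <- codon_matrix(aln)
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  for (p in 1:3) {
    nt <- substr(as.vector(cm), p, p)
    counts <- table(factor(nt, levels = NUCS))
    if (sum(counts) == 0) {
      stop("no unambiguous nucleotides observed at codon position ", p)
    }
    pos_freq[p, ] <- counts / sum(counts)
  }
  .f3x4_from_positions(pos_freq)
}

# build sense-codon frequencies from a 3 x 4 positional frequency matrix
.f3x4_from_positions <- function(pos_freq) {
  tab <- .universal_table()
  split3 <- do.call(rbind, strsplit(tab$sense, ""))
  pi <- pos_freq[1, split3[, 1]] * pos_freq[2, split3[, 2]] *
    pos_freq[3, split3[, 3]]
  names(pi) <- tab$sense
  if (sum(pi) <= 0) stop("degenerate F3x4 frequencies (all zero)")
  pi <- pi / sum(pi)
  structure(pi, class = "codon_frequencies")
}

#' Uniform codon frequencies (1/61 per sense codon)
#' @export
uniform_codon_frequencies <- function() {
  tab <- .universal_table()
  pi <- rep(1 / length(tab$sense), length(tab$sense))
  names(pi) <- tab$sense
  structure(pi, class = "codon_frequencies")
}

#' Goldman-Yang codon rate matrix
#'
#' Off-diagonal rate from codon i to codon j is 0 unless the codons differ
#' at exactly one nucleotide; otherwise it is `pi_j`, multiplied by `kappa`
#' if the nucleotide change is a transition and by `omega` if the codon
#' change is nonsynonymous.  The diagonal makes rows sum to zero.  With
#' `scale = TRUE` the matrix is divided by its equilibrium expected rate so
#' that branch lengths are expected substitutions per codon; the
#' branch-site fit instead uses `scale = FALSE` plus a mixture-level
#' scaling over the four site classes.
#'
#' @param freqs A `codon_frequencies`.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param scale Scale to one expected substitution per unit time
#'   (default TRUE).
#' @return 61 x 61 rate matrix with `pi` attached as attribute.
#' @export
build_rate_matrix <- function(freqs, kappa, omega, scale = TRUE) {
  stopifnot(inherits(freqs, "codon_frequencies"), kappa > 0, omega >= 0)
  type <- .pair_classification()
  pi <- as.numeric(freqs)
  n <- length(pi)
  mult <- matrix(0, n, n)
  mult[type == 1L] <- 1
  mult[type == 2L] <- kappa
  mult[type == 3L] <- omega
  mult[type == 4L] <- kappa * omega
  Q <- mult * rep(pi, each = n)  # column j scaled by pi_j
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  dimnames(Q) <- dimnames(type)
  attr(Q, "pi") <- pi
  Q
}

# expected equilibrium rate of an unscaled GY matrix
.expected_rate <- function(Q) {
  -sum(attr(Q, "pi") * diag(Q))
}

# Spectral decomposition of a reversible rate matrix, for cheap repeated
# matrix exponentials: Q = D^{-1/2} S D^{1/2} with S symmetric.
.decompose_reversible <- function(Q) {
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("rate matrix lacks 'pi' attribute")
  sq <- sqrt(pi)
  S <- Q * (sq / rep(sq, each = length(sq)))  # S_ij = sqrt(pi_i/pi_j)...
  S <- (S + t(S)) / 2                          # symmetrize roundoff
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / sq,        # D^{-1/2} U  (columns)
       left = t(e$vectors * sq))      # U' D^{1/2}
}

.pmat_from_decomp <- function(dec, t) {
  P <- (dec$right * rep(exp(dec$values * t), each = nrow(dec$right))) %*%
    dec$left
  P[P < 0] <- 0
  P
}

#' Transition probabilities of a codon rate matrix
#'
#' Computes `expm(Q t)` via the spectral decomposition of the reversible
#' rate matrix.  Rows sum to one; entries are clipped at zero against
#' roundoff.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0).
#' @return Stochastic matrix of codon transition probabilities.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(t >= 0)
  dec <- .decompose_reversible(Q)
  P <- .pmat_from_decomp(dec, t)
  dimnames(P) <- dimnames(Q)
  P
}
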