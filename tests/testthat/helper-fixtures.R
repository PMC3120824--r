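# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written without reusing the package's
# computational path (plain string ops, explicit enumeration, series
# expansions).

fixture_tree_4 <- function() {
  read_labeled_tree(text = "((A:0.2,B:0.3)#1:0.1,(C:0.25,D:0.15):0.05);")
}

# 8-taxon tree with a 4-tip foreground clade; used for the simulation
# studies (type-I error, warm-start protocol)
fixture_tree_8 <- function() {
  tr <- read_labeled_tree(text = paste0(
    "(((A:0.15,B:0.12):0.08,(C:0.1,D:0.14):0.06):0.05,",
    "((E:0.1,F:0.12):0.07,(G:0.09,H:0.11):0.05):0.04);"))
  label_clade_foreground(tr, c("A", "B", "C", "D"))
}

# --- independent codon-pair classification (string ops only) -------------

oracle_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aa3 <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa3
}

# classify a codon pair: NULL if not single-nt neighbors, otherwise
# list(transition = , nonsyn = )
oracle_pair_class <- function(ci, cj) {
  aa <- oracle_codon_table()
  a <- strsplit(ci, "")[[1]]
  b <- strsplit(cj, "")[[1]]
  diff <- which(a != b)
  if (length(diff) != 1) return(NULL)
  purine <- c("A", "G")
  ts <- (a[diff] %in% purine) == (b[diff] %in% purine)
  list(transition = ts, nonsyn = aa[[ci]] != aa[[cj]])
}

# --- independent matrix exponential (scaling and squaring + Taylor) ------

oracle_expm <- function(A, order = 24) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0, ceiling(log2(max(nrm, 1e-300))) + 2)
  As <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% As / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# --- brute-force branch-site site likelihood by enumeration --------------
# Sums over all internal-node codon assignments; usable for <= 5 leaves.
# Uses the package's P matrices (the enumeration itself is what is being
# checked against the pruning recursion).
oracle_site_likelihood <- function(aln, tree, params, freqs, site,
                                   class_label) {
  tab <- genetic_code_table()
  n_codon <- length(tab$sense)
  pi <- pmax(as.numeric(freqs), 0)
  pi[pi < 1e-10] <- 1e-10
  pi <- pi / sum(pi)
  fr <- structure(pi, names = tab$sense, class = "codon_frequencies")
  Q0 <- build_rate_matrix(fr, params$kappa, params$omega0, scale = FALSE)
  Q1 <- build_rate_matrix(fr, params$kappa, 1, scale = FALSE)
  Q2 <- build_rate_matrix(fr, params$kappa, params$omega2, scale = FALSE)
  r <- function(Q) -sum(pi * diag(Q))
  rho <- (params$p0 + params$p2a) * r(Q0) +
    (params$p1 + params$p2b) * r(Q1)
  omega_pair <- switch(class_label,
                       `0` = c("Q0", "Q0"), `1` = c("Q1", "Q1"),
                       `2a` = c("Q0", "Q2"), `2b` = c("Q1", "Q2"))
  Qs <- list(Q0 = Q0, Q1 = Q1, Q2 = Q2)
  edge <- tree$phy$edge
  bl <- tree$phy$edge.length
  fg <- tree$foreground
  Ps <- lapply(seq_len(nrow(edge)), function(e) {
    transition_probabilities(
      Qs[[omega_pair[if (fg[e]) 2 else 1]]] / rho, bl[e])
  })
  ntip <- length(tree$phy$tip.label)
  n_int <- tree$phy$Nnode
  states <- venomscan:::.codon_states(aln)
  tips <- states[match(tree$phy$tip.label, aln$taxa), site]
  # vectorized enumeration over all internal-node assignments, chunked
  # to bound memory for 4 internal nodes (61^4 combinations)
  total <- 0
  chunk <- 200000L
  n_comb <- n_codon^n_int
  start <- 1
  while (start <= n_comb) {
    idx <- start:min(n_comb, start + chunk - 1L)
    # decode mixed-radix: column k = state of internal node ntip + k
    grid <- matrix(0L, length(idx), n_int)
    rem <- idx - 1L
    for (k in seq_len(n_int)) {
      grid[, k] <- rem %% n_codon + 1L
      rem <- rem %/% n_codon
    }
    p <- pi[grid[, 1]]  # root = ntip + 1 is the first internal node
    for (e in seq_len(nrow(edge))) {
      fromn <- edge[e, 1]
      ton <- edge[e, 2]
      from_state <- grid[, fromn - ntip]
      to_state <- if (ton <= ntip) {
        rep(tips[ton], length(idx))
      } else {
        grid[, ton - ntip]
      }
      if (ton <= ntip && is.na(tips[ton])) next
      p <- p * Ps[[e]][cbind(from_state, to_state)]
    }
    total <- total + sum(p)
    start <- start + chunk
  }
  total
}

# --- exhaustive rank-sum enumeration oracle ------------------------------
# Exact two-sided p for untied samples by enumerating every assignment of
# pooled ranks to the first group.
oracle_rank_sum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Ws <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  list(W = W_obs, p = p)
}

# small codon alignment simulated quickly on the 4-taxon fixture
fixture_alignment <- function(n_sites = 30, seed = 42, omega2 = 3) {
  simulate_codon_alignment(
    fixture_tree_4(),
    branch_site_params(2, 0.6, 0.2, 0.1, omega2),
    n_sites = n_sites, seed = seed)
}
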