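#' Study-shaped example tree for simulations
#'
#' A synthetic 26-leaf didelphid-like phylogeny (topology and branch
#' lengths are a constructed stand-in, not an estimate from data) with a
#' venom-resistant clade of nine tips: an aquatic-otter-analog lineage
#' ("Chironectes") sister to a clade of lutrine, four-eyed and common
#' opossum analogs.  Two foreground schemes are provided, mirroring the
#' uncertainty over whether the aquatic lineage is resistant: the full
#' resistant clade including its stem, or the clade excluding
#' "Chironectes" (with that smaller clade's stem).
#'
#' @param scheme `"didelphini"` (foreground = the whole resistant clade),
#'   `"didelphini_no_chironectes"`, or `"none"` (no foreground; null-model
#'   use).
#' @return A [selection_tree()].
#' @export
example_tree <- function(scheme = c("didelphini",
                                    "didelphini_no_chironectes",
                                    "none")) {
  scheme <- match.arg(scheme)
  nwk <- paste0(
    "(((Glironia:0.08,(Caluromys_philander:0.03,Caluromys_lanatus:0.03)",
    ":0.05):0.04,((((Marmosa:0.05,Micoureus:0.05):0.02,Tlacuatzin:0.06)",
    ":0.02,((Monodelphis_brevicaudata:0.04,Monodelphis_emiliae:0.04)",
    ":0.03,Marmosops:0.06):0.02):0.015,(((Thylamys:0.05,Lestodelphys_an",
    "alog:0.05):0.02,(Gracilinanus:0.045,Cryptonanus:0.045):0.025):0.01",
    "5,(Chacodelphys:0.06,Hyladelphys:0.07):0.015):0.01):0.02):0.02,(Me",
    "tachirus:0.075,(Chironectes:0.06,(Lutreolina:0.05,((Philander_fren",
    "atus:0.02,(Philander_opossum:0.015,Philander_mcilhennyi:0.015):0.0",
    "05):0.02,((Didelphis_virginiana:0.015,Didelphis_albiventris:0.015)",
    ":0.008,(Didelphis_marsupialis:0.012,Didelphis_imperfecta:0.012):0.",
    "011):0.017):0.01):0.01):0.015):0.02):0.0;"
  )
  tree <- read_labeled_tree(text = nwk)
  didelphini <- c("Chironectes", "Lutreolina", "Philander_frenatus",
                  "Philander_opossum", "Philander_mcilhennyi",
                  "Didelphis_virginiana", "Didelphis_albiventris",
                  "Didelphis_marsupialis", "Didelphis_imperfecta")
  if (scheme == "didelphini") {
    tree <- label_clade_foreground(tree, didelphini)
  } else if (scheme == "didelphini_no_chironectes") {
    tree <- label_clade_foreground(tree,
                                   setdiff(didelphini, "Chironectes"))
  }
  tree
}

#' Simulate a codon alignment under the branch-site mixture
#'
#' Each site independently draws a latent class from
#' `(p0, p1, p2a, p2b)`; the root codon is drawn from the equilibrium
#' frequencies and evolved along the tree with the class- and
#' branch-appropriate rate matrix.  By default child states are sampled
#' exactly from the matrix-exponential transition probabilities; with
#' `history = TRUE` a Gillespie path is simulated instead and every
#' substitution event is recorded (branch, site, from/to codon,
#' synonymous or not) so that substitution counts can be checked against
#' the generating model.
#'
#' Branch lengths are interpreted as expected substitutions per codon
#' under the model's own mixture-rate scaling (see
#' [build_rate_matrix()]).
#'
#' @param tree A `selection_tree`; foreground branches take `omega2` for
#'   classes 2a/2b.
#' @param params A [branch_site_params()].  Defaults emulate a strong
#'   episodic-selection regime on a conserved protein.
#' @param n_sites Number of codon sites.
#' @param freqs Codon frequencies (default uniform over sense codons).
#' @param seed RNG seed (default 2011).
#' @param history Record the full substitution history via Gillespie
#'   simulation (default FALSE).
#' @return A list: `alignment` (a [codon_alignment()]), `site_class`
#'   (factor of latent classes `0/1/2a/2b` per site), and with
#'   `history = TRUE` a data.frame `events` (`edge`, `foreground`,
#'   `site`, `class`, `from`, `to`, `nonsynonymous`).
#' @export
simulate_codon_alignment <- function(tree,
                                     params = branch_site_params(
                                       kappa = 2, p0 = 0.692, p1 = 0.205,
                                       omega0 = 0.054, omega2 = 6.79),
                                     n_sites = 300L, freqs = NULL,
                                     seed = 2011L, history = FALSE) {
  stopifnot(inherits(tree, "selection_tree"), n_sites >= 1)
  if (is.null(freqs)) freqs <- uniform_codon_frequencies()
  tab <- .universal_table()
  pi <- pmax(as.numeric(freqs), 0)
  pi[pi < 1e-10] <- 1e-10
  pi <- pi / sum(pi)
  fr <- structure(pi, names = tab$sense, class = "codon_frequencies")

  Q0 <- build_rate_matrix(fr, params$kappa, params$omega0, scale = FALSE)
  Q1 <- build_rate_matrix(fr, params$kappa, 1, scale = FALSE)
  Q2 <- build_rate_matrix(fr, params$kappa, params$omega2, scale = FALSE)
  props <- .class_props(params)
  rho <- (props[1] + props[3]) * .expected_rate(Q0) +
    (props[2] + props[4]) * .expected_rate(Q1)
  Qs <- list(w0 = Q0 / rho, w1 = Q1 / rho, w2 = Q2 / rho)

  phy <- ape::reorder.phylo(tree$phy, "postorder")
  key_in <- paste(tree$phy$edge[, 1], tree$phy$edge[, 2])
  key_po <- paste(phy$edge[, 1], phy$edge[, 2])
  fg <- tree$foreground[match(key_po, key_in)]
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  # preorder: reverse postorder edge order
  edge_order <- rev(seq_len(nrow(phy$edge)))

  class_names <- c("0", "1", "2a", "2b")
  omega_role <- list(`0` = c("w0", "w0"), `1` = c("w1", "w1"),
                     `2a` = c("w0", "w2"), `2b` = c("w1", "w2"))

  rng <- .seeded_rng(seed)
  site_class <- class_names[rng$sample_int(4L, n_sites, replace = TRUE,
                                           prob = props)]
  node_states <- matrix(NA_integer_, ntip + phy$Nnode, n_sites)
  node_states[root, ] <- rng$sample_int(length(pi), n_sites,
                                        replace = TRUE, prob = pi)

  # per (omega role): precompute decomposition for exact sampling
  decs <- lapply(Qs, .decompose_reversible)
  events <- if (history) list() else NULL

  for (e in edge_order) {
    parent <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    t <- phy$edge.length[e]
    for (cl in class_names) {
      idx <- which(site_class == cl)
      if (!length(idx)) next
      role <- omega_role[[cl]][if (fg[e]) 2L else 1L]
      from <- node_states[parent, idx]
      if (t == 0) {
        node_states[child, idx] <- from
        next
      }
      if (!history) {
        P <- .pmat_from_decomp(decs[[role]], t)
        P <- P / rowSums(P)
        to <- integer(length(from))
        for (s in unique(from)) {
          sel <- which(from == s)
          to[sel] <- rng$sample_int(length(pi), length(sel),
                                    replace = TRUE, prob = P[s, ])
        }
        node_states[child, idx] <- to
      } else {
        Q <- Qs[[role]]
        rates <- -diag(Q)
        to <- from
        for (k in seq_along(idx)) {
          s <- from[k]
          time <- 0
          repeat {
            r <- rates[s]
            if (r <= 0) break
            time <- time + rng$rexp(1, r)
            if (time > t) break
            nxt <- rng$sample_int(length(pi), 1L,
                                  prob = pmax(Q[s, ], 0) *
                                    (seq_along(pi) != s))
            events[[length(events) + 1L]] <- data.frame(
              edge = e, foreground = fg[e], site = idx[k], class = cl,
              from = tab$sense[s], to = tab$sense[nxt],
              nonsynonymous = tab$aa[s] != tab$aa[nxt])
            s <- nxt
          }
          to[k] <- s
        }
        node_states[child, idx] <- to
      }
    }
  }
  seqs <- vapply(seq_len(ntip), function(i) {
    paste0(tab$sense[node_states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- phy$tip.label
  aln <- codon_alignment(seqs)
  out <- list(alignment = aln,
              site_class = factor(site_class, levels = class_names),
              params = params, seed = seed)
  if (history) {
    out$events <- if (length(events)) do.call(rbind, events) else
      data.frame(edge = integer(), foreground = logical(),
                 site = integer(), class = character(),
                 from = character(), to = character(),
                 nonsynonymous = logical())
  }
  out
}

#' Simulate an amino-acid alignment with binding-site property shifts
#'
#' Emulates the resistant-vs-non-resistant contrast of the comparative
#' physicochemical analysis: all taxa descend from one ancestral
#' sequence with independent background substitution noise; resistant
#' taxa additionally receive, at annotated binding sites and their
#' neighbors (shift probability decaying as `exp(-d / decay_length)`),
#' a residue replacement chosen to move charge and hydropathy by
#' approximately the stated effect sizes.
#'
#' @param n_resistant,n_non_resistant Taxon counts (>= 2 each).
#' @param region_length Number of sites (default 320, the length of the
#'   sequenced vWF fragment).
#' @param start_pos Reference position of the first site (default 524).
#' @param binding Binding positions (default [binding_sites()]).
#' @param effect_size_charge Target |charge change| at a shifted site
#'   (default 2, e.g. Lys -> Glu).
#' @param effect_size_hydropathy Target |hydropathy change| at a shifted
#'   site (default 6, e.g. Gln -> Val scale distance).
#' @param decay_length Decay scale, in residues, of the shift probability
#'   away from binding sites; 0 restricts shifts to binding sites
#'   (default 0).
#' @param background_noise Per-site, per-taxon probability of a random
#'   residue substitution (default 0.02).
#' @param seed RNG seed (default 2011).
#' @return A list: `alignment` ([amino_alignment()]), `groups`
#'   ([taxon_groups()]), `binding` ([binding_sites()]), `coord`
#'   ([coordinate_map][build_coordinate_map()]), `shifted_sites`
#'   (reference positions that systematically differ), `shift_prob`
#'   (per-site probability applied).
#' @export
simulate_property_alignment <- function(n_resistant = 4L,
                                        n_non_resistant = 22L,
                                        region_length = 320L,
                                        start_pos = 524L,
                                        binding = binding_sites(),
                                        effect_size_charge = 2,
                                        effect_size_hydropathy = 6,
                                        decay_length = 0,
                                        background_noise = 0.02,
                                        seed = 2011L) {
  stopifnot(n_resistant >= 2, n_non_resistant >= 2, decay_length >= 0,
            region_length >= 1)
  rng <- .seeded_rng(seed)
  charge <- property_scale("charge")
  hydro <- property_scale("hydropathy")
  positions <- start_pos + seq_len(region_length) - 1L
  b <- as.integer(binding)
  b <- b[b >= min(positions) & b <= max(positions)]
  if (!length(b)) stop("no binding site falls inside the region")
  dist <- vapply(positions, function(p) min(abs(p - b)), numeric(1))
  shift_prob <- if (decay_length > 0) {
    exp(-dist / decay_length)
  } else {
    as.numeric(dist == 0)
  }
  if (effect_size_charge == 0 && effect_size_hydropathy == 0) {
    shift_prob[] <- 0  # no systematic contrast requested
  }

  # ancestral sequence: uniform over the 20 residues
  anc <- AA_ALPHABET[rng$sample_int(20L, region_length, replace = TRUE)]

  # for each site, pick the replacement residue whose property changes
  # best match the requested effect sizes (hydropathy scaled to charge
  # units so both contribute comparably)
  target_for <- function(res) {
    dc <- abs(charge[AA_ALPHABET] - charge[res])
    dh <- abs(hydro[AA_ALPHABET] - hydro[res])
    score <- abs(dc - effect_size_charge) +
      abs(dh - effect_size_hydropathy) / 4
    cand <- AA_ALPHABET[AA_ALPHABET != res]
    cand[which.min(score[cand])]
  }
  shifted_target <- vapply(anc, target_for, character(1))

  mutate_background <- function(seq) {
    hit <- rng$runif(region_length) < background_noise
    if (any(hit)) {
      for (i in which(hit)) {
        seq[i] <- AA_ALPHABET[rng$sample_int(20L, 1L)]
      }
    }
    seq
  }
  taxa_r <- sprintf("resistant_%02d", seq_len(n_resistant))
  taxa_n <- sprintf("nonresistant_%02d", seq_len(n_non_resistant))
  seqs <- character(0)
  for (tx in taxa_n) {
    seqs[tx] <- paste0(mutate_background(anc), collapse = "")
  }
  for (tx in taxa_r) {
    s <- mutate_background(anc)
    hit <- rng$runif(region_length) < shift_prob
    s[hit] <- shifted_target[hit]
    seqs[tx] <- paste0(s, collapse = "")
  }
  aln <- amino_alignment(seqs)
  coord <- build_coordinate_map(aln, reference_taxon = taxa_n[1],
                                start_pos = start_pos)
  list(alignment = aln,
       groups = taxon_groups(taxa_r, taxa_n),
       binding = binding_sites(b),
       coord = coord,
       shifted_sites = positions[shift_prob > 0],
       shift_prob = shift_prob,
       ancestral = paste0(anc, collapse = ""),
       seed = seed)
}
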