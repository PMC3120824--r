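#' @importFrom Biostrings GENETIC_CODE
NULL

NUCS <- c("A", "C", "G", "T")

# Transition pairs (purine<->purine, pyrimidine<->pyrimidine)
.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Genetic-code table for codon-model work
#'
#' Returns the sense codons, stop codons and codon-to-amino-acid map for a
#' genetic code.  Only the universal (standard) code is currently supported;
#' the table is taken from [Biostrings::GENETIC_CODE].
#'
#' @param code Genetic-code identifier; `"universal"` (alias `"standard"`).
#' @return A list with elements `sense` (character vector of sense codons,
#'   61 for the universal code), `stops`, `aa` (named character vector over
#'   sense codons), and `code` (the identifier, normalized).
#' @export
genetic_code_table <- function(code = "universal") {
  code <- match.arg(tolower(code), c("universal", "standard"))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  list(
    sense = sense,
    stops = names(gc)[gc == "*"],
    aa = gc[gc != "*"],
    code = "universal"
  )
}

# Cache: the universal table is used throughout.
.univ <- NULL
.universal_table <- function() {
  if (is.null(.univ)) {
    # assign in namespace at first use; loading order safe
    utils::assignInMyNamespace(".univ", genetic_code_table("universal"))
  }
  .univ
}

# 61 x 61 neighbor classification for the universal code.
# Returns a list of matrices: `type` (0 = not single-nt neighbors,
# 1 = synonymous transversion, 2 = synonymous transition,
# 3 = nonsynonymous transversion, 4 = nonsynonymous transition).
.codon_pair_classification <- function(tab = .universal_table()) {
  n <- length(tab$sense)
  split3 <- do.call(rbind, strsplit(tab$sense, ""))
  type <- matrix(0L, n, n, dimnames = list(tab$sense, tab$sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(split3[i, ] != split3[j, ])
      if (length(diff) != 1L) next
      ts <- .is_transition(split3[i, diff], split3[j, diff])
      ns <- tab$aa[i] != tab$aa[j]
      type[i, j] <- 1L + ts + 2L * ns
    }
  }
  type
}

.pair_class_cache <- NULL
.pair_classification <- function() {
  if (is.null(.pair_class_cache)) {
    utils::assignInMyNamespace(".pair_class_cache",
                               .codon_pair_classification())
  }
  .pair_class_cache
}

# Encode codon strings to indices into the sense-codon list.
# Codons containing any non-ACGT symbol (gaps, IUPAC ambiguity) -> NA.
.encode_codons <- function(codons, tab = .universal_table()) {
  idx <- match(codons, tab$sense)
  idx
}
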