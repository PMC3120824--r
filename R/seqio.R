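#' @importFrom Biostrings readBStringSet BStringSet writeXStringSet
NULL

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.check_taxa <- function(taxa) {
  if (length(taxa) == 0L) stop("alignment has no sequences")
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (any(!nzchar(taxa))) stop("empty taxon label")
  invisible(taxa)
}

#' In-frame codon alignment
#'
#' Construct a validated codon alignment from named nucleotide strings.
#' Sequences must be equal length and in frame (length divisible by 3).
#' Allowed symbols are `ACGT`, the gap character `-`, and IUPAC ambiguity
#' codes; any codon containing a non-ACGT symbol is treated as missing data
#' for that taxon at that site.  Stop codons before the final codon column
#' are a validation error; a stop in the final column is tolerated and
#' treated as missing.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (names are taxon labels; order is preserved).
#' @param code Genetic code identifier (see [genetic_code_table()]).
#' @return An object of class `codon_alignment` with fields `taxa`,
#'   `sequences`, `n_codons`, `code`.
#' @seealso [read_codon_alignment()]
#' @export
codon_alignment <- function(sequences, code = "universal") {
  taxa <- .check_taxa(names(sequences))
  sequences <- toupper(as.character(sequences))
  names(sequences) <- taxa
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ",
         paste(unique(lens), collapse = ", "))
  }
  for (i in seq_along(sequences)) {
    if (lens[i] %% 3L != 0L) {
      stop("frame error: sequence for taxon '", taxa[i], "' has length ",
           lens[i], ", not divisible by 3")
    }
  }
  bad <- grepl("[^ACGTUMRWSYKVHDBN-]", sequences)
  if (any(bad)) {
    stop("invalid nucleotide symbol in taxon '", taxa[which(bad)[1]], "'")
  }
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  tab <- genetic_code_table(code)
  n_codons <- unname(lens[1]) %/% 3L
  cod <- .codon_strings(sequences, n_codons)
  for (i in seq_along(taxa)) {
    hit <- which(cod[i, ] %in% tab$stops)
    internal <- hit[hit < n_codons]
    if (length(internal)) {
      stop("internal stop codon '", cod[i, internal[1]], "' in taxon '",
           taxa[i], "' at codon ", internal[1])
    }
  }
  structure(
    list(taxa = taxa, sequences = sequences, n_codons = n_codons,
         code = tab$code),
    class = "codon_alignment"
  )
}

# taxa x codon-column character matrix
.codon_strings <- function(sequences, n_codons) {
  out <- matrix("", length(sequences), n_codons,
                dimnames = list(names(sequences), NULL))
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  for (i in seq_along(sequences)) {
    out[i, ] <- substring(sequences[i], starts, starts + 2L)
  }
  out
}

#' Codon matrix view of an alignment
#'
#' @param aln A `codon_alignment`.
#' @return taxa x codon-column character matrix of codon strings.
#' @export
codon_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  .codon_strings(aln$sequences, aln$n_codons)
}

# taxa x codon-column integer matrix of sense-codon indices (NA = missing)
.codon_states <- function(aln) {
  cm <- codon_matrix(aln)
  st <- matrix(.encode_codons(as.vector(cm)), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  st
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$n_codons,
      "codons (", x$code, "code )\n")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path Path to a FASTA file.
#' @param code Genetic code identifier.
#' @return A validated [codon_alignment()]; taxon order follows the file.
#' @export
read_codon_alignment <- function(path, code = "universal") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  codon_alignment(seqs, code = code)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}

#' Amino-acid alignment
#'
#' Residues come from the canonical 20-letter alphabet plus gap (`-`) and
#' unknown (`X`); `*` is rejected.
#'
#' @param sequences Named character vector of aligned residue strings.
#' @return An object of class `amino_alignment` with `taxa`, `sequences`,
#'   `n_sites`.
#' @export
amino_alignment <- function(sequences) {
  taxa <- .check_taxa(names(sequences))
  sequences <- toupper(as.character(sequences))
  names(sequences) <- taxa
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ",
         paste(unique(lens), collapse = ", "))
  }
  ok <- paste0("[^", paste0(c(AA_ALPHABET, "X"), collapse = ""), "-]")
  bad <- grepl(ok, sequences)
  if (any(bad)) {
    i <- which(bad)[1]
    sym <- regmatches(sequences[i], regexpr(ok, sequences[i]))
    stop("invalid residue symbol '", sym, "' in taxon '", taxa[i], "'")
  }
  structure(list(taxa = taxa, sequences = sequences,
                 n_sites = unname(lens[1])),
            class = "amino_alignment")
}

#' @export
print.amino_alignment <- function(x, ...) {
  cat("amino_alignment:", length(x$taxa), "taxa x", x$n_sites, "sites\n")
  invisible(x)
}

#' Read an amino-acid alignment from FASTA
#'
#' @param path Path to a FASTA file.
#' @return An [amino_alignment()].
#' @export
read_amino_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  amino_alignment(seqs)
}

#' Write an amino-acid alignment to FASTA
#'
#' @param aln An `amino_alignment`.
#' @param path Output path.
#' @export
write_amino_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "amino_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}

#' Residue matrix view
#'
#' @param aln An `amino_alignment`.
#' @return taxa x site character matrix of single residues.
#' @export
residue_matrix <- function(aln) {
  stopifnot(inherits(aln, "amino_alignment"))
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$taxa
  m
}

#' Translate a codon alignment
#'
#' Codon columns with any ambiguous/gap nucleotide translate to `X`, except
#' all-gap codons which become `-`.  Used to carry reference coordinates
#' from protein numbering onto codon columns.
#'
#' @param aln A `codon_alignment`.
#' @return An [amino_alignment()] with one residue per codon column.
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- genetic_code_table(aln$code)
  cm <- codon_matrix(aln)
  aa <- matrix("X", nrow(cm), ncol(cm))
  known <- cm %in% tab$sense
  aa[known] <- tab$aa[match(cm[known], tab$sense)]
  aa[cm == "---"] <- "-"
  aa[cm %in% tab$stops] <- "X"
  seqs <- apply(aa, 1L, paste0, collapse = "")
  names(seqs) <- aln$taxa
  amino_alignment(seqs)
}

#' Taxon group assignment (venom-resistant vs non-resistant)
#'
#' @param resistant,non_resistant Character vectors of taxon labels; must be
#'   disjoint.  Matching elsewhere is exact and case-sensitive.
#' @return An object of class `taxon_groups`.
#' @export
taxon_groups <- function(resistant, non_resistant) {
  resistant <- unique(as.character(resistant))
  non_resistant <- unique(as.character(non_resistant))
  both <- intersect(resistant, non_resistant)
  if (length(both)) {
    stop("taxa assigned to both groups: ", paste(both, collapse = ", "))
  }
  if (!length(resistant) || !length(non_resistant)) {
    stop("both groups must be non-empty")
  }
  structure(list(resistant = resistant, non_resistant = non_resistant),
            class = "taxon_groups")
}

#' Read taxon groups from a two-column TSV (label, group)
#'
#' Group values are `resistant` / `non_resistant` (also accepts
#' `nonresistant`, `non-resistant`).
#'
#' @param path TSV path, no header.
#' @return A [taxon_groups()].
#' @export
read_taxon_groups <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 2L) stop("expected two columns (label, group)")
  g <- tolower(gsub("[-_]", "", d[[2]]))
  res <- d[[1]][g == "resistant"]
  non <- d[[1]][g == "nonresistant"]
  unknown <- d[[1]][!(g %in% c("resistant", "nonresistant"))]
  if (length(unknown)) stop("unknown group value for: ",
                            paste(unknown, collapse = ", "))
  taxon_groups(res, non)
}

#' Write taxon groups as TSV
#'
#' @param groups A `taxon_groups`.
#' @param path Output path.
#' @export
write_taxon_groups <- function(groups, path) {
  d <- data.frame(
    label = c(groups$resistant, groups$non_resistant),
    group = c(rep("resistant", length(groups$resistant)),
              rep("non_resistant", length(groups$non_resistant)))
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
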