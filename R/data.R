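#' Reference BEB posterior probabilities for the opossum vWF survey
#'
#' Per-site posterior probabilities of positive selection reported for
#' the sequenced vWF A1/A2 fragment under the two foreground schemes
#' (with and without the untested aquatic lineage among the
#' venom-resistant foreground), together with the binding-site flag.
#' Sites reported below 0.50, or absent for a scheme, are `NA`.  These
#' printed values serve as inputs for threshold filters and enrichment
#' counts; they are not recomputed by the package.
#'
#' @return data.frame with columns `ref_pos`, `residue`,
#'   `p_selected_exclude`, `p_selected_include`, `binding`.
#' @export
vwf_reference_posteriors <- function() {
  path <- system.file("extdata", "vwf_beb_reference.tsv",
                      package = "venomscan", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Reference enrichment counts for the selected-site G-test
#'
#' The published cross-classification of A1-domain sites at the
#' `P >= 0.95` threshold with the full resistant clade in the foreground:
#' 3 of the 12 botrocetin-binding sites and 4 of the 193 remaining A1
#' sites show strong evidence of positive selection.
#'
#' @return 2x2 integer matrix (rows binding/non-binding, columns
#'   selected/not selected).
#' @export
vwf_reference_enrichment_counts <- function() {
  matrix(c(3L, 9L, 4L, 189L), nrow = 2, byrow = TRUE,
         dimnames = list(c("binding", "non_binding"),
                         c("selected", "not_selected")))
}
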