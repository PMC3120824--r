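#' Default domain bounds (Mus mature-peptide numbering)
#'
#' The A1 domain of vWF spans residues 478-728; the region sequenced in
#' venom-resistance surveys spans 524-843.  Bounds are 1-based inclusive.
#' @name domain_bounds
#' @export
A1_BOUNDS <- c(478L, 728L)

#' @rdname domain_bounds
#' @export
SEQUENCED_BOUNDS <- c(524L, 843L)

#' Botrocetin-binding sites of the vWF A1 domain
#'
#' The 12 residues (Mus mature-peptide numbering) identified by
#' site-directed mutagenesis as critical for botrocetin binding.
#'
#' @param positions Integer positions (default the 12 canonical sites).
#' @param a1_bounds Inclusive bounds the positions must fall in.
#' @return An object of class `binding_site_set` (sorted unique integer
#'   vector with a bounds attribute).
#' @export
binding_sites <- function(positions = c(628L, 629L, 632L, 635L, 636L,
                                        639L, 643L, 660L, 661L, 664L,
                                        667L, 668L),
                          a1_bounds = A1_BOUNDS) {
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions)) stop("binding-site set is empty")
  out <- positions[positions < a1_bounds[1] | positions > a1_bounds[2]]
  if (length(out)) {
    stop("binding sites outside A1 bounds [", a1_bounds[1], ", ",
         a1_bounds[2], "]: ", paste(out, collapse = ", "))
  }
  structure(positions, class = "binding_site_set", a1_bounds = a1_bounds)
}

#' Read binding sites from a two-column TSV (label, position)
#'
#' Only the second column is used; the first is a free-text label.
#' @param path TSV path, no header.
#' @param ... Passed to [binding_sites()].
#' @export
read_binding_sites <- function(path, ...) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  col <- if (ncol(d) >= 2L) 2L else 1L
  binding_sites(as.integer(d[[col]]), ...)
}

#' Write binding sites as TSV
#' @param binding A `binding_site_set`.
#' @param path Output path.
#' @export
write_binding_sites <- function(binding, path) {
  d <- data.frame(label = paste0("site", seq_along(binding)),
                  position = as.integer(binding))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map alignment columns to reference residue coordinates
#'
#' Non-gap columns of the reference taxon's row receive consecutive
#' positions `start_pos, start_pos + 1, ...` (Mus mature-peptide numbering
#' in the vWF application); columns where the reference has a gap carry no
#' reference position.  Columns are 1-based here; any internal 0-based
#' indexing is converted at this boundary.
#'
#' @param aln An `amino_alignment`.
#' @param reference_taxon Label of the reference row (exact match).
#' @param start_pos Reference position of the first non-gap reference
#'   column (>= 1).
#' @param a1_bounds,sequenced_bounds Domain bounds stored for downstream
#'   region filters.
#' @return An object of class `coordinate_map`: a data.frame with columns
#'   `column` and `ref_pos` (NA where unmapped), plus attributes
#'   `reference_taxon`, `a1_bounds`, `sequenced_bounds`.
#' @export
build_coordinate_map <- function(aln, reference_taxon, start_pos,
                                 a1_bounds = A1_BOUNDS,
                                 sequenced_bounds = SEQUENCED_BOUNDS) {
  stopifnot(inherits(aln, "amino_alignment"))
  if (!reference_taxon %in% aln$taxa) {
    stop("reference taxon '", reference_taxon, "' not in alignment")
  }
  stopifnot(start_pos >= 1)
  start_pos <- as.integer(start_pos)
  res <- strsplit(aln$sequences[[reference_taxon]], "")[[1]]
  nongap <- res != "-"
  ref_pos <- rep(NA_integer_, length(res))
  ref_pos[nongap] <- start_pos + seq_len(sum(nongap)) - 1L
  map <- data.frame(column = seq_along(res), ref_pos = ref_pos)
  structure(map, class = c("coordinate_map", "data.frame"),
            reference_taxon = reference_taxon,
            a1_bounds = as.integer(a1_bounds),
            sequenced_bounds = as.integer(sequenced_bounds))
}

#' Reference position of alignment columns
#' @param map A `coordinate_map`.
#' @param column Column indices (1-based).
#' @return Integer reference positions (NA where the reference has a gap).
#' @export
ref_position <- function(map, column) {
  stopifnot(inherits(map, "coordinate_map"))
  if (any(column < 1L | column > nrow(map))) {
    stop("column index out of range")
  }
  map$ref_pos[column]
}

#' Alignment column of reference positions
#' @param map A `coordinate_map`.
#' @param pos Reference positions.
#' @return Integer column indices; error if any position is unmapped.
#' @export
column_of <- function(map, pos) {
  stopifnot(inherits(map, "coordinate_map"))
  idx <- match(as.integer(pos), map$ref_pos)
  if (anyNA(idx)) {
    stop("reference position(s) outside mapped range: ",
         paste(pos[is.na(idx)], collapse = ", "))
  }
  map$column[idx]
}

#' Export a coordinate map as TSV (column, reference position)
#' @param map A `coordinate_map`.
#' @param path Output path.
#' @export
write_coordinate_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
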