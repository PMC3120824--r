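#' Load and validate an analysis configuration
#'
#' The configuration is a JSON object with file paths and analysis
#' settings.  Recognized fields: `codon_alignment`, `tree` /
#' `tree_no_aquatic` (Newick with `#1` tags, one per foreground scheme),
#' `amino_alignment`, `groups`, `binding`, `reference_taxon`,
#' `start_pos`, `thresholds` (default `[0.5, 0.95]`), `window` (default
#' 5), `n_perm` (default 1000), `n_restarts` (default 5), `seed`
#' (default 2011), `out_dir`.  Referenced files must exist.
#'
#' @param path Path to the JSON configuration.
#' @return A validated config list (class `analysis_config`).
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(thresholds = c(0.5, 0.95), window = 5L,
                   n_perm = 1000L, n_restarts = 5L, seed = 2011L,
                   start_pos = 524L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  .validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

.validate_config <- function(cfg) {
  for (f in c("codon_alignment", "tree", "tree_no_aquatic",
              "amino_alignment", "groups", "binding")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("configured file not found: ", f, " = ", cfg[[f]])
    }
  }
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 1)) {
    stop("thresholds must lie in (0, 1]")
  }
  if (cfg$window %% 2 == 0) stop("window must be odd")
  invisible(cfg)
}

#' Run the configured study-shaped analysis
#'
#' Dispatches to [run_selection_scan()] (when a codon alignment and at
#' least one labeled tree are configured) and [run_physchem_scan()]
#' (when an amino-acid alignment, groups and binding sites are
#' configured), writing reports under `out_dir`.
#'
#' @param config An `analysis_config` (or a path to one).
#' @param dry_run Validate the configuration and return without
#'   computing (default FALSE).
#' @return A list with elements `selection` and/or `physchem`.
#' @export
run_analysis <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- load_analysis_config(config)
  .validate_config(config)
  if (dry_run) return(invisible(list(config = config)))
  out <- list()
  binding <- if (!is.null(config$binding)) {
    read_binding_sites(config$binding)
  } else NULL
  if (!is.null(config$codon_alignment) && !is.null(config$tree)) {
    aln <- read_codon_alignment(config$codon_alignment)
    trees <- list(with_aquatic = read_labeled_tree(config$tree))
    if (!is.null(config$tree_no_aquatic)) {
      trees$without_aquatic <- read_labeled_tree(config$tree_no_aquatic)
    }
    coord <- NULL
    if (!is.null(config$reference_taxon)) {
      coord <- build_coordinate_map(translate_alignment(aln),
                                    config$reference_taxon,
                                    config$start_pos)
    }
    out$selection <- run_selection_scan(
      aln, trees, coord = coord, binding = binding,
      thresholds = config$thresholds, n_restarts = config$n_restarts,
      seed = config$seed, out_dir = config$out_dir)
  }
  if (!is.null(config$amino_alignment) && !is.null(config$groups) &&
      !is.null(binding)) {
    aa <- read_amino_alignment(config$amino_alignment)
    groups <- read_taxon_groups(config$groups)
    ref <- config$reference_taxon %||% aa$taxa[1]
    coord <- build_coordinate_map(aa, ref, config$start_pos)
    out$physchem <- run_physchem_scan(
      aa, groups, coord, binding, window = config$window,
      n_perm = config$n_perm, seed = config$seed,
      out_dir = config$out_dir)
  }
  if (!length(out)) {
    stop("config specifies neither a selection nor a physchem analysis")
  }
  out
}
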