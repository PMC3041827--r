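# The feature registry: an ordered, data-driven catalogue of the 243 feature
# values. The per-group breakdown summing to 243 is a repo convention (the 18
# source features are known, their per-value dimensionality is not), recorded
# here so alternative breakdowns stay configurable.

.registry_version <- "uriexc-registry-243-v1"

registry_block <- function(names, group, scale_hint) {
  data.frame(name = names, group = group, scale_hint = scale_hint,
             stringsAsFactors = FALSE)
}

#' Default feature registry
#'
#' Ordered catalogue of the 243 feature values: 0-based index, name, feature
#' group and scale hint. Blocks: amino-acid composition (20), CTD descriptors
#' over 7 property partitions (147), secondary-structure content (3),
#' disorder (3), signal peptide (2), membrane/motifs (3), glycosylation (2),
#' charge (7), ProtParam indices (5), and length-normalized sequence
#' statistics (51: N-terminal and C-terminal window compositions plus 11
#' global fractions).
#'
#' @return data.frame with columns `index` (0-based), `name`, `group`,
#'   `scale_hint`; `attr(, "registry_version")` identifies the layout.
#' @examples
#' nrow(default_registry())
#' @export
default_registry <- function() {
  ctd_names <- names(ctd_features(.aa_alphabet))
  qs <- c("first", "q25", "q50", "q75", "q100")
  blocks <- rbind(
    registry_block(paste0("comp_", .aa_alphabet_split), "aa_composition", "continuous"),
    registry_block(ctd_names, "ctd", "continuous"),
    registry_block(c("ss_helix", "ss_strand", "ss_coil"), "secondary_structure", "continuous"),
    registry_block(c("dis_mean_foldindex", "dis_frac_disordered", "dis_longest_run"),
                   "disorder", "continuous"),
    registry_block(c("sp_score", "sp_call"), "signal_peptide", c("continuous", "binary")),
    registry_block(c("mem_tm_count", "mem_barrel_score", "mem_tat_flag"),
                   "membrane_motif", c("count", "continuous", "binary")),
    registry_block(c("gly_sequon_density", "gly_st_density"), "glycosylation", "continuous"),
    registry_block(c("chg_net", "chg_frac_K", "chg_frac_R", "chg_frac_H",
                     "chg_frac_positive", "chg_frac_negative", "chg_net_per_residue"),
                   "charge", "continuous"),
    registry_block(c("pp_mw", "pp_pi", "pp_gravy", "pp_instability", "pp_aliphatic"),
                   "protparam", "continuous"),
    registry_block(paste0("nterm_comp_", .aa_alphabet_split), "seq_stats", "continuous"),
    registry_block(paste0("cterm_comp_", .aa_alphabet_split), "seq_stats", "continuous"),
    registry_block(c("st_log_length", "st_aromaticity", "st_frac_tiny", "st_frac_small",
                     "st_frac_aliphatic", "st_frac_aromatic", "st_frac_polar",
                     "st_frac_nonpolar", "st_frac_charged", "st_frac_sulfur",
                     "st_frac_hydroxyl"), "seq_stats", "continuous")
  )
  blocks$index <- seq_len(nrow(blocks)) - 1L
  blocks <- blocks[, c("index", "name", "group", "scale_hint")]
  stopifnot(!anyDuplicated(blocks$name))
  attr(blocks, "registry_version") <- .registry_version
  blocks
}

#' Compute the full feature vector for one protein
#'
#' Concatenates all feature-group outputs in registry order. Deterministic:
#' the same sequence always yields a bit-identical vector.
#'
#' @param record a [protein_record()] (or a bare sequence string).
#' @param registry feature registry, default [default_registry()].
#' @return named numeric vector aligned to `registry$name` (length 243 for
#'   the default registry), with `attr(, "registry_version")`.
#' @examples
#' v <- compute_feature_vector(protein_record("P1", "MKWVTFISLLLLFSSAYS"))
#' length(v)
#' @export
compute_feature_vector <- function(record, registry = default_registry()) {
  sequence <- if (inherits(record, "protein_record")) record$sequence else record
  vals <- c(
    aa_composition(sequence),
    suppressWarnings(ctd_features(sequence)),
    secondary_structure_content(sequence),
    disorder_features(sequence, .feature_config$disorder$window),
    signal_peptide_features(sequence),
    membrane_motif_features(sequence),
    glycosylation_features(sequence)[c("gly_sequon_density", "gly_st_density")],
    charge_features(sequence),
    suppressWarnings(protparam_features(sequence)),
    seqstat_features(sequence)
  )
  missing <- setdiff(registry$name, names(vals))
  if (length(missing) > 0L) {
    stop(sprintf("registry names not produced by any feature group: %s",
                 paste(missing, collapse = ", ")))
  }
  out <- vals[registry$name]
  stopifnot(all(is.finite(out)))
  attr(out, "registry_version") <- attr(registry, "registry_version")
  out
}

#' Compute the feature matrix for many proteins
#'
#' @param records list of [protein_record()] objects.
#' @param registry feature registry.
#' @return numeric matrix, proteins x features, rownames = protein ids,
#'   colnames = registry names; `attr(, "registry_version")` set.
#' @export
compute_feature_matrix <- function(records, registry = default_registry()) {
  stopifnot(length(records) > 0L)
  rows <- lapply(records, compute_feature_vector, registry = registry)
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(records, function(r) r$id, "")
  attr(mat, "registry_version") <- attr(registry, "registry_version")
  mat
}

#' Write a feature matrix as TSV
#'
#' First column `protein_id`, remaining columns the registry feature names;
#' header row mandatory. [read_feature_matrix()] reverses this losslessly.
#'
#' @param mat matrix from [compute_feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with protein ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(colnames(df)[1] == "protein_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$protein_id
  mat
}

#' Write the registry as JSON
#'
#' @param registry registry data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(
    list(registry_version = attr(registry, "registry_version"),
         features = registry),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
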