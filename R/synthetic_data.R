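# Synthetic fixtures: two-class protein sequences, protein-family tables and
# paired tumor/control expression matrices with planted effects. Every
# generator is a pure function of its spec (seed included).

#' Simulation specification
#'
#' One stated world for all generators. Defaults emulate the data regimes the
#' pipeline is meant for: a positive class rich in signal-peptide-like
#' N-termini, positive charge and helix-favoring residues versus background
#' human-proteome composition; family tables mixing positive-contaminated and
#' clean families; and paired expression with a small planted
#' differentially-expressed fraction under lognormal noise. See the methods
#' vignette for the rationale of each default.
#'
#' @param n_pos,n_neg class sizes (default 200 / 400, a 1:2 imbalance like
#'   the training regime the method targets).
#' @param len_range sequence length range (default 100-500 residues).
#' @param sp_prob probability that a positive carries a signal-peptide-like
#'   N-terminal prefix (default 0.9).
#' @param kr_boost relative enrichment of K/R in positives (default 0.5).
#' @param helix_boost relative enrichment of helix-favoring residues
#'   (A, E, L, M, Q) in positives (default 0.3).
#' @param n_genes,n_pairs expression matrix size (default 1000 genes x 80
#'   pairs).
#' @param de_fraction fraction of genes with a planted effect (default 0.05).
#' @param fold_effect planted fold-change (default 4).
#' @param affected_fraction fraction of pairs in which a planted gene is
#'   shifted (default 0.5).
#' @param noise_sdlog lognormal noise SD on the log scale (default 0.5).
#' @param n_families,family_size_range,contaminated_fraction family-table
#'   shape (default 30 families of 2-20 proteins, 30% containing positives).
#' @param seed integer RNG seed.
#' @return `simulation_spec` list.
#' @export
simulation_spec <- function(n_pos = 200L, n_neg = 400L,
                            len_range = c(100L, 500L),
                            sp_prob = 0.9, kr_boost = 0.5, helix_boost = 0.3,
                            n_genes = 1000L, n_pairs = 80L,
                            de_fraction = 0.05, fold_effect = 4,
                            affected_fraction = 0.5, noise_sdlog = 0.5,
                            n_families = 30L, family_size_range = c(2L, 20L),
                            contaminated_fraction = 0.3, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(len_range) == 2L,
            len_range[1] >= 15L, len_range[1] <= len_range[2],
            sp_prob >= 0, sp_prob <= 1, kr_boost >= 0, helix_boost >= 0,
            n_genes >= 1L, n_pairs >= 1L,
            de_fraction >= 0, de_fraction <= 1, fold_effect >= 1,
            affected_fraction >= 0, affected_fraction <= 1, noise_sdlog >= 0,
            n_families >= 1L, contaminated_fraction >= 0,
            contaminated_fraction <= 1)
  structure(as.list(environment()), class = "simulation_spec")
}

sample_residues <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

# signal-peptide-like prefix: Met start, short basic n-region, hydrophobic
# h-region, small-residue c-region
random_signal_prefix <- function() {
  n_len <- sample(2:5, 1)
  h_len <- sample(9:12, 1)
  n_region <- sample(c("K", "R", "N", "S", "T"), n_len, replace = TRUE,
                     prob = c(0.35, 0.35, 0.1, 0.1, 0.1))
  h_region <- sample(c("L", "A", "V", "I", "F"), h_len, replace = TRUE,
                     prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  c_region <- sample(c("A", "S", "G", "P"), 4, replace = TRUE)
  paste(c("M", n_region, h_region, c_region), collapse = "")
}

#' Simulate a two-class protein set
#'
#' Positives are drawn from a K/R- and helix-residue-enriched composition and
#' carry a signal-peptide-like N-terminal prefix with probability
#' `spec$sp_prob`; negatives are drawn from background human-proteome
#' composition. Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return list: `records` (list of [protein_record()]),
#'   `labels` (data.frame `protein_id`, `label` with +1/-1).
#' @export
simulate_proteins <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  pos_freq <- .human_aa_freq
  pos_freq[c("K", "R")] <- pos_freq[c("K", "R")] * (1 + spec$kr_boost)
  pos_freq[c("A", "E", "L", "M", "Q")] <-
    pos_freq[c("A", "E", "L", "M", "Q")] * (1 + spec$helix_boost)
  pos_freq <- pos_freq / sum(pos_freq)

  withr::with_seed(as.integer(spec$seed), {
    make_one <- function(i, positive) {
      len <- sample(seq(spec$len_range[1], spec$len_range[2]), 1)
      freq <- if (positive) pos_freq else .human_aa_freq
      body <- paste(sample_residues(len, freq), collapse = "")
      if (positive && stats::runif(1) < spec$sp_prob) {
        prefix <- random_signal_prefix()
        body <- paste0(prefix, substr(body, nchar(prefix) + 1, len))
      }
      protein_record(sprintf("%s%04d", if (positive) "POS" else "NEG", i), body)
    }
    records <- c(lapply(seq_len(spec$n_pos), make_one, positive = TRUE),
                 lapply(seq_len(spec$n_neg), make_one, positive = FALSE))
  })
  labels <- data.frame(
    protein_id = vapply(records, function(r) r$id, ""),
    label = rep(c(1L, -1L), c(spec$n_pos, spec$n_neg)),
    stringsAsFactors = FALSE)
  list(records = records, labels = labels)
}

#' Simulate a protein-family table
#'
#' Families draw sizes uniformly from `spec$family_size_range`; a
#' `spec$contaminated_fraction` of them receive 1-3 positive members. The
#' returned positives list marks exactly the contaminating proteins, so
#' [eligible_families()] on this table excludes exactly the contaminated
#' families.
#'
#' @param spec a [simulation_spec()].
#' @return list: `table` (data.frame `protein_id`, `family_id`),
#'   `positives` (character vector).
#' @export
simulate_family_table <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(as.integer(spec$seed), {
    sizes <- sample(seq(spec$family_size_range[1], spec$family_size_range[2]),
                    spec$n_families, replace = TRUE)
    contaminated <- stats::runif(spec$n_families) < spec$contaminated_fraction
    rows <- list(); positives <- character(0); serial <- 0L
    for (f in seq_len(spec$n_families)) {
      fam <- sprintf("FAM%03d", f)
      ids <- sprintf("PROT%05d", serial + seq_len(sizes[f]))
      serial <- serial + sizes[f]
      if (contaminated[f]) {
        k <- sample(seq_len(min(3L, sizes[f])), 1)
        positives <- c(positives, ids[seq_len(k)])
      }
      rows[[f]] <- data.frame(protein_id = ids, family_id = fam,
                              stringsAsFactors = FALSE)
    }
  })
  list(table = do.call(rbind, rows), positives = positives)
}

#' Simulate a paired tumor/control expression matrix
#'
#' Per-gene baseline levels are lognormal; tumor and control values add
#' independent lognormal noise (`spec$noise_sdlog`), so unplanted genes are
#' exchangeable within pairs. A `spec$de_fraction` of genes is planted: in a
#' random `spec$affected_fraction` of pairs the tumor (or, for half of the
#' planted genes, the control) value is multiplied by `spec$fold_effect`.
#'
#' @param spec a [simulation_spec()].
#' @return list: `tumor`, `control` (gene x pair matrices),
#'   `truth` (data.frame `gene_id`, `planted`, `direction`).
#' @export
simulate_paired_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(as.integer(spec$seed), {
    g <- spec$n_genes; p <- spec$n_pairs
    base <- exp(stats::rnorm(g, mean = log(100), sd = 1))
    noise <- function() {
      matrix(exp(stats::rnorm(g * p, sd = spec$noise_sdlog)), g, p)
    }
    tumor <- base * noise()
    control <- base * noise()
    gene_ids <- sprintf("GENE%05d", seq_len(g))
    rownames(tumor) <- rownames(control) <- gene_ids

    n_planted <- round(g * spec$de_fraction)
    planted <- if (n_planted > 0) sort(sample.int(g, n_planted)) else integer(0)
    dir <- rep("none", g)
    for (i in planted) {
      up <- stats::runif(1) < 0.5
      dir[i] <- if (up) "up" else "down"
      hit <- stats::runif(p) < spec$affected_fraction
      if (up) tumor[i, hit] <- tumor[i, hit] * spec$fold_effect
      else control[i, hit] <- control[i, hit] * spec$fold_effect
    }
  })
  truth <- data.frame(gene_id = gene_ids,
                      planted = seq_len(spec$n_genes) %in% planted,
                      direction = dir, stringsAsFactors = FALSE)
  list(tumor = tumor, control = control, truth = truth)
}
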