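# Paired tumor-versus-control fold-change statistic: per gene, K_exp = the
# number of tissue pairs whose fold-change reaches the cutoff, with a
# within-pair label-swap permutation null.

#' Count pairs reaching a fold-change (K_exp)
#'
#' @param tumor,control positive expression values, one per tissue pair.
#' @param fold fold cutoff >= 1 (default 2).
#' @param direction `"up"` counts pairs with `tumor/control >= fold`,
#'   `"down"` counts `control/tumor >= fold`, `"either"` (default) counts
#'   pairs where the larger of the two ratios reaches the fold.
#' @return integer count in `[0, n_pairs]`.
#' @examples
#' k_exp(c(4, 1, 2), c(1, 1, 1), direction = "up")  # 2
#' @export
k_exp <- function(tumor, control, fold = 2, direction = c("either", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(tumor) == length(control), all(tumor > 0), all(control > 0))
  if (!is.numeric(fold) || fold < 1) stop("fold must be >= 1")
  up <- tumor / control >= fold
  dn <- control / tumor >= fold
  switch(direction,
         up = sum(up),
         down = sum(dn),
         either = sum(up | dn))
}

# directional exceedance summary used by the permutation test: which pairs
# reach the fold in either direction, and in which direction
exceedance <- function(tumor, control, fold) {
  lr <- log(tumor) - log(control)
  e <- abs(lr) >= log(fold)
  list(n_exceed = sum(e), n_up = sum(e & lr > 0))
}

#' Permutation p-value for K_exp
#'
#' Null model: within each tissue pair, the tumor/control labels are swapped
#' independently with probability 1/2 (exact exchangeability under no
#' effect). Swapping inverts a pair's ratio but not its magnitude, so the
#' two-sided (`direction = "either"`) test statistic is `max(K_up, K_down)`,
#' the larger of the two directional counts; for `"up"`/`"down"` it is the
#' directional K_exp itself. p = (1 + #\{permuted statistic >= observed\}) /
#' (1 + n_perm).
#'
#' @inheritParams k_exp
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param exact if `TRUE`, use the closed-form binomial null (each exceeding
#'   pair lands in the tested direction with probability 1/2 under swaps)
#'   instead of Monte Carlo; the Monte Carlo default matches the stated
#'   permutation recipe.
#' @return p-value in `(0, 1]`.
#' @export
k_exp_pvalue <- function(tumor, control, fold = 2,
                         direction = c("either", "up", "down"),
                         n_perm = 10000L, seed = 1L, exact = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(tumor) == length(control), length(tumor) >= 2L,
            all(tumor > 0), all(control > 0))
  if (!exact && n_perm < 100L) stop("n_perm must be >= 100")
  ex <- exceedance(tumor, control, fold)
  obs <- switch(direction,
                up = ex$n_up,
                down = ex$n_exceed - ex$n_up,
                either = max(ex$n_up, ex$n_exceed - ex$n_up))
  if (exact) return(binomial_null_pvalue(obs, ex$n_exceed, direction))
  withr::with_seed(as.integer(seed), {
    # under a swap each exceeding pair points up with probability 1/2;
    # non-exceeding pairs can never contribute (magnitude is swap-invariant)
    k_up <- stats::rbinom(n_perm, ex$n_exceed, 0.5)
  })
  stat <- switch(direction,
                 up = k_up,
                 down = ex$n_exceed - k_up,
                 either = pmax(k_up, ex$n_exceed - k_up))
  (1 + sum(stat >= obs)) / (1 + n_perm)
}

binomial_null_pvalue <- function(obs, n_exceed, direction) {
  if (n_exceed == 0L) return(1)
  if (direction %in% c("up", "down")) {
    return(stats::pbinom(obs - 1L, n_exceed, 0.5, lower.tail = FALSE))
  }
  if (obs <= ceiling(n_exceed / 2)) return(1)
  p <- 2 * stats::pbinom(obs - 1L, n_exceed, 0.5, lower.tail = FALSE)
  min(1, p)
}

#' Differential-expression calls for a paired expression matrix
#'
#' @param tumor,control numeric gene x pair matrices with identical
#'   dimensions, positive entries, gene ids as rownames.
#' @param fold fold cutoff (default 2).
#' @param alpha significance level on the K_exp p-value (default 0.05, no
#'   multiple-testing correction, matching the p < 0.05 rule; set
#'   `fdr = TRUE` for a Benjamini-Hochberg variant).
#' @param n_perm permutations per gene.
#' @param seed integer seed; per-gene streams are derived from it.
#' @param direction see [k_exp()].
#' @param fdr adjust p-values by Benjamini-Hochberg before flagging.
#' @param exact use the closed-form binomial null (see [k_exp_pvalue()]).
#' @return data.frame: `gene_id`, `k_exp`, `direction` (up/down/mixed/none),
#'   `p_value`, `de_flag`, ordered by ascending p then gene id.
#' @export
call_de <- function(tumor, control, fold = 2, alpha = 0.05, n_perm = 10000L,
                    seed = 1L, direction = c("either", "up", "down"),
                    fdr = FALSE, exact = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(tumor), is.matrix(control),
            all(dim(tumor) == dim(control)),
            all(tumor > 0), all(control > 0), alpha >= 0, alpha <= 1)
  genes <- rownames(tumor)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tumor)))
  res <- lapply(seq_len(nrow(tumor)), function(i) {
    tu <- tumor[i, ]; co <- control[i, ]
    ex <- exceedance(tu, co, fold)
    n_dn <- ex$n_exceed - ex$n_up
    dir_i <- if (ex$n_exceed == 0L) "none"
             else if (ex$n_up == ex$n_exceed) "up"
             else if (n_dn == ex$n_exceed) "down"
             else "mixed"
    p <- k_exp_pvalue(tu, co, fold, direction,
                      n_perm = n_perm, seed = gene_seed(seed, genes[i]),
                      exact = exact)
    data.frame(gene_id = genes[i],
               k_exp = k_exp(tu, co, fold, direction),
               direction = dir_i, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_use <- if (fdr) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$de_flag <- p_use < alpha
  out[order(out$p_value, out$gene_id), , drop = FALSE]
}

# derived per-gene seed from the gene id (so results are equivariant under
# row permutation), kept below 2^31
gene_seed <- function(seed, id) {
  v <- utf8ToInt(id)
  h <- sum(v * (seq_along(v) %% 31 + 1)) %% 1e6
  as.integer((as.numeric(seed) * 7919 + h * 1013) %% 2147483647)
}

#' Read a paired expression matrix
#'
#' TSV with `gene_id` then alternating tumor/control columns named
#' `<pair>_tumor`, `<pair>_control`.
#'
#' @param path TSV path.
#' @return list with matrices `tumor`, `control` and `pair_ids`.
#' @export
read_paired_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(colnames(df)[1] == "gene_id")
  cols <- colnames(df)[-1]
  tu_cols <- grep("_tumor$", cols, value = TRUE)
  co_cols <- grep("_control$", cols, value = TRUE)
  pairs <- sub("_tumor$", "", tu_cols)
  stopifnot(length(tu_cols) > 0L, identical(pairs, sub("_control$", "", co_cols)))
  tumor <- as.matrix(df[, tu_cols, drop = FALSE])
  control <- as.matrix(df[, co_cols, drop = FALSE])
  rownames(tumor) <- rownames(control) <- df$gene_id
  list(tumor = tumor, control = control, pair_ids = pairs)
}

#' Write a paired expression matrix
#'
#' @param tumor,control gene x pair matrices.
#' @param path output path.
#' @param pair_ids optional pair identifiers.
#' @return `path`, invisibly.
#' @export
write_paired_expression <- function(tumor, control, path, pair_ids = NULL) {
  stopifnot(all(dim(tumor) == dim(control)))
  if (is.null(pair_ids)) pair_ids <- paste0("pair", seq_len(ncol(tumor)))
  out <- data.frame(gene_id = rownames(tumor), stringsAsFactors = FALSE)
  for (j in seq_along(pair_ids)) {
    out[[paste0(pair_ids[j], "_tumor")]] <- tumor[, j]
    out[[paste0(pair_ids[j], "_control")]] <- control[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
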