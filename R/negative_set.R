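# Negative-training-set construction: sample proteins only from families with
# no positive member, at least one per family, proportional to family size.

#' Read a protein-family table
#'
#' Two-column TSV (`protein_id`, `family_id`), one row per membership; a
#' protein may belong to several families.
#'
#' @param path TSV path.
#' @return data.frame with columns `protein_id`, `family_id`.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "family_id") %in% colnames(df)))
  validate_family_table(df)
}

validate_family_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("protein_id", "family_id") %in% colnames(table)))
  if (nrow(table) == 0L) stop("family table is empty")
  if (anyDuplicated(table[, c("protein_id", "family_id")])) {
    stop("duplicate (protein, family) pairs in family table")
  }
  table
}

#' Families free of positive training proteins
#'
#' A family is eligible when none of its members is a positive. Proteins that
#' belong to any positive-containing family are additionally excluded from
#' sampling altogether (see [sample_negatives()]).
#'
#' @param table family table (`protein_id`, `family_id`).
#' @param positives character vector of positive protein ids.
#' @return character vector of eligible family ids.
#' @export
eligible_families <- function(table, positives) {
  table <- validate_family_table(table)
  contaminated <- unique(table$family_id[table$protein_id %in% positives])
  out <- setdiff(unique(table$family_id), contaminated)
  if (length(out) == 0L) stop("no family is free of positive proteins")
  out
}

# largest-remainder apportionment with an at-least-one floor and a
# family-size cap
allocate_proportional <- function(sizes, budget) {
  stopifnot(budget >= length(sizes), budget <= sum(sizes))
  quota <- budget * sizes / sum(sizes)
  alloc <- pmin(pmax(1L, as.integer(floor(quota + 0.5))), sizes)
  # adjust to hit the budget exactly, moving along the largest remainders
  repeat {
    diff <- budget - sum(alloc)
    if (diff == 0L) break
    rem <- quota - alloc
    if (diff > 0L) {
      cand <- which(alloc < sizes)
      pick <- cand[order(-rem[cand], cand)][seq_len(min(diff, length(cand)))]
      alloc[pick] <- alloc[pick] + 1L
    } else {
      cand <- which(alloc > 1L)
      pick <- cand[order(rem[cand], cand)][seq_len(min(-diff, length(cand)))]
      alloc[pick] <- alloc[pick] - 1L
    }
  }
  alloc
}

#' Sample a negative training set
#'
#' Keeps only proteins whose every family is free of positives, assigns each
#' remaining protein to its largest eligible family (so multi-family proteins
#' are counted once), allocates the budget proportionally to family size with
#' an at-least-one floor (largest-remainder rounding, capped at family size)
#' and draws members uniformly without replacement within each family.
#' The allocation is deterministic; only member identity depends on the seed.
#'
#' @param table family table (`protein_id`, `family_id`).
#' @param positives character vector of positive protein ids.
#' @param budget total number of negatives to draw; must be at least the
#'   number of eligible families and at most the eligible pool size.
#' @param seed integer RNG seed.
#' @return character vector of `budget` sampled protein ids.
#' @examples
#' tab <- data.frame(protein_id = c(paste0("a", 1:4), "b1", "b2"),
#'                   family_id = rep(c("FA", "FB"), c(4, 2)))
#' sample_negatives(tab, positives = character(0), budget = 3, seed = 1)
#' @export
sample_negatives <- function(table, positives, budget, seed = 1L) {
  table <- validate_family_table(table)
  stopifnot(is.numeric(budget), length(budget) == 1L, budget == round(budget))
  fams <- eligible_families(table, positives)
  elig <- table[table$family_id %in% fams, , drop = FALSE]
  # drop proteins with any contaminated membership
  contaminated_prot <- unique(table$protein_id[!(table$family_id %in% fams)])
  elig <- elig[!(elig$protein_id %in% contaminated_prot), , drop = FALSE]
  if (nrow(elig) == 0L) stop("no eligible proteins outside positive-containing families")

  fam_size_all <- table(elig$family_id)
  # assign each protein to its largest eligible family, ties by family id
  split_f <- split(elig$family_id, elig$protein_id)
  assigned <- vapply(split_f, function(fs) {
    fs[order(-as.numeric(fam_size_all[fs]), fs)][1]
  }, "")
  pool <- split(names(assigned), assigned)
  sizes <- lengths(pool)
  if (budget < length(sizes)) {
    stop(sprintf(
      "budget %d < %d eligible families; the at-least-one-per-family rule is unsatisfiable",
      budget, length(sizes)))
  }
  if (budget > sum(sizes)) {
    stop(sprintf("budget %d exceeds eligible pool size %d", budget, sum(sizes)))
  }
  alloc <- allocate_proportional(as.integer(sizes), as.integer(budget))
  withr::with_seed(as.integer(seed), {
    out <- unlist(lapply(seq_along(pool), function(i) {
      members <- sort(pool[[i]])
      members[sample.int(length(members), alloc[i])]
    }), use.names = FALSE)
  })
  out
}
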