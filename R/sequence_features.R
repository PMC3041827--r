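# Sequence-derived physicochemical features.
#
# Every operation is a pure function of (sequence, shipped tables, config):
# identical input gives bit-identical output. Nonstandard residues are held
# as X and excluded from composition denominators.

aa_counts <- function(chars) {
  tab <- table(factor(chars, levels = .aa_alphabet_split))
  as.numeric(tab)
}

n_standard <- function(chars) sum(chars %in% .aa_alphabet_split)

seq_chars <- function(sequence) strsplit(normalize_sequence(sequence), "")[[1]]

# KD hydropathy per position; X scored 0 (no evidence either way)
kd_values <- function(chars) {
  v <- unname(.kd_scale[chars])
  v[is.na(v)] <- 0
  v
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 standard residues, in alphabet order
#' `ACDEFGHIKLMNPQRSTVWY`. `X` positions are excluded from the denominator,
#' so the fractions always sum to 1 for any sequence containing at least one
#' standard residue.
#'
#' @param sequence amino-acid sequence string.
#' @return named numeric vector of 20 fractions summing to 1.
#' @examples
#' aa_composition("ACDC")
#' @export
aa_composition <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- n_standard(chars)
  if (n == 0L) stop("sequence contains no standard residues")
  out <- aa_counts(chars) / n
  names(out) <- paste0("comp_", .aa_alphabet_split)
  out
}

# composition of a subsequence window; falls back to the whole-sequence
# composition if the window holds no standard residue (keeps block sum = 1)
window_composition <- function(chars, idx, prefix) {
  sub <- chars[idx]
  if (n_standard(sub) == 0L) sub <- chars
  out <- aa_counts(sub) / n_standard(sub)
  names(out) <- paste0(prefix, .aa_alphabet_split)
  out
}

# net charge by Henderson-Hasselbalch summation over side chains and termini
hh_net_charge <- function(chars, pH) {
  pos_counts <- vapply(names(.pka$positive), function(a) sum(chars == a), 0)
  neg_counts <- vapply(names(.pka$negative), function(a) sum(chars == a), 0)
  pos <- sum(pos_counts / (1 + 10^(pH - .pka$positive))) +
    1 / (1 + 10^(pH - .pka$nterm))
  neg <- sum(neg_counts / (1 + 10^(.pka$negative - pH))) +
    1 / (1 + 10^(.pka$cterm - pH))
  pos - neg
}

#' Charge features
#'
#' Net charge at the given pH (Henderson-Hasselbalch summation over ionizable
#' side chains and both termini, EMBOSS pKa set), the fractions of K, R and H
#' separately and pooled, the pooled D+E fraction, and net charge per residue.
#' The glomerular membrane is negatively charged, so these features carry real
#' signal for urinary excretion.
#'
#' @param sequence amino-acid sequence string.
#' @param pH solvent pH in `[0, 14]`.
#' @return named numeric vector: `chg_net`, `chg_frac_K`, `chg_frac_R`,
#'   `chg_frac_H`, `chg_frac_positive`, `chg_frac_negative`,
#'   `chg_net_per_residue`.
#' @export
charge_features <- function(sequence, pH = 7.0) {
  if (!is.numeric(pH) || length(pH) != 1L || pH < 0 || pH > 14) {
    stop("pH must be a single number in [0, 14]")
  }
  chars <- seq_chars(sequence)
  n <- n_standard(chars)
  if (n == 0L) stop("sequence contains no standard residues")
  net <- hh_net_charge(chars, pH)
  fr <- function(set) sum(chars %in% set) / n
  c(chg_net = net,
    chg_frac_K = fr("K"), chg_frac_R = fr("R"), chg_frac_H = fr("H"),
    chg_frac_positive = fr(c("K", "R", "H")),
    chg_frac_negative = fr(c("D", "E")),
    chg_net_per_residue = net / length(chars))
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge crosses zero, found by
#' bisection on `[0, 14]` to `|charge| < 1e-4`.
#'
#' @param sequence amino-acid sequence string.
#' @return estimated pI.
#' @export
isoelectric_point <- function(sequence) {
  chars <- seq_chars(sequence)
  lo <- 0; hi <- 14
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- hh_net_charge(chars, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' ProtParam-style global indices
#'
#' Molecular weight (average residue masses plus one water), isoelectric
#' point, GRAVY (mean Kyte-Doolittle hydropathy), the Guruprasad instability
#' index and the aliphatic index. `X` contributes the mean residue mass to the
#' weight and is excluded from GRAVY and instability dipeptides.
#'
#' @param sequence amino-acid sequence string.
#' @return named numeric vector: `pp_mw`, `pp_pi`, `pp_gravy`,
#'   `pp_instability`, `pp_aliphatic`.
#' @export
protparam_features <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- n_standard(chars)
  if (n == 0L) stop("sequence contains no standard residues")
  mass <- .residue_mass[chars]
  mass[is.na(mass)] <- mean(.residue_mass)
  mw <- sum(mass) + .water_mass

  kd <- unname(.kd_scale[chars])
  gravy <- mean(kd, na.rm = TRUE)

  if (length(chars) < 2L) {
    warning("instability index undefined for length-1 sequence; reporting 0")
    instab <- 0
  } else {
    a <- chars[-length(chars)]
    b <- chars[-1]
    ok <- a %in% .aa_alphabet_split & b %in% .aa_alphabet_split
    instab <- if (any(ok)) {
      (10 / length(chars)) * sum(.diwv[cbind(a[ok], b[ok])])
    } else 0
  }

  fr <- function(set) sum(chars %in% set) / n
  aliphatic <- 100 * (fr("A") + 2.9 * fr("V") + 3.9 * (fr("I") + fr("L")))

  c(pp_mw = mw, pp_pi = isoelectric_point(sequence), pp_gravy = gravy,
    pp_instability = instab, pp_aliphatic = aliphatic)
}

# mean over symmetric windows truncated at the ends, O(L) via cumsum
window_means <- function(x, window) {
  L <- length(x)
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Intrinsic-disorder features (fold-index style)
#'
#' Per-residue score `2.785 * <H> - |<R>| - 1.151` over a sliding window,
#' where `<H>` is the mean Kyte-Doolittle hydropathy rescaled to `[0, 1]` and
#' `<R>` the mean formal charge (K/R = +1, D/E = -1) of the window. Negative
#' scores mark disorder. Windows are truncated symmetrically at the ends.
#'
#' @param sequence amino-acid sequence string.
#' @param window odd window width in residues.
#' @return named numeric vector: `dis_mean_foldindex`, `dis_frac_disordered`,
#'   `dis_longest_run` (longest disordered run / length).
#' @export
disorder_features <- function(sequence, window = 51L) {
  chars <- seq_chars(sequence)
  h_scaled <- (kd_values(chars) + 4.5) / 9
  charge <- unname(.formal_charge[chars])
  charge[is.na(charge)] <- 0
  score <- 2.785 * window_means(h_scaled, window) -
    abs(window_means(charge, window)) - 1.151
  dis <- score < 0
  runs <- rle(dis)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  c(dis_mean_foldindex = mean(score),
    dis_frac_disordered = mean(dis),
    dis_longest_run = longest / length(chars))
}

#' Secondary-structure content estimate
#'
#' Composition-based estimate: the mean Chou-Fasman helix, strand and coil
#' propensities over the sequence, clipped to be non-negative and normalized
#' to sum to 1. A coarse stand-in for per-residue structure prediction, but
#' faithful to composition-driven differences (helix content ranked among the
#' strongest discriminators of urine excretory proteins).
#'
#' @param sequence amino-acid sequence string.
#' @return named numeric vector `ss_helix`, `ss_strand`, `ss_coil`, summing
#'   to 1.
#' @export
secondary_structure_content <- function(sequence) {
  chars <- seq_chars(sequence)
  std <- chars[chars %in% .aa_alphabet_split]
  if (length(std) == 0L) stop("sequence contains no standard residues")
  raw <- c(ss_helix = mean(.helix_propensity[std]),
           ss_strand = mean(.strand_propensity[std]),
           ss_coil = mean(.coil_propensity[std]))
  raw <- pmax(raw, 0)
  raw / sum(raw)
}

#' Signal-peptide heuristic
#'
#' Deterministic stand-in for a signal-peptide predictor: within the first 45
#' residues, the best sliding h-region window (length 8-12) by mean
#' Kyte-Doolittle hydropathy, plus half the count of K/R in the preceding
#' n-region. Sequences shorter than 15 residues score 0 and are called
#' negative. The call is `score >= cutoff` (default 2.0, a typical h-region
#' mean hydropathy).
#'
#' @param sequence amino-acid sequence string.
#' @param config list of tuning constants (see `.feature_config`).
#' @return named numeric vector `sp_score`, `sp_call` (0/1).
#' @export
signal_peptide_features <- function(sequence, config = .feature_config$signal_peptide) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < config$min_len) {
    return(c(sp_score = 0, sp_call = 0))
  }
  scan <- chars[seq_len(min(config$scan_len, L))]
  kd <- kd_values(scan)
  is_basic <- scan %in% c("K", "R")
  n_basic_before <- c(0, cumsum(is_basic))  # count in positions 1..s-1
  best <- -Inf
  for (w in config$h_window) {
    if (w > length(scan)) next
    wm <- window_sums(kd, w) / w
    starts <- seq_along(wm)
    cand <- wm + config$n_charge_weight * n_basic_before[starts]
    best <- max(best, max(cand))
  }
  if (!is.finite(best)) best <- 0
  c(sp_score = best, sp_call = as.numeric(best >= config$cutoff))
}

# contiguous window sums of exact width w (valid windows only)
window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  n <- length(x) - w + 1L
  cs[seq_len(n) + w] - cs[seq_len(n)]
}

#' Membrane and motif features
#'
#' Transmembrane-segment count (disjoint 19-residue windows with mean
#' hydropathy above the cutoff, scanned greedily left to right), a
#' beta-barrel propensity (maximum alternating-position hydropathy contrast
#' over 10-residue windows) and a twin-arginine (Tat) motif flag
#' (`[ST]-R-R-x-[FL]-[LK]` within the first 35 residues).
#'
#' @param sequence amino-acid sequence string.
#' @return named numeric vector `mem_tm_count`, `mem_barrel_score`,
#'   `mem_tat_flag` (0/1).
#' @export
membrane_motif_features <- function(sequence) {
  chars <- seq_chars(sequence)
  kd <- kd_values(chars)
  L <- length(chars)
  cfg <- .feature_config$membrane

  tm <- 0L
  i <- 1L
  cs <- c(0, cumsum(kd))
  while (i + cfg$tm_window - 1L <= L) {
    m <- (cs[i + cfg$tm_window] - cs[i]) / cfg$tm_window
    if (m > cfg$tm_cutoff) {
      tm <- tm + 1L
      i <- i + cfg$tm_window
    } else {
      i <- i + 1L
    }
  }

  bw <- cfg$barrel_window
  barrel <- 0
  if (L >= 2L) {
    w <- min(bw, L)
    starts <- seq_len(L - w + 1L)
    contrasts <- vapply(starts, function(s) {
      win <- kd[s:(s + w - 1L)]
      odd <- win[seq(1L, w, by = 2L)]
      even <- win[seq(2L, w, by = 2L)]
      abs(mean(odd) - mean(even))
    }, 0)
    barrel <- max(contrasts)
  }

  tcfg <- .feature_config$tat_motif
  head <- paste(chars[seq_len(min(tcfg$scan_len, L))], collapse = "")
  tat <- as.numeric(grepl(tcfg$pattern, head))

  c(mem_tm_count = as.numeric(tm), mem_barrel_score = barrel, mem_tat_flag = tat)
}

#' Glycosylation motif features
#'
#' Overlapping N-glycosylation sequons (`N-X-[S/T]`, X != P) counted left to
#' right, plus the S/T density as a mucin-type O-glycosylation proxy.
#'
#' @param sequence amino-acid sequence string.
#' @return named numeric vector `n_sequons` (raw count),
#'   `gly_sequon_density` (count / length), `gly_st_density`.
#' @export
glycosylation_features <- function(sequence) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  n_seq <- 0L
  if (L >= 3L) {
    n_seq <- sum(chars[seq_len(L - 2L)] == "N" &
                   chars[seq_len(L - 2L) + 1L] != "P" &
                   chars[seq_len(L - 2L) + 2L] %in% c("S", "T"))
  }
  c(n_sequons = as.numeric(n_seq),
    gly_sequon_density = n_seq / L,
    gly_st_density = sum(chars %in% c("S", "T")) / L)
}

ctd_group_index <- function(chars, partition) {
  g <- rep(NA_integer_, length(chars))
  for (k in seq_along(partition)) {
    members <- strsplit(partition[[k]], "")[[1]]
    g[chars %in% members] <- k
  }
  g
}

#' Composition/Transition/Distribution descriptors
#'
#' For each shipped 3-group physicochemical partition of the alphabet
#' (hydrophobicity, van der Waals volume, polarity, polarizability, charge,
#' secondary-structure preference, solvent accessibility): 3 composition
#' fractions, 3 adjacent-pair transition frequencies and 15 distribution
#' values (normalized positions of the first, 25%, 50%, 75% and last
#' occurrence of each group). 7 x 21 = 147 values. Sequences shorter than 5
#' residues get zero distribution values with a warning.
#'
#' @param sequence amino-acid sequence string.
#' @param properties named list of 3-group partitions.
#' @return named numeric vector of length `21 * length(properties)`.
#' @export
ctd_features <- function(sequence, properties = .ctd_properties) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  dist_ok <- L >= 5L
  if (!dist_ok) {
    warning("sequence shorter than 5 residues: CTD distribution values set to 0")
  }
  out <- numeric(0)
  for (p in names(properties)) {
    g <- ctd_group_index(chars, properties[[p]])
    valid <- !is.na(g)
    nv <- sum(valid)
    comp <- if (nv > 0) tabulate(g[valid], 3L) / nv else rep(0, 3)
    names(comp) <- paste0("ctd_", p, "_comp_g", 1:3)

    a <- g[-L]; b <- g[-1]
    ok <- !is.na(a) & !is.na(b)
    npair <- sum(ok)
    trans <- c(0, 0, 0)
    if (npair > 0) {
      pair_min <- pmin(a[ok], b[ok]); pair_max <- pmax(a[ok], b[ok])
      trans <- c(sum(pair_min == 1 & pair_max == 2),
                 sum(pair_min == 1 & pair_max == 3),
                 sum(pair_min == 2 & pair_max == 3)) / npair
    }
    names(trans) <- paste0("ctd_", p, "_trans_", c("12", "13", "23"))

    dist <- numeric(15)
    qs <- c("first", "q25", "q50", "q75", "q100")
    names(dist) <- paste0("ctd_", p, "_dist_g", rep(1:3, each = 5), "_", rep(qs, 3))
    if (dist_ok) {
      for (k in 1:3) {
        pos <- which(g == k)
        if (length(pos) > 0) {
          idx <- pmax(1L, ceiling(c(0.0001, 0.25, 0.5, 0.75, 1) * length(pos)))
          dist[(k - 1) * 5 + 1:5] <- pos[idx] / L
        }
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

# length-normalized global statistics (padding block of the registry)
seqstat_features <- function(sequence) {
  chars <- seq_chars(sequence)
  n <- n_standard(chars)
  if (n == 0L) stop("sequence contains no standard residues")
  cfg <- .feature_config
  nterm <- window_composition(chars, seq_len(min(cfg$nterm_len, length(chars))), "nterm_comp_")
  cterm <- window_composition(
    chars, seq(max(1L, length(chars) - cfg$cterm_len + 1L), length(chars)), "cterm_comp_")
  fr <- function(set) sum(chars %in% strsplit(set, "")[[1]]) / n
  misc <- c(
    st_log_length = log10(length(chars)),
    st_aromaticity = fr("FWY"),
    st_frac_tiny = fr("ACGST"),
    st_frac_small = fr("ACDGNPSTV"),
    st_frac_aliphatic = fr("AILV"),
    st_frac_aromatic = fr("FHWY"),
    st_frac_polar = fr("DEHKNQRST"),
    st_frac_nonpolar = fr("ACFGILMPVWY"),
    st_frac_charged = fr("DEHKR"),
    st_frac_sulfur = fr("CM"),
    st_frac_hydroxyl = fr("STY")
  )
  c(nterm, cterm, misc)
}
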