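# Shipped coefficient tables. All scores in this package are desk-scale
# approximations computed from these versioned tables, not the outputs of the
# original prediction servers; see the methods vignette for provenance.

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWY"
.aa_alphabet_split <- strsplit(.aa_alphabet, "")[[1]]

# residues accepted on input but excluded from composition denominators
.aa_nonstandard <- c("B", "J", "Z", "X", "U", "O")

# Kyte & Doolittle (1982) hydropathy
.kd_scale <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# EMBOSS pKa set; termini included in the Henderson-Hasselbalch sum
.pka <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# average residue masses (Da); water added once per chain
.residue_mass <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)
.water_mass <- 18.01524

# Chou & Fasman (1978) conformational propensities
.helix_propensity <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)
.strand_propensity <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
  I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
  R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47
)
.coil_propensity <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60, G = 1.56, H = 0.95,
  I = 0.47, K = 1.01, L = 0.59, M = 0.60, N = 1.56, P = 1.52, Q = 0.98,
  R = 0.95, S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14
)

# simple per-residue formal charge used by the fold-index score
.formal_charge <- c(K = 1, R = 1, D = -1, E = -1)

# Dubchak-style 3-group alphabet partitions for the CTD descriptors
.ctd_properties <- list(
  hydrophobicity = list(polar = "RKEDQN", neutral = "GASTPHY", hydrophobic = "CLVIMFW"),
  vdw_volume = list(small = "GASTPD", medium = "NVEQIL", large = "MHKFRYW"),
  polarity = list(low = "LIFWCMVY", medium = "PATGS", high = "HQRKNED"),
  polarizability = list(low = "GASDT", medium = "CPNVEQIL", high = "KMHFRYW"),
  charge = list(positive = "KR", neutral = "ANCQGHILMFPSTWYV", negative = "DE"),
  secondary_structure = list(helix = "EALMQKRH", strand = "VIYCWFT", coil = "GNPSD"),
  solvent_accessibility = list(buried = "ALFCGIVW", exposed = "RKQEND", intermediate = "MSPTHY")
)

# approximate human-proteome background amino-acid frequencies (UniProt human
# reference proteome, rounded); used by the synthetic sequence generator
.human_aa_freq <- c(
  A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365, G = 0.0657,
  H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996, M = 0.0213, N = 0.0359,
  P = 0.0631, Q = 0.0477, R = 0.0564, S = 0.0832, T = 0.0536, V = 0.0597,
  W = 0.0122, Y = 0.0267
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weights,
# rows = first residue, columns = second residue
.diwv <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.aa_alphabet_split, .aa_alphabet_split))

# tunable cutoffs for the heuristic feature groups
.feature_config <- list(
  signal_peptide = list(
    scan_len = 45, h_window = 8:12, min_len = 15,
    n_charge_weight = 0.5, cutoff = 2.0
  ),
  membrane = list(tm_window = 19, tm_cutoff = 1.6, barrel_window = 10),
  tat_motif = list(pattern = "[ST]RR.[FL][LK]", scan_len = 35),
  disorder = list(window = 51L),
  nterm_len = 50L, cterm_len = 50L
)
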