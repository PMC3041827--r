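# Feature extraction: FASTA plumbing, each feature group against hand or
# closed-form oracles, and the whole-vector invariants.

test_that("read_fasta parses, normalizes and rejects degenerate input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1 some description", "mkv", ">P2", "ACDE", "FGHI"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "P1")
  expect_equal(recs[[1]]$sequence, "MKV")     # uppercased
  expect_equal(recs[[2]]$sequence, "ACDEFGHI")  # wrapped lines joined

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1", "MKV", ">P1", "ACD"), dup)
  expect_error(read_fasta(dup), "P1")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")

  expect_error(protein_record("P1", "MK1V"), "invalid residue")
  expect_equal(protein_record("P1", "MBZV")$sequence, "MXXV")
})

test_that("amino-acid composition matches hand counts and sums to 1", {
  expect_equal(unname(aa_composition("AAAA")["comp_A"]), 1)
  comp <- aa_composition("ACDC")
  expect_equal(unname(comp[c("comp_A", "comp_C", "comp_D")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(comp), 1)

  comp18 <- aa_composition("MKWVTFISLLLLFSSAYS")
  expect_equal(sum(comp18), 1, tolerance = 1e-12)
  expect_equal(unname(comp18["comp_W"]), 1 / 18)

  # X excluded from the denominator
  expect_equal(unname(aa_composition("AXXA")["comp_A"]), 1)
})

test_that("charge features follow the Henderson-Hasselbalch sum", {
  # closed-form oracle with the shipped pKa table, written out independently
  hh <- function(counts, pH) {
    pka_pos <- c(K = 10.8, R = 12.5, H = 6.5)
    pka_neg <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
    pos <- 1 / (1 + 10^(pH - 8.6))      # N-terminus
    neg <- 1 / (1 + 10^(3.6 - pH))      # C-terminus
    for (a in names(pka_pos)) pos <- pos + counts[a] / (1 + 10^(pH - pka_pos[a]))
    for (a in names(pka_neg)) neg <- neg + counts[a] / (1 + 10^(pka_neg[a] - pH))
    pos - neg
  }
  counts0 <- setNames(rep(0, 7), c("K", "R", "H", "D", "E", "C", "Y"))
  ck <- counts0; ck["K"] <- 1
  expect_equal(unname(charge_features("K")["chg_net"]), unname(hh(ck, 7)),
               tolerance = 1e-12)
  expect_lt(abs(charge_features("K")["chg_net"] - 1), 0.1)
  expect_lt(abs(charge_features("D")["chg_net"] + 1), 0.1)

  # equal K and D: side-chain contributions cancel at pH 7
  side_chain <- charge_features("GKDGKDG")["chg_net"] -
    charge_features("GGGGGGG")["chg_net"]
  expect_lt(abs(side_chain), 0.05)

  cf <- charge_features("KKRRHDE")
  expect_equal(unname(cf["chg_frac_positive"]), 5 / 7)
  expect_equal(unname(cf["chg_frac_negative"]), 2 / 7)
  expect_error(charge_features("KK", pH = 15), "pH")
})

test_that("protparam indices match closed-form values", {
  expect_warning(pp <- protparam_features("G"), "instability")
  expect_equal(unname(pp["pp_mw"]), 75.07, tolerance = 0.05)

  expect_equal(unname(protparam_features("IIII")["pp_gravy"]), 4.5)

  # no ionizable side chains: pI bracketed by the terminal pKa values
  pi_g <- protparam_features("GGGG")["pp_pi"]
  expect_gt(pi_g, 3.6)
  expect_lt(pi_g, 8.6)

  # aliphatic index of poly-L: 100 * 3.9
  expect_equal(unname(protparam_features("LLLL")["pp_aliphatic"]), 390)

  # instability via the shipped dipeptide table on a 2-mer:
  # 10/2 * DIWV[A][G] = 5 * 1
  expect_equal(unname(protparam_features("AG")["pp_instability"]), 5)
})

test_that("disorder features evaluate the fold-index formula", {
  di <- disorder_features(strrep("I", 80))
  expect_gt(di["dis_mean_foldindex"], 0)
  expect_equal(unname(di["dis_longest_run"]), 0)

  de <- disorder_features(strrep("E", 80))
  expect_lt(de["dis_mean_foldindex"], 0)
  expect_equal(unname(de["dis_frac_disordered"]), 1)
  # closed form for a homopolymer: every window is pure E
  expect_equal(unname(de["dis_mean_foldindex"]),
               2.785 * (-3.5 + 4.5) / 9 - 1 - 1.151, tolerance = 1e-12)

  withr::with_seed(42, {
    for (i in 1:5) {
      f <- disorder_features(random_aa_seq(sample(5:200, 1)))["dis_frac_disordered"]
      expect_gte(f, 0)
      expect_lte(f, 1)
    }
  })
})

test_that("secondary-structure content is a propensity-weighted simplex", {
  for (s in c("AAAA", "PPPP", "MKWVTFISLLLLFSSAYS")) {
    expect_equal(sum(secondary_structure_content(s)), 1, tolerance = 1e-9)
  }
  expect_gt(secondary_structure_content(strrep("A", 30))["ss_helix"],
            secondary_structure_content(strrep("P", 30))["ss_helix"])
  expect_gt(secondary_structure_content(strrep("V", 30))["ss_strand"],
            secondary_structure_content(strrep("A", 30))["ss_strand"])
})

test_that("signal-peptide heuristic fires on a canonical prefix only", {
  acidic <- strrep("DE", 20)
  expect_equal(unname(signal_peptide_features(acidic)["sp_call"]), 0)

  canonical <- paste0("MKKTLLALSLLAALSAPAFA", strrep("G", 30))
  sp <- signal_peptide_features(canonical)
  expect_equal(unname(sp["sp_call"]), 1)
  # hand evaluation of the window rule: the all-leucine-rich 8-mer LLALSLLA
  # (after n-region MKKT with 2 basic residues) gives the best score
  expect_gte(sp["sp_score"], (3.8 * 5 + 1.8 * 2 - 0.8) / 8 + 0.5 * 2 - 1e-9)

  short <- signal_peptide_features("MKVLLATTSV")
  expect_equal(unname(short), c(0, 0))
})

test_that("membrane and motif heuristics match hand evaluation", {
  tm_seq <- paste0(strrep("S", 10), strrep("L", 19), strrep("S", 10))
  expect_gte(membrane_motif_features(tm_seq)["mem_tm_count"], 1)

  tat <- membrane_motif_features(paste0("MTRRNFLK", strrep("A", 20)))
  expect_equal(unname(tat["mem_tat_flag"]), 1)

  allg <- membrane_motif_features(strrep("G", 60))
  expect_equal(unname(allg["mem_tm_count"]), 0)
  expect_equal(unname(allg["mem_tat_flag"]), 0)
  expect_equal(unname(allg["mem_barrel_score"]), 0)
})

test_that("glycosylation sequons are counted with the proline exclusion", {
  expect_equal(unname(glycosylation_features("NAS")["n_sequons"]), 1)
  expect_equal(unname(glycosylation_features("NPS")["n_sequons"]), 0)
  expect_equal(unname(glycosylation_features("NASNAT")["n_sequons"]), 2)
  expect_equal(unname(glycosylation_features("TSTS")["gly_st_density"]), 1)
})

test_that("CTD descriptors behave on degenerate and alternating input", {
  hom <- suppressWarnings(ctd_features(strrep("A", 10)))
  # A is neutral (group 2) under the hydrophobicity partition
  expect_equal(unname(hom["ctd_hydrophobicity_comp_g2"]), 1)
  expect_equal(unname(hom["ctd_hydrophobicity_trans_12"]), 0)

  # alternating K (positive, g1) and D (negative, g3) under the charge
  # partition: every adjacent pair is a 1-3 transition
  alt <- ctd_features(strrep("KD", 5))
  expect_equal(unname(alt["ctd_charge_trans_13"]), 1)

  v <- ctd_features("MKWVTFISLLLLFSSAYS")
  for (p in c("hydrophobicity", "vdw_volume", "polarity", "polarizability",
              "charge", "secondary_structure", "solvent_accessibility")) {
    expect_equal(sum(v[paste0("ctd_", p, "_comp_g", 1:3)]), 1, tolerance = 1e-9)
  }

  expect_warning(ctd_features("MKV"), "distribution")
})

test_that("the full feature vector is deterministic, finite and sensitive", {
  reg <- default_registry()
  expect_equal(nrow(reg), 243)
  expect_equal(reg$index, 0:242)
  expect_false(anyDuplicated(reg$name) > 0)

  rec <- protein_record("P1", "MKWVTFISLLLLFSSAYSRGVFRRDTHKSEIAHRFKDLGE")
  v1 <- compute_feature_vector(rec)
  v2 <- compute_feature_vector(rec)
  expect_identical(v1, v2)
  expect_length(v1, 243)
  expect_true(all(is.finite(v1)))
  expect_identical(names(v1), reg$name)

  # single-residue perturbation of a fixed 30-mer must change the vector
  base <- strrep("ALKVE", 6)
  mutant <- paste0("G", substr(base, 2, 30))
  expect_false(identical(compute_feature_vector(protein_record("a", base)),
                         compute_feature_vector(protein_record("b", mutant))))

  # finiteness across lengths, including extremes
  withr::with_seed(99, {
    for (n in c(1, 2, 5, 51, 400)) {
      v <- suppressWarnings(compute_feature_vector(
        protein_record("x", random_aa_seq(n))))
      expect_true(all(is.finite(v)))
    }
  })
})

test_that("feature matrix TSV round-trips losslessly", {
  withr::with_seed(7, {
    recs <- lapply(1:4, function(i) protein_record(paste0("P", i), random_aa_seq(60)))
  })
  mat <- compute_feature_matrix(recs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(mat, tsv)
  back <- read_feature_matrix(tsv)
  expect_equal(back, mat, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(rownames(back), rownames(mat))
})
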