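# Independent mass oracles. These rebuild every composition by a different
# route than the package: free GlcNAc monomers (C8H15NO6) condensed with
# loss of one water per glycosidic bond, the acyl chain attached as a free
# fatty acid (CcH(2c-2d)O2, minus 2H per double bond, plus O per hydroxyl)
# condensing onto the deacetylated amine with loss of water. Masses are
# summed from a separate copy of the isotope table.

oracle_nominal_table <- c(C = 12, H = 1, N = 14, O = 16, Na = 23)
oracle_mono_table <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                       O = 15.9949146221, Na = 22.98976928)

oracle_atoms <- function(C = 0, H = 0, N = 0, O = 0, Na = 0) {
  c(C = C, H = H, N = N, O = O, Na = Na)
}

# atom counts of the k non-reducing-end residues of a structure (the Bk
# fragment skeleton); k = n gives the full backbone, and + H2O the molecule
oracle_residue_atoms <- function(s, k) {
  monomer <- oracle_atoms(C = 8, H = 15, N = 1, O = 6)   # free GlcNAc
  water <- oracle_atoms(H = 2, O = 1)
  atoms <- k * monomer - k * water                       # k in-chain residues
  # acyl replacement on residue 1: remove N-acetyl (ketene equivalent),
  # condense free fatty acid onto the amine
  fatty_acid <- oracle_atoms(C = s$acyl$carbons,
                             H = 2 * s$acyl$carbons - 2 * s$acyl$double_bonds,
                             O = 2 + s$acyl$hydroxyls)
  atoms <- atoms - oracle_atoms(C = 2, H = 2, O = 1) + fatty_acid - water
  if (s$substituents$carbamoyl) {
    atoms <- atoms + oracle_atoms(C = 1, H = 1, N = 1, O = 1)
  }
  if (k >= 2 && s$substituents$o_acetyl) {
    atoms <- atoms + oracle_atoms(C = 2, H = 2, O = 1)
  }
  if (k >= s$backbone_length && s$substituents$methyl) {
    atoms <- atoms + oracle_atoms(C = 1, H = 2)
  }
  atoms
}

oracle_molecule_atoms <- function(s) {
  oracle_residue_atoms(s, s$backbone_length) + oracle_atoms(H = 2, O = 1)
}

oracle_adduct <- list(H = oracle_atoms(H = 1), Na = oracle_atoms(Na = 1))

oracle_nominal <- function(atoms) sum(atoms * oracle_nominal_table[names(atoms)])
oracle_mono <- function(atoms) sum(atoms * oracle_mono_table[names(atoms)])

oracle_precursor_nominal <- function(s, adduct) {
  oracle_nominal(oracle_molecule_atoms(s) + oracle_adduct[[adduct]])
}

oracle_bk_nominal <- function(s, k, adduct) {
  oracle_nominal(oracle_residue_atoms(s, k) + oracle_adduct[[adduct]])
}

oracle_bk_mono <- function(s, k, adduct) {
  oracle_mono(oracle_residue_atoms(s, k) + oracle_adduct[[adduct]])
}

# brute-force count of a search space by an independent nested loop over
# explicitly materialised axis vectors
oracle_space_size <- function(backbones, carbons, max_db, max_oh,
                              cb, oac, me) {
  n <- 0L
  for (b in backbones) {
    for (c_ in carbons) {
      for (d in 0:max_db) {
        if (d > (c_ - 2) %/% 2) next
        for (h in 0:max_oh) {
          n <- n + length(if (cb) c(0, 1) else 0) *
            length(if (oac) c(0, 1) else 0) *
            length(if (me) c(0, 1) else 0)
        }
      }
    }
  }
  n
}

# random structure under a fixed RNG state (caller sets the seed)
random_structure <- function() {
  c_ <- sample(c(14L, 16L, 18L, 20L, 22L), 1)
  d <- sample(0:min(4L, (c_ - 2L) %/% 2L), 1)
  lco_structure(sample(3:5, 1), acyl_chain(c_, d, sample(0:1, 1)),
                substituent_set(sample(c(TRUE, FALSE), 1),
                                sample(c(TRUE, FALSE), 1),
                                sample(c(TRUE, FALSE), 1)))
}
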