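# Shared package constants (loaded before all other sources).

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.AA1 <- setNames(names(.AA3), unname(.AA3))

# idealized backbone geometry (Engh-Huber-like values)
.BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.01,
  b_CACB = 1.521, b_CC = 1.53, b_CH = 1.09,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  a_CNH = 119.15, a_CCACB = 110.5, a_tet = 109.5, a_CCC = 113.0,
  impCB = 122.6  # N-C-CA-CB improper for L-amino acids
)

# canonical phi/psi (degrees): helix, antiparallel strand, parallel strand,
# extended coil
.PHIPSI <- list(H = c(-57, -47), E = c(-139, 135), Ep = c(-119, 113),
                C = c(-120, 120))

.METHYL_CARBONS <- list(ALA = "CB", VAL = c("CG1", "CG2"),
                        LEU = c("CD1", "CD2"), ILE = c("CG2", "CD1"),
                        THR = "CG2")
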