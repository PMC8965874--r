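# Writes a minimal single-TIP3P-water Amber prmtop fixture
# (inst/extdata/toy/tip3p_water.prmtop).  Charges are in the prmtop
# internal unit (e * 18.2223); LJ as A/B coefficients.
dir.create("inst/extdata/toy", recursive = TRUE, showWarnings = FALSE)

f <- file("inst/extdata/toy/tip3p_water.prmtop", "w")
w <- function(...) writeLines(c(...), f)
fmtE <- function(x) {
  s <- sprintf("%16.8E", x)
  paste(s, collapse = "")
}
w("%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/01  00:00:00")
w("%FLAG TITLE", "%FORMAT(20a4)", "TIP3P water (fixture)")
ptr <- integer(31)
ptr[1] <- 3   # NATOM
ptr[2] <- 2   # NTYPES
ptr[3] <- 2   # NBONH
ptr[5] <- 1   # NTHETH
w("%FLAG POINTERS", "%FORMAT(10I8)")
for (i in seq(1, 31, by = 10))
  w(paste(sprintf("%8d", ptr[i:min(i + 9, 31)]), collapse = ""))
q <- c(-0.834, 0.417, 0.417) * 18.2223
w("%FLAG CHARGE", "%FORMAT(5E16.8)", fmtE(q))
w("%FLAG MASS", "%FORMAT(5E16.8)", fmtE(c(16.0, 1.008, 1.008)))
w("%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)",
  paste(sprintf("%8d", c(1, 2, 2)), collapse = ""))
w("%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)",
  paste(sprintf("%8d", c(1, 2, 2, 3)), collapse = ""))
w("%FLAG ATOM_NAME", "%FORMAT(20a4)", "O   H1  H2  ")
# TIP3P oxygen: eps 0.1520 kcal/mol, rmin/2 1.7683 A
eps <- 0.1520; rmin <- 2 * 1.7683
A_OO <- eps * rmin^12; B_OO <- 2 * eps * rmin^6
w("%FLAG LENNARD_JONES_ACOEF", "%FORMAT(5E16.8)", fmtE(c(A_OO, 0, 0)))
w("%FLAG LENNARD_JONES_BCOEF", "%FORMAT(5E16.8)", fmtE(c(B_OO, 0, 0)))
w("%FLAG BOND_FORCE_CONSTANT", "%FORMAT(5E16.8)", fmtE(553.0))
w("%FLAG BOND_EQUIL_VALUE", "%FORMAT(5E16.8)", fmtE(0.9572))
w("%FLAG ANGLE_FORCE_CONSTANT", "%FORMAT(5E16.8)", fmtE(100.0))
w("%FLAG ANGLE_EQUIL_VALUE", "%FORMAT(5E16.8)", fmtE(104.52 * pi / 180))
w("%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)",
  paste(sprintf("%8d", c(0, 3, 1, 0, 6, 1)), collapse = ""))
w("%FLAG ANGLES_INC_HYDROGEN", "%FORMAT(10I8)",
  paste(sprintf("%8d", c(3, 0, 6, 1)), collapse = ""))
w("%FLAG RADII", "%FORMAT(5E16.8)", fmtE(c(1.5, 0.8, 0.8)))
close(f)
cat("wrote inst/extdata/toy/tip3p_water.prmtop\n")
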