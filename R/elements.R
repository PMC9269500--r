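# Elemental reference data used throughout the package.
#
# I-values are the ICRU-37 recommendations for elemental constituents of
# condensed compounds (H 19.2, C 81.0, N 82.0, O 106.0 eV, ...), which is the
# convention under which Bragg additivity reproduces the accepted I of water
# (~75 eV). Subshell binding energies (eV) and occupancies feed the exact
# Sternheimer density-effect evaluation in the stopping-power module.

.ELEMENTS <- list(
  H  = list(Z = 1,  A = 1.008,   I = 19.2,  shells_B = 13.6,
            shells_n = 1),
  C  = list(Z = 6,  A = 12.011,  I = 81.0,  shells_B = c(288, 16.59, 11.26),
            shells_n = c(2, 2, 2)),
  N  = list(Z = 7,  A = 14.007,  I = 82.0,  shells_B = c(402, 20.33, 14.53),
            shells_n = c(2, 2, 3)),
  O  = list(Z = 8,  A = 15.999,  I = 106.0, shells_B = c(538, 28.48, 13.62),
            shells_n = c(2, 2, 4)),
  Na = list(Z = 11, A = 22.990,  I = 168.4, shells_B = c(1075, 66, 34, 5.14),
            shells_n = c(2, 2, 6, 1)),
  S  = list(Z = 16, A = 32.06,   I = 180.0, shells_B = c(2472, 230, 168, 21, 10.4),
            shells_n = c(2, 2, 6, 2, 4)),
  Cl = list(Z = 17, A = 35.45,   I = 180.0, shells_B = c(2833, 277, 203, 25, 13),
            shells_n = c(2, 2, 6, 2, 5)),
  Ca = list(Z = 20, A = 40.078,  I = 215.8, shells_B = c(4041, 441, 350, 48, 34, 6.1),
            shells_n = c(2, 2, 6, 2, 6, 2))
)

# physical constants (MeV units unless noted)
.MEC2 <- 0.51099895          # electron rest energy, MeV
.KBETHE <- 0.1535363         # 2*pi*re^2*me*c^2*NA, MeV cm^2 / mol
.NAVO <- 6.02214076e23       # Avogadro, 1/mol

.element <- function(symbol) {
  el <- .ELEMENTS[[symbol]]
  if (is.null(el)) stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  el
}
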