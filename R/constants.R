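# Physical constants used throughout (MeV, mm, g units)
.const <- list(
  mec2      = 0.51099895,     # electron rest energy, MeV
  mpc2      = 938.27209,      # proton rest energy, MeV
  re_mm     = 2.8179403e-12,  # classical electron radius, mm
  NA_mol    = 6.02214076e23,  # Avogadro constant, 1/mol
  K_bethe   = 0.307075,       # 4 pi NA re^2 me c^2 / A, MeV cm^2 / mol
  I_water   = 75e-6           # mean excitation energy of water, MeV
)

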