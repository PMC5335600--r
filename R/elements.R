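## Standard atomic weights (IUPAC 2021, conventional values) for the
## elements encountered in small-molecule work.  Used for molecular weight
## and formula computation.

ATOMIC_MASS <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078, Sc = 44.956,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723,
  Ge = 72.63, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Ag = 107.87, Cd = 112.41, Sn = 118.71,
  Sb = 121.76, Te = 127.60, I = 126.904, Xe = 131.29, Cs = 132.905,
  Ba = 137.33, Pt = 195.08, Au = 196.967, Hg = 200.59, Tl = 204.38,
  Pb = 207.2, Bi = 208.98
)

ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
  Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25,
  Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33,
  Se = 34, Br = 35, Kr = 36, Rb = 37, Sr = 38, Ag = 47, Cd = 48, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, Pt = 78, Au = 79,
  Hg = 80, Tl = 81, Pb = 82, Bi = 83
)

atomic_mass <- function(elem) {
  m <- ATOMIC_MASS[elem]
  if (anyNA(m)) {
    adm_error("adm_untypable_atom",
              paste0("no atomic mass for element(s): ",
                     paste(unique(elem[is.na(m)]), collapse = ", ")))
  }
  unname(m)
}

atomic_number <- function(elem) {
  z <- ATOMIC_NUMBER[elem]
  z[is.na(z)] <- 0
  unname(z)
}
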