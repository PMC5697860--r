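# Nuclide mass table (CODATA/AME monoisotopic masses, >= 9 decimals).
#
# Keys are either a bare element symbol, meaning the most abundant (light)
# nuclide, or a bracketed heavy nuclide such as "[2]H" or "[13]C" following
# the shorthand used for stable isotope-labeled lipids.

.ELECTRON_MASS <- 0.000548579909

.NUCLIDES <- local({
  tab <- rbind(
    #       monoisotopic    nominal
    H      = c(1.007825032,   1),
    C      = c(12.0,         12),
    N      = c(14.003074004, 14),
    O      = c(15.994914620, 16),
    P      = c(30.973761998, 31),
    S      = c(31.972071174, 32),
    Na     = c(22.989769282, 23),
    K      = c(38.963706487, 39),
    Li     = c(7.016003437,   7),
    Cl     = c(34.968852682, 35),
    F      = c(18.998403163, 19),
    "[2]H"  = c(2.014101778, 2),
    "[13]C" = c(13.003354835, 13),
    "[15]N" = c(15.000108899, 15),
    "[18]O" = c(17.999159613, 18),
    "[34]S" = c(33.967867012, 34)
  )
  colnames(tab) <- c("mono", "nominal")
  tab
})

# Hill ordering with the convention that metal adduct atoms sort last, so
# deltas print as "(+ONa)" and "(+HONa)" rather than strict-Hill "(+NaO)".
.METALS <- c("Na", "K", "Li")

# element symbol of a nuclide key ("[2]H" -> "H")
.nuclide_element <- function(key) sub("^\\[[0-9]+\\]", "", key)

.is_heavy <- function(key) grepl("^\\[", key)

#' Nuclide mass lookup
#'
#' Monoisotopic mass of a single nuclide key, e.g. `"C"` or `"[13]C"`.
#'
#' @param key nuclide key (element symbol, optionally prefixed with the mass
#'   number in square brackets).
#' @return mass in Da.
#' @keywords internal
nuclide_mass <- function(key) {
  if (!key %in% rownames(.NUCLIDES))
    stop("unknown nuclide: '", key, "'", call. = FALSE)
  .NUCLIDES[key, "mono"]
}
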