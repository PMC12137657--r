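#' Published per-locality diversity statistics for the bullfrog study
#' system
#'
#' The 28 river-valley localities with reported average expected (He)
#' and observed (Ho) heterozygosity and inbreeding coefficient (F_IS),
#' estimated from genome-wide SNPs after full-sib filtering. Three
#' additional localities (6, 11 and 22) had a single usable individual
#' and carry no statistics, so they are excluded here. `n` is the number
#' of individuals retained after full-sib filtering.
#'
#' @return data frame with columns `locality_id`, `n`, `He`, `Ho`,
#'   `F_IS` (28 rows).
#' @export
table1_fixture <- function() {
  df <- data.frame(
    locality_id = c(1L, 2L, 3L, 4L, 5L, 7L, 8L, 9L, 10L, 12L, 13L, 14L,
                    15L, 16L, 17L, 18L, 19L, 20L, 21L, 23L, 24L, 25L,
                    26L, 27L, 28L, 29L, 30L, 31L),
    n  = c(9L, 11L, 17L, 11L, 12L, 10L, 14L, 9L, 2L, 4L, 13L, 3L, 15L,
           11L, 13L, 7L, 14L, 10L, 14L, 8L, 14L, 10L, 8L, 12L, 9L, 3L,
           10L, 2L),
    He = c(0.2023, 0.2439, 0.2413, 0.2130, 0.2107, 0.1849, 0.2119,
           0.2215, 0.2370, 0.1992, 0.2255, 0.1910, 0.2397, 0.2395,
           0.2361, 0.2103, 0.2319, 0.2340, 0.2192, 0.1860, 0.2139,
           0.2355, 0.2191, 0.2182, 0.1815, 0.1803, 0.2008, 0.1991),
    Ho = c(0.2116, 0.2320, 0.2222, 0.2276, 0.2121, 0.1747, 0.2010,
           0.2011, 0.2233, 0.2466, 0.2124, 0.2405, 0.2285, 0.2407,
           0.2264, 0.2305, 0.2364, 0.2587, 0.2157, 0.1812, 0.2235,
           0.2015, 0.2200, 0.1983, 0.1743, 0.2347, 0.1903, 0.1836),
    F_IS = c(-0.050, 0.032, 0.071, -0.053, -0.011, 0.045, 0.043, 0.073,
             -0.065, -0.226, 0.045, -0.267, 0.037, -0.008, 0.031,
             -0.085, -0.015, -0.091, 0.016, 0.015, -0.032, 0.119,
             -0.017, 0.072, 0.029, -0.300, 0.038, -0.047))
  df
}
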