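# Published values from the underlying survey of seven Alu
# insertion/deletion loci in South Indian caste and tribal populations,
# bundled for re-analysis and as worked-example inputs. All values are
# transcribed at the published precision (4-5 decimals).

ALU_LOCI <- c("ACE", "TPA25", "FXIIIB", "CD4", "APO", "D1", "PV92")

#' Published tribal allele frequencies (Kani and Paliyar)
#'
#' Insertion-allele frequencies at the seven Alu loci for the two Western
#' Ghats tribal populations of the survey, with the typed sample sizes
#' published alongside the frequencies (which differ from the sampling-map
#' counts for Paliyar: 57 typed vs 58 sampled — hence per-locus `n`).
#'
#' @return A [frequency_matrix()] (2 populations x 7 loci) with `n`.
#' @export
alu_tribal_freqs <- function() {
  p <- rbind(
    Kani    = c(0.5000, 0.7959, 0.4795, 0.8979, 0.7857, 0.4387, 0.5306),
    Paliyar = c(0.4912, 0.5701, 0.6315, 0.8421, 0.5964, 0.5438, 0.6052))
  colnames(p) <- ALU_LOCI
  n <- matrix(rep(c(49L, 57L), each = length(ALU_LOCI)),
              nrow = 2L, byrow = TRUE, dimnames = dimnames(p))
  frequency_matrix(p, n = n)
}

#' Published observed heterozygosities per population
#'
#' Observed heterozygosity (fraction of heterozygous individuals) at each
#' of the seven Alu loci for all twelve survey populations, plus the
#' published unweighted "all loci" average. Sample sizes are the ones
#' published with this table.
#'
#' @return Data frame: `population`, `n`, one column per locus,
#'   `all_loci`.
#' @export
alu_population_het <- function() {
  df <- data.frame(
    population = c("Pallan", "Nair", "Namboothiri", "Kani", "Vanniyar",
                   "Paliyar", "Narikuravar", "Sourastra", "Iyer",
                   "V.Goundar", "Kallar", "Yadava"),
    n = c(50L, 56L, 35L, 49L, 51L, 58L, 41L, 39L, 44L, 44L, 53L, 54L),
    ACE    = c(0.4130, 0.6041, 0.2894, 0.5918, 0.5600, 0.5614, 0.6097,
               0.4102, 0.4883, 0.5227, 0.6425, 0.5000),
    TPA25  = c(0.4782, 0.5535, 0.4210, 0.3265, 0.4600, 0.5087, 0.1707,
               0.4615, 0.4186, 0.5681, 0.5476, 0.8148),
    FXIIIB = c(0.4782, 0.4464, 0.5000, 0.2244, 0.4000, 0.2105, 0.3658,
               0.3846, 0.2790, 0.4772, 0.4761, 0.3703),
    CD4    = c(0.1521, 0.1785, 0.1052, 0.1224, 0.1800, 0.1754, 0.2439,
               0.1025, 0.1395, 0.0909, 0.1190, 0.0363),
    APO    = c(0.3043, 0.4107, 0.7631, 0.1428, 0.2200, 0.3508, 0.3658,
               0.2307, 0.1627, 0.2045, 0.5238, 0.6666),
    D1     = c(0.3478, 0.2678, 0.4210, 0.1020, 0.1200, 0.3859, 0.2439,
               0.3333, 0.2352, 0.5227, 0.1904, 0.4363),
    PV92   = c(0.5217, 0.5892, 0.4736, 0.5306, 0.4000, 0.4385, 0.3414,
               0.5128, 0.5581, 0.5227, 0.2380, 0.4545),
    all_loci = c(0.3850, 0.4357, 0.42477, 0.29152, 0.33428, 0.37590,
                 0.33447, 0.34797, 0.32594, 0.41556, 0.39110, 0.46845),
    stringsAsFactors = FALSE)
  df
}

#' Published gene-diversity decomposition across the 12 survey populations
#'
#' Per-locus total diversity (`Ht`), mean within-population diversity
#' (`Hs`) and differentiation (`Gst`) over the twelve caste/tribal
#' populations, plus the published "All loci" aggregates (unweighted means
#' of the per-locus columns).
#'
#' Two published rows are internally inconsistent and cannot be reproduced
#' from the `(Ht - Hs) / Ht` identity: FXIIIB (printed `Hs` exceeds `Ht`)
#' and CD4 (the identity gives 0.4176, printed 0.0109) — flagged in the
#' `identity_ok` column.
#'
#' @return List with `per_locus` (data frame: `locus`, `Ht`, `Hs`, `Gst`,
#'   `identity_ok`) and `all_loci` (named vector `Ht`, `Hs`, `Gst`).
#' @export
alu_study_diversity <- function() {
  per_locus <- data.frame(
    locus = ALU_LOCI,
    Ht  = c(0.4959, 0.4784, 0.4951, 0.2550, 0.4336, 0.4994, 0.4900),
    Hs  = c(0.4664, 0.4572, 0.5219, 0.1485, 0.4153, 0.4871, 0.4773),
    Gst = c(0.0595, 0.0444, 0.0494, 0.0109, 0.0420, 0.0246, 0.02602),
    identity_ok = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(per_locus = per_locus,
       all_loci = c(Ht = 0.4496, Hs = 0.4248, Gst = 0.03671))
}

#' Published gene-diversity decomposition across tribal groups
#'
#' `Ht`, `Hs`, `Gst` per locus for three published tribal groupings:
#' the five South Indian tribes (`SIT`), the four North Indian tribes
#' (`NIT`) and the combined set (`CSNIT`). `NA` where a locus was not
#' analysed for a grouping. The NIT D1 row is internally inconsistent
#' (printed `Hs` exceeds `Ht`) and is flagged in `identity_ok`.
#'
#' @return List with `per_locus` (data frame: `locus`, `group`, `Ht`,
#'   `Hs`, `Gst`, `identity_ok`) and `all_loci` (data frame: `group`,
#'   `Ht`, `Hs`, `Gst`).
#' @export
alu_tribal_diversity <- function() {
  loci <- c("ACE", "FXIIIB", "CD4", "APO", "PV92", "TPA25", "D1")
  per_locus <- rbind(
    data.frame(locus = loci, group = "SIT",
               Ht  = c(0.48539, 0.45151, 0.09986, 0.39732, 0.49817, NA, NA),
               Hs  = c(0.45038, 0.41058, 0.09412, 0.35581, 0.45311, NA, NA),
               Gst = c(0.07212, 0.09065, 0.05750, 0.10445, 0.09046, NA, NA),
               identity_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, NA, NA),
               stringsAsFactors = FALSE),
    data.frame(locus = loci, group = "NIT",
               Ht  = c(0.47991, 0.42369, 0.09859, 0.46798, 0.48481,
                       0.47886, 0.44524),
               Hs  = c(0.44763, 0.39324, 0.09197, 0.38898, 0.46197,
                       0.45235, 0.463420),
               Gst = c(0.06726, 0.07186, 0.06712, 0.16879, 0.04711,
                       0.05536, 0.03921),
               identity_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
               stringsAsFactors = FALSE),
    data.frame(locus = loci, group = "CSNIT",
               Ht  = c(0.47590, 0.42350, 0.07370, 0.43630, 0.49940, NA, NA),
               Hs  = c(0.4400, 0.3880, 0.0693, 0.3642, 0.4516, NA, NA),
               Gst = c(0.0753, 0.0836, 0.0600, 0.1651, 0.0958, NA, NA),
               identity_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, NA, NA),
               stringsAsFactors = FALSE))
  all_loci <- data.frame(group = c("SIT", "NIT", "CSNIT"),
                         Ht  = c(0.38645, 0.41129, 0.38180),
                         Hs  = c(0.35284, 0.38565, 0.3426),
                         Gst = c(0.08304, 0.07381, 0.0959),
                         stringsAsFactors = FALSE)
  list(per_locus = per_locus, all_loci = all_loci)
}
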