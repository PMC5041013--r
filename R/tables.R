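#' NCBI full-genome sample of halophilic archaea
#'
#' The 29 halophilic archaea (one randomly chosen representative strain per
#' species with a full genome in NCBI, taxid 183963) with their reported G+C
#' content, genome size and gene count. The `gc_percent` column is the
#' in-package dataset consumed by the summary-statistics stage
#' ([summarize_group()]).
#'
#' @format data.frame with 29 rows: `species`, `strain`, `gc_percent`,
#'   `size_mb`, `genes`.
#' @seealso [gc_group_reference]
#' @export
halophilic_archaea <- data.frame(
  species = c(
    "Halalkalicoccus jeotgali", "Halanaeroarchaeum sulfurireducens",
    "Haloarcula hispanica", "Haloarcula marismortui", "Haloarcula sp.",
    "Halobacterium hubeiense", "Halobacterium salinarum", "Halobacterium sp.",
    "Haloferax gibbonsii", "Haloferax mediterranei", "Haloferax volcanii",
    "Halogeometricum borinquense", "Halomicrobium mukohataei",
    "Halopiger xanaduensis", "Haloquadratum walsbyi", "Halorhabdus tiamatea",
    "Halorhabdus utahensis", "Halorubrum lacusprofundi",
    "Halostagnicola larsenii", "Haloterrigena turkmenica", "Halovivax ruber",
    "Natrialba magadii", "Natrinema pellirubrum", "Natrinema sp.",
    "Natronobacterium gregoryi", "Natronococcus occultus",
    "Natronomonas moolapensis", "Natronomonas pharaonis", "Salinarchaeum sp."
  ),
  strain = c(
    "B3", "HSR2", "N601", "ATCC 43049", "CBA1115", "JI20-1", "NRC-1", "DL1",
    "ARA6", "ATCC 33500", "DS2", "DSM 11551", "DSM 12286", "SH-6",
    "DSM 16790", "SARL4B", "DSM 12940", "ATCC 49239", "XH-48", "DSM 5511",
    "XH-70", "ATCC 43099", "DSM 15624", "J7-2", "SP2", "SP4", "8.8.11",
    "DSM 2160", "Harcht-Bsk1"
  ),
  gc_percent = c(
    62.56, 62.86, 62.47, 61.14, 61.98, 66.58, 65.92, 66.44, 66.24, 60.26,
    65.46, 59.97, 65.51, 65.20, 47.90, 62.77, 62.90, 63.95, 60.87, 64.25,
    64.30, 61.03, 63.96, 64.06, 62.20, 64.63, 64.50, 63.08, 66.60
  ),
  size_mb = c(
    3.699, 2.210, 3.902, 4.275, 4.225, 3.130, 2.571, 3.163, 3.918, 3.905,
    4.013, 3.944, 3.332, 4.355, 3.179, 3.146, 3.117, 3.693, 4.131, 5.441,
    3.224, 4.444, 4.354, 3.794, 3.788, 4.314, 2.913, 2.750, 3.255
  ),
  genes = c(
    3717L, 2213L, 3825L, 4226L, 4108L, 3189L, 2629L, 3237L, 3783L, 3800L,
    3925L, 3838L, 3293L, 4174L, 2827L, 3069L, 2969L, 3523L, 3954L, 5074L,
    3187L, 4128L, 4178L, 3681L, 3720L, 4162L, 2793L, 2799L, 3036L
  ),
  stringsAsFactors = FALSE
)

#' Reported G+C summary of the five taxonomic sample groups
#'
#' Group sizes and G+C content summaries (mean with 1.96-standard-error
#' half-width, and median, in percent) reported for the five NCBI genome
#' sample groups. Used as emulation targets by [reference_group_specs()] and
#' as the external check for [summarize_group()] on the halophilic-archaea
#' row, whose values recompute from [halophilic_archaea]`$gc_percent`.
#'
#' @format data.frame with 5 rows: `group_label`, `n`, `gc_mean_percent`,
#'   `gc_halfwidth_196se`, `gc_median_percent`.
#' @export
gc_group_reference <- data.frame(
  group_label = c(
    "archaea", "bacteria", "cyanobacteria", "enterobacteriaceae",
    "halophilic_archaea"
  ),
  n = c(68L, 101L, 32L, 42L, 29L),
  gc_mean_percent = c(43.87, 49.10, 44.21, 47.83, 63.09),
  gc_halfwidth_196se = c(2.30, 2.55, 3.08, 3.17, 1.28),
  gc_median_percent = c(43.05, 47.25, 42.65, 51.73, 63.95),
  stringsAsFactors = FALSE
)
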