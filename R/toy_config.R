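# Bundled "toy-asia" study conditions: six East-Asian-style cohorts at one
# tenth of the published sample sizes (discovery 2,490/8,044 and replication
# 2,425/5,469), with planted residue effects at the six independently
# associated positions and their published odds ratios.

#' Bundled synthetic allele-to-protein map
#'
#' DRB1 allele residue vectors at 14 binding-groove positions are real
#' (transcribed from published allele tables); the Class I / DP / DQ maps
#' are invented toy maps that carry the independently associated positions
#' (A-70, B-9, DPB1-35, DQB1-37). The \code{"x"} residue at A-152 exercises
#' the absence/indel grouping path.
#'
#' @return An \code{allele_protein_map}.
#' @export
toy_allele_map <- function() {
  drb1_pos <- c(86, 26, 70, 71, 74, 11, 13, 30, 28, 47, 67, 9, 37, 57)
  drb1 <- rbind(
    "15:01" = c("V","F","Q","A","A","P","R","Y","D","F","I","W","S","D"),
    "09:01" = c("G","F","Q","R","E","D","F","G","D","Y","F","K","N","V"),
    "04:01" = c("G","F","Q","K","A","V","H","Y","D","Y","L","E","Y","D"),
    "04:05" = c("G","F","Q","R","A","V","H","Y","D","Y","L","E","Y","S"),
    "03:01" = c("V","Y","Q","K","R","S","S","Y","D","F","L","E","N","D"),
    "08:03" = c("G","F","D","R","L","S","G","Y","D","Y","I","E","Y","S"),
    "01:03" = c("G","L","D","E","A","L","F","C","E","Y","I","W","S","D"),
    "04:02" = c("V","F","D","E","A","V","H","Y","D","Y","I","E","Y","D"),
    "07:01" = c("G","F","D","R","Q","G","Y","L","E","Y","I","W","F","V"),
    "11:01" = c("G","F","D","R","A","S","S","Y","D","F","F","E","Y","D"),
    "14:01" = c("V","F","R","R","E","S","G","Y","D","Y","L","E","F","A"),
    "14:04" = c("V","F","R","E","E","S","G","Y","D","F","I","E","N","D"),
    "12:01" = c("V","L","D","R","A","S","G","H","E","F","I","E","L","V"),
    "01:01" = c("G","L","Q","R","A","L","F","C","E","Y","L","W","S","D"))
  rows <- list()
  for (al in rownames(drb1))
    rows[[length(rows) + 1L]] <-
      data.frame(gene = "DRB1", allele = al, aa_pos = drb1_pos,
                 residue = drb1[al, ], stringsAsFactors = FALSE)
  toy <- function(gene, pos, tab) {
    for (al in rownames(tab))
      rows[[length(rows) + 1L]] <<-
        data.frame(gene = gene, allele = al, aa_pos = pos,
                   residue = tab[al, ], stringsAsFactors = FALSE)
  }
  toy("A", c(70, 97, 152), rbind(
    "02:01" = c("Q", "R", "A"),
    "11:01" = c("H", "I", "V"),
    "24:02" = c("H", "R", "A"),
    "33:03" = c("Q", "I", "x")))
  toy("B", c(9, 63, 67), rbind(
    "40:01" = c("H", "E", "C"),
    "58:01" = c("D", "N", "M"),
    "15:11" = c("Y", "N", "S"),
    "46:01" = c("Y", "E", "M")))
  toy("DPB1", c(9, 35, 55), rbind(
    "05:01" = c("Y", "Y", "D"),
    "02:01" = c("F", "F", "D"),
    "04:01" = c("F", "L", "A"),
    "03:01" = c("Y", "L", "E")))
  toy("DQB1", c(37, 57, 70), rbind(
    "06:02" = c("I", "A", "E"),
    "03:01" = c("Y", "D", "E"),
    "03:03" = c("I", "V", "G"),
    "05:01" = c("S", "D", "G")))
  as_allele_map(do.call(rbind, rows))
}

#' Bundled synthetic per-gene allele frequency tables
#'
#' Illustrative East-Asian-style 4-digit allele frequencies for the five
#' genes covered by \code{\link{toy_allele_map}}; each gene's table sums
#' to 1.
#'
#' @return Named list of named numeric vectors.
#' @export
toy_allele_freqs <- function() {
  list(
    DRB1 = c("09:01" = 0.15, "15:01" = 0.10, "04:01" = 0.06, "04:05" = 0.07,
             "03:01" = 0.05, "08:03" = 0.07, "01:03" = 0.02, "04:02" = 0.03,
             "07:01" = 0.08, "11:01" = 0.12, "14:01" = 0.06, "14:04" = 0.04,
             "12:01" = 0.10, "01:01" = 0.05),
    A    = c("02:01" = 0.30, "11:01" = 0.25, "24:02" = 0.25, "33:03" = 0.20),
    B    = c("40:01" = 0.28, "58:01" = 0.18, "15:11" = 0.24, "46:01" = 0.30),
    DPB1 = c("05:01" = 0.40, "02:01" = 0.25, "04:01" = 0.20, "03:01" = 0.15),
    DQB1 = c("06:02" = 0.105, "03:01" = 0.355, "03:03" = 0.14, "05:01" = 0.40))
}

#' Bundled multi-cohort study conditions
#'
#' Six cohorts (KR, HC1, MC discovery; HC2, JP1, JP2 replication) at
#' \code{scale} times one tenth of the published sample sizes, sharing the
#' bundled allele frequency tables and map. A DRB1--DQB1 joint haplotype
#' block couples DRB1*15:01 with DQB1*06:02 at squared correlation 0.92
#' (the DR15 linkage). Planted residue effects use the published most-risk
#' odds ratios at the six independent positions; the nRNP and Ro
#' sub-phenotype models plant the published DRB1-11 and DPB1-35 effects.
#'
#' @param seed Integer seed.
#' @param scale Multiplier on the 1/10-scale cohort sizes.
#' @return A \code{sim_config}.
#' @export
toy_asia_config <- function(seed = 1, scale = 1) {
  freqs <- toy_allele_freqs()
  sizes <- list(KR  = c(125, 440), HC1 = c(75, 225), MC  = c(49, 139),
                HC2 = c(60, 130),  JP1 = c(120, 290), JP2 = c(63, 127))
  cohorts <- lapply(sizes, function(s)
    list(n_cases = max(2L, round(s[1] * scale)),
         n_controls = max(2L, round(s[2] * scale))))
  hap <- couple_alleles(freqs$DRB1, freqs$DQB1, "15:01", "06:02", 0.92)
  names(hap) <- c("DRB1", "DQB1", "freq")
  causal <- data.frame(
    gene    = c("DRB1", "DRB1", "A", "DPB1", "DQB1", "B"),
    aa_pos  = c(13, 37, 70, 35, 37, 9),
    residue = c("R", "S", "Q", "Y", "I", "D"),
    beta    = log(c(1.43, 1.20, 1.16, 1.29, 1.25, 2.43)),
    stringsAsFactors = FALSE)
  subpheno <- list(
    nRNP  = list(baseline = 0.372,
                 effects = data.frame(gene = c("DRB1", "DRB1"),
                                      aa_pos = c(11, 11),
                                      residue = c("D", "S"),
                                      beta = log(c(1.82, 0.62)))),
    Ro    = list(baseline = 0.466,
                 effects = data.frame(gene = "DPB1", aa_pos = 35,
                                      residue = "L", beta = log(1.3))),
    La    = list(baseline = 0.25, effects = NULL),
    Sm    = list(baseline = 0.20, effects = NULL),
    dsDNA = list(baseline = 0.40, effects = NULL),
    ACL   = list(baseline = 0.15, effects = NULL))
  sim_config(seed = seed, cohorts = cohorts, allele_freqs = freqs,
             allele_map = toy_allele_map(),
             haplo_ld = list(list(genes = c("DRB1", "DQB1"), haps = hap)),
             causal_effects = causal,
             default_r2 = 0.95,
             target_r2 = c(SNP_A_29909247 = 0.65),
             subpheno = subpheno)
}
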