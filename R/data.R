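#' Confirmed-disorder reference counts
#'
#' The disorder spectrum confirmed by the modelled five-year screening
#' programme (300,849 newborns): per-disorder case counts, screening
#' category (AAMD/OAMD/FAOD), the screening rule and rule group that detects
#' the disorder, and the reported "1:N" frequency string.
#'
#' @return data frame `disorder`, `label`, `category`, `cases`, `rule_id`,
#'   `target_group`, `frequency`.
#' @export
nbs_confirmed_counts <- function() {
  utils::read.csv(nbs_extdata("confirmed_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Yearly screening volume of the modelled programme
#'
#' Per-year screened, first-screen suspected-positive, successfully recalled
#' and confirmed counts, 2016-2020, with the reported yearly frequency
#' strings.
#'
#' @return data frame `year`, `screened`, `suspected`, `recalled`,
#'   `confirmed`, `frequency`.
#' @export
nbs_screening_volume <- function() {
  utils::read.csv(nbs_extdata("screening_volume.csv"),
                  stringsAsFactors = FALSE)
}

#' Abnormal marker levels of the confirmed cases
#'
#' Long-format table of the printed abnormal MS/MS levels of the programme's
#' confirmed cases: one row per (case, marker).  `subset` distinguishes
#' cases with full laboratory and genetic work-up (`sequenced`) from those
#' diagnosed clinically elsewhere (`clinical`).  These values anchor the
#' disease profiles of the synthetic cohort generator and serve as the rule
#' engine's regression fixture.
#'
#' @return data frame `case_id`, `diagnosis`, `sex`, `subset`, `marker`,
#'   `value`.
#' @export
nbs_case_panels <- function() {
  utils::read.csv(nbs_extdata("case_panels.csv"), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Genotypes of the sequenced confirmed cases
#'
#' @return allele-level data frame (see [read_genotypes()]).
#' @export
nbs_case_genotypes <- function() {
  read_genotypes(nbs_extdata("case_genotypes.tsv"))
}

#' Canonical variant allele counts of the mutation spectrum
#'
#' The consolidated allele-count table of the programme's mutation spectrum
#' (118 detected alleles), with pathogenicity annotation and the reported
#' relative/total frequency percentages.  This table is the canonical
#' accounting; the raw per-case genotypes ([nbs_case_genotypes()]) differ
#' from it by single alleles for two genes.
#'
#' @return data frame `disorder`, `gene`, `transcript`, `variant_c`,
#'   `variant_p`, `classification`, `count`, `rel_freq`, `total_freq`.
#' @export
nbs_variant_counts <- function() {
  utils::read.delim(nbs_extdata("variant_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Gene-to-disease-group map for spectrum tabulation
#'
#' @return named list group -> gene symbols (HPA pools PAH and PTS).
#' @export
nbs_group_map <- function() {
  yaml::read_yaml(nbs_extdata("group_map.yaml"))$groups
}
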