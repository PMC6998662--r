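#' Controlled vocabularies for cohort tables
#'
#' The ten circulating RNA classes profiled in serum small-RNA sequencing,
#' and the levels used for sample covariates. `not_applicable` is reserved
#' for controls, which carry no stage, histology or time to diagnosis.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
rna_classes <- function() {
  c("miRNA", "miRNA_hairpin", "isomiR", "piRNA", "tRNA",
    "tRF", "snoRNA", "miscRNA", "lncRNA", "mRNA")
}

#' @rdname vocabularies
#' @export
stage_levels <- function() {
  c("early", "locally_advanced", "advanced", "unknown", "not_applicable")
}

#' @rdname vocabularies
#' @export
histology_levels <- function() {
  c("NSCLC", "SCLC", "ADC", "other", "not_applicable")
}

#' @rdname vocabularies
#' @export
smoking_levels <- function() c("current", "former", "never", "unknown")

#' @rdname vocabularies
#' @export
sex_levels <- function() c("male", "female")

group_levels <- function() c("case", "control")

sample_table_cols <- function() {
  c("sample_id", "subject_id", "group", "sex", "age_at_donation", "bdg",
    "smoking", "stage", "histology", "time_to_diagnosis")
}

#' Cohort margins of the Janus serum-bank lung-cancer study
#'
#' Sample counts by stage, histology, sex and smoking as published for the
#' 542 prediagnostic lung-cancer serum samples and 519 matched cancer-free
#' controls. These are the default margins of [simulate_cohort()].
#'
#' @return A list with components:
#'   * `cases`: integer matrix of case sample counts, histology x stage
#'     (rows `NSCLC`, `SCLC`, `other`; columns `early`, `locally_advanced`,
#'     `advanced`, `unknown`).
#'   * `case_sex`: integer matrix, sex x stage.
#'   * `case_never_smokers`: per-stage counts of case samples that are never
#'     smokers or missing smoking data (excluded from windowed analyses).
#'   * `n_controls`: number of control samples.
#'   * `control_sex`: named counts of control samples by sex.
#'   * `n_control_smokers`: control samples that are current or former smokers.
#'   * `age`: list of per-group age means/SDs (years) at donation.
#' @examples
#' m <- janus_margins()
#' sum(m$cases)        # 542 case samples
#' colSums(m$cases)    # per-stage totals
#' @export
janus_margins <- function() {
  cases <- rbind(
    NSCLC = c(84L, 101L, 171L, 11L),
    SCLC  = c(9L, 35L, 76L, 4L),
    other = c(10L, 5L, 32L, 4L)
  )
  colnames(cases) <- stage_levels()[1:4]
  case_sex <- rbind(
    male   = c(78L, 104L, 180L, 12L),
    female = c(25L, 37L, 99L, 7L)
  )
  colnames(case_sex) <- stage_levels()[1:4]
  list(
    cases = cases,
    case_sex = case_sex,
    case_never_smokers = c(early = 1L, locally_advanced = 2L,
                           advanced = 8L, unknown = 0L),
    n_controls = 519L,
    control_sex = c(male = 350L, female = 169L),
    n_control_smokers = 189L,
    age = list(
      control = c(mean = 49.9, sd = 11.2),
      case = rbind(
        mean = c(early = 54.3, locally_advanced = 55.0,
                 advanced = 53.4, unknown = 51.8),
        sd   = c(early = 7.33, locally_advanced = 9.04,
                 advanced = 8.26, unknown = 6.53)
      )
    )
  )
}
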