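#' Reference per-category leaf counts of HPO Phenotypic abnormality
#'
#' The published leaf-node counts of the 23 categories directly under
#' Phenotypic abnormality (HP:0000118), as extracted per category with
#' TogoDX from the HPO snapshot profiled in the motivating curation study
#' (category labels reproduced verbatim, including their spellings).
#' Absolute counts are release-dependent: rerunning the extraction against
#' a current HPO release will give different numbers. The table is kept as
#' reference input for the summary arithmetic this package reproduces
#' (counts ranging 4 to 2743, mean 676.8).
#'
#' @return A tibble with columns `category_label`, `n_total` (23 rows).
#' @export
hpo_category_counts <- function() {
  tibble::tribble(
    ~category_label, ~n_total,
    "Abnormality of the genitourinary system", 1039L,
    "Abnormal cellular phenotyp", 191L,
    "Abnormality of blood and blood-forming tissues", 570L,
    "Abnormality of head and neck", 961L,
    "Abnormality of limbs", 1688L,
    "Abnormality of metabolism/homeostasis", 1219L,
    "Abnormality of prenatal development or birth", 192L,
    "Abnormality of the breast", 24L,
    "Abnormality of the cardiovascular system", 957L,
    "Abnormality of the digestive system", 496L,
    "Abnormality of the ear", 213L,
    "Abnormality of the endocrine system", 273L,
    "Abnormality of the eye", 777L,
    "Abnormality of the immune system", 871L,
    "Abnormality of the integument", 713L,
    "Abnormality of the muscleskeletal system", 2743L,
    "Abnormality of the nervous system", 1586L,
    "Abnormality of the respiratory system", 445L,
    "Abnormality of the thoracic cavity", 4L,
    "Abnormality of the voice", 21L,
    "Constitutional symptom", 81L,
    "Growth abnormality", 68L,
    "Neoplasm", 435L
  )
}

#' Reference Symptoms-and-Findings curation tallies
#'
#' Clinician curation results for the 16 categories curated in the
#' motivating study: total leaf terms per category and how many were
#' tagged Symptoms and Findings (abnormalities revealable by physical
#' examination). The published percentage column is recomputed, never
#' stored: `percent_half_up(n_symptoms_findings, n_total)` reproduces
#' every printed cell (0.0 for Neoplasm through 93.1 for head and neck),
#' which is the package's exact-arithmetic check.
#'
#' @return A tibble with columns `category_label`, `n_total`,
#'   `n_symptoms_findings` (16 rows).
#' @export
hpo_symptoms_findings <- function() {
  tibble::tribble(
    ~category_label, ~n_total, ~n_symptoms_findings,
    "Abnormal cellular phenotyp", 191L, 0L,
    "Abnormality of blood and blood-forming tissues", 570L, 26L,
    "Abnormality of head and neck", 961L, 895L,
    "Abnormality of prenatal development or birth", 192L, 33L,
    "Abnormality of the breast", 24L, 19L,
    "Abnormality of the digestive system", 496L, 92L,
    "Abnormality of the ear", 213L, 154L,
    "Abnormality of the endocrine system", 273L, 5L,
    "Abnormality of the immune system", 871L, 31L,
    "Abnormality of the integument", 713L, 603L,
    "Abnormality of the respiratory system", 445L, 67L,
    "Abnormality of the thoracic cavity", 4L, 0L,
    "Abnormality of the voice", 21L, 16L,
    "Constitutional symptom", 81L, 77L,
    "Growth abnormality", 68L, 63L,
    "Neoplasm", 435L, 0L
  )
}

#' Published percentage cells of the curation report
#'
#' The one-decimal percentages as printed in the published Symptoms and
#' Findings table, keyed by category, for checking that
#' [percent_half_up()] reproduces each from its (count, total) pair.
#'
#' @return A tibble with columns `category_label`, `percent_printed`.
#' @export
hpo_symptoms_findings_percent <- function() {
  tibble::tribble(
    ~category_label, ~percent_printed,
    "Abnormal cellular phenotyp", 0.0,
    "Abnormality of blood and blood-forming tissues", 4.6,
    "Abnormality of head and neck", 93.1,
    "Abnormality of prenatal development or birth", 17.2,
    "Abnormality of the breast", 79.2,
    "Abnormality of the digestive system", 18.5,
    "Abnormality of the ear", 72.3,
    "Abnormality of the endocrine system", 1.8,
    "Abnormality of the immune system", 3.6,
    "Abnormality of the integument", 84.6,
    "Abnormality of the respiratory system", 15.1,
    "Abnormality of the thoracic cavity", 0.0,
    "Abnormality of the voice", 76.2,
    "Constitutional symptom", 95.1,
    "Growth abnormality", 92.6,
    "Neoplasm", 0.0
  )
}
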