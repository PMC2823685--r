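#' Published Zur target measurements for C. glutamicum ATCC 13032
#'
#' `cgl_zur_targets()` returns the nine genes of the five Zur-repressed
#' transcription units of *Corynebacterium glutamicum* ATCC 13032, with the
#' 21-bp candidate Zur-binding site of each unit's promoter region (NA for
#' operon-internal genes), the microarray mean log2 ratio (`m_array`, zur
#' mutant vs wild type) and the qPCR fold change (`fold_rtpcr`, `2^-dCP`).
#' `cgl_zur_other_de()` returns the seventeen additional differentially
#' expressed genes that lack candidate Zur-binding sites; `fold_rtpcr` is
#' `NA` where the qPCR assay was not significant. `cgl_adha_site()` returns
#' the conserved candidate site found upstream of the alcohol-dehydrogenase
#' gene `adhA` (`cg3107`), which is not differentially expressed in the zur
#' mutant and is not bound by Zur in vitro.
#'
#' @return Tibbles (see above); `cgl_adha_site()` a single 21-mer string.
#' @export
#' @examples
#' cgl_zur_targets() |> dplyr::filter(!is.na(motif))
cgl_zur_targets <- function() {
  tibble::tribble(
    ~cds,      ~gene,    ~product,                                             ~tu,       ~motif,                  ~m_array, ~fold_rtpcr,
    "cg0040",  NA,       "secreted protein",                                   "cg0042",  NA,                      3.34,     4.5,
    "cg0041",  "znuA2",  "ABC-type Zn/Mn transporter, substrate-binding protein", "cg0042", NA,                    5.68,     27900,
    "cg0042",  "znuB2",  "ABC-type Zn/Mn transporter, permease subunit",       "cg0042",  "TAATGATAACGGTTATCATTT", 2.25,     331,
    "cg0043",  "znuC2",  "ABC-type Zn/Mn transporter, ATPase subunit",         "cg0043",  "AAATGATAACCGTTATCATTA", 2.13,     50.2,
    "cg0794",  "yciC",   "P-loop GTPase of the COG0523 family",                "cg0794",  "TATTGAAAATGATTCCCAAAA", 2.75,     10.5,
    "cg0795",  NA,       "oxidoreductase",                                     "cg0795",  "TAATGGAAATTGTTTTCAATA", 5.43,     45500,
    "cg2911",  "znuA1",  "ABC-type Zn/Mn transporter, substrate-binding protein", "cg2911", "TGTTGACATCCTTTTTCAATA", 3.52,   43.8,
    "cg2912",  "znuC1",  "ABC-type Zn/Mn transporter, ATPase subunit",         "cg2911",  NA,                      2.79,     75.8,
    "cg2913",  "znuB1",  "ABC-type Zn/Mn transporter, permease subunit",       "cg2911",  NA,                      1.29,     29.0)
}

#' @rdname cgl_zur_targets
#' @export
cgl_zur_other_de <- function() {
  tibble::tribble(
    ~cds,      ~gene,     ~product,                                       ~m_array, ~fold_rtpcr,
    "cg0045",  NA,        "ABC-type transporter, permease subunit",       -1.12,    NA,
    "cg0215",  "cspA",    "cold-shock protein A",                          1.24,    NA,
    "cg0793",  NA,        "putative secreted protein",                     1.67,    4.01,
    "cg0796",  "prpD1",   "citrate dehydratase",                           1.00,    6.68,
    "cg1109",  "porB",    "anion-specific porin precursor",                1.12,    7.67,
    "cg1332",  NA,        "putative secreted protein",                     1.42,    2.57,
    "cg1447",  NA,        "putative Co/Zn/Cd efflux transporter",          3.16,    25.8,
    "cg1670",  NA,        "hypothetical protein",                          1.07,    4.81,
    "cg2181",  NA,        "ABC-type transporter, substrate-binding protein", 1.10,  4.91,
    "cg2261",  "amtB",    "secondary ammonium transporter",               -1.01,    NA,
    "cg2560",  "aceA",    "isocitrate lyase",                              1.56,    NA,
    "cg2925",  "ptsS",    "phosphotransferase system component",          -1.35,    NA,
    "cg3096",  "ald",     "acetaldehyde dehydrogenase",                    1.69,    103,
    "cg3138",  NA,        "putative membrane protease subunit",            3.14,    NA,
    "cg3139",  NA,        "hypothetical protein",                          2.03,    NA,
    "cg3140",  "tagA1",   "DNA-3-methyladenine glycolase I",               1.88,    NA,
    "cg3195",  NA,        "putative flavin-containing monooxygenase",      1.44,    3.22)
}

#' @rdname cgl_zur_targets
#' @export
cgl_adha_site <- function() "AATTGAAAAACATTTCCATTA"

#' The canonical C. glutamicum Zur motif model
#'
#' Convenience constructor: the palindromic PWM built from the five 21-bp
#' candidate Zur-binding sites of the *C. glutamicum* target table, with
#' the training-minimum threshold set.
#'
#' @param pseudocount Passed to [build_motif()].
#' @return A `pwm_model` with threshold set.
#' @export
cgl_zur_motif <- function(pseudocount = 0.5) {
  sites <- cgl_zur_targets()$motif
  set_threshold_from_training(
    build_motif(sites[!is.na(sites)], palindromic = TRUE,
                pseudocount = pseudocount))
}
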