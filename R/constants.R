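#' @keywords internal
"_PACKAGE"

# Canonical orderings used throughout the package.
LIKERT_LABELS <- c("never", "almost_never", "sometimes", "most_of_time", "always")
DK_LABEL <- "dont_know"
TRIPLET_SOURCES <- c("R1", "SR", "R2")
BEHAVIORS <- c("grinding", "clenching", "bracing_thrusting")
COMPONENTS <- c("R1", "SR", "R2", "ICA", "ECA", "EMA")
STAGES <- c("test", "retest")
INTRAORAL_FINDINGS <- c(
  "buccal_hyperkeratosis_linea_alba", "labial_hyperkeratosis",
  "labial_indentation", "tongue_indentation", "buccal_indentation"
)
EXTRAORAL_FINDINGS <- c("masseter_hypertrophy", "temporal_hypertrophy")
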