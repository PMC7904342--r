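# Shared schema constants (defined first in collation order).

GROUP_LEVELS <- c("NC", "PDN", "PD-MCI", "PDD")
DOMAIN_COLS <- c("z_attention", "z_executive", "z_language", "z_memory",
                 "z_visuospatial")
COHORT_REQUIRED <- c("id", "group", "age", "sex", "disease_duration",
                     "updrs1", "updrs2", "updrs3", "updrs_total", "hy",
                     "se_adl", "mmse", "casi", DOMAIN_COLS,
                     "nuclear_dna", "mito_dna", "alps")
HY_LEVELS <- seq(0, 5, by = 0.5)
TENSOR_COMPONENTS <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
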