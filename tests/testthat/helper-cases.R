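# Shared harmonization fixtures: a minimal record builder and the
# enumeration of allele configurations against the documented contract.

assoc_row <- function(id, ea, oa, beta, se = 0.01, eaf = NA, trait = "t") {
  tibble::tibble(variant_id = id, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pval = 0.5, n = 1e5,
                 trait_id = trait)
}

# enumeration of every allele configuration against the documented contract
harmonization_cases <- function() {
  tibble::tribble(
    ~ea_e, ~oa_e, ~eaf_e, ~ea_o, ~oa_o, ~eaf_o, ~status, ~beta_mult,
    # non-palindromic
    "A", "G", 0.3, "A", "G", 0.3,  "kept",                 1,
    "A", "G", 0.3, "G", "A", 0.7,  "sign_flipped",        -1,
    "A", "G", 0.3, "T", "C", 0.3,  "strand_flipped",       1,
    "A", "G", 0.3, "C", "T", 0.7,  "strand_flipped",      -1,
    "A", "G", 0.3, "A", "C", 0.3,  "dropped_incompatible", NA,
    "A", "G", 0.3, "T", "G", 0.3,  "dropped_incompatible", NA,
    # palindromic, frequencies informative and agreeing
    "A", "T", 0.2, "A", "T", 0.25, "kept",                 1,
    "C", "G", 0.8, "G", "C", 0.25, "sign_flipped",        -1,
    # palindromic, frequencies disagree -> opposite-strand coding
    "A", "T", 0.2, "A", "T", 0.75, "strand_flipped",      -1,
    # letters look swapped but frequencies say same effect allele: the
    # two flips cancel, leaving the outcome beta unchanged
    "A", "T", 0.2, "T", "A", 0.3,  "strand_flipped",       1,
    # palindromic, a frequency inside the ambiguity window or missing
    "A", "T", 0.5, "A", "T", 0.2,  "dropped_palindromic",  NA,
    "A", "T", 0.2, "A", "T", 0.43, "dropped_palindromic",  NA,
    "C", "G", NA,  "C", "G", 0.2,  "dropped_palindromic",  NA,
    # palindromic letters against non-palindromic outcome record
    "A", "T", 0.2, "A", "G", 0.2,  "dropped_incompatible", NA
  )
}

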