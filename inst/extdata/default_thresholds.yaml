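# Default peptide-ID filtering profile. Every key mirrors an argument of
# filter_thresholds(); edit per dataset. All comparisons are inclusive.
min_replicates: 2          # replicates a peptide must appear in (per trendline)
max_rt_rsd: 5              # retention-time relative SD across replicates, %
min_products_per_aa: 0.2   # fragment products per amino acid
min_intensity: 5000        # precursor intensity
min_length: 4              # residues
max_length: 30             # residues
min_matched_products: 3    # matched product ions
min_consecutive_products: 2
min_sum_product_intensity: 500
min_plgs_score: 6.62       # search-engine confidence score
max_abs_ppm_error: 10      # absolute MH+ mass error, ppm
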