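{
  "title": "ftirfp analysis report",
  "description": "Structural schema of the report produced by run_pipeline(). Checked by validate_report().",
  "type": "object",
  "required": {
    "provenance": "object: config (echoed, normalized), config_md5, seed, package_version",
    "regions": "object keyed '<low>-<high>': region bounds, explained_variance_pct, side_tables (per PC: group, n, fraction_positive, side), clean_separation_pcs, quadrants (group, majority_quadrant, purity), loading_peaks (per PC: wavenumber, loading, side, assignment)",
    "ratios": "array of {sample_id, group, replicate, ch2_ch3, carbonyl_total_lipid, unsat_sat, error}",
    "stats": "array of {ratio, test, comparison, statistic, df, p_value, adjusted, significant}",
    "alpha": "number in (0, 1)"
  },
  "constraints": [
    "every stats[].p_value lies in [0, 1] or is null",
    "every loading peak wavenumber lies inside its region bounds",
    "quadrant purity lies in [0, 1]"
  ]
}
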