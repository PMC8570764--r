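# Published incremental results (health-impact table) of the Cambodia HEF
# diabetes coverage evaluation: incremental discounted cost and incremental
# DALYs vs the current standard, with the published ICER (USD per DALY
# averted, signed for cost-saving strategies).
strategy,eligibility,incremental_cost,incremental_dalys,icer
drug_therapy_only,0.20,1041566,-38404,27
drug_therapy_only,0.30,-1212155,-38404,-32
diagnostics_drug,0.20,142898661,-38341,3727
diagnostics_drug,0.30,141710592,-38341,3696
drug_complications,0.20,143197068,-38403,3729
drug_complications,0.30,141319370,-38404,3680
diagnostics_drug_complications,0.20,436637189,-38341,11388
diagnostics_drug_complications,0.30,437370072,-38341,11407
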