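# Published incremental results (financial-risk-protection table) of the
# Cambodia HEF diabetes coverage evaluation: incremental discounted cost,
# CHE person-year cases at the 40% threshold for the strategy and the
# current-standard comparator, and the published ICER (USD per CHE case
# averted). CHE averted is comparator_che - che.
strategy,eligibility,oop_coverage,incremental_cost,che,comparator_che,icer
diagnostics_only,0.20,1.00,153329057,195860,676340,319
diagnostics_only,0.20,0.80,153329057,482720,676340,792
diagnostics_only,0.30,1.00,153065726,214020,746840,287
diagnostics_only,0.30,0.80,153065726,553100,746840,790
drug_therapy_only,0.20,1.00,1041566,197080,676340,2
drug_therapy_only,0.20,0.80,1041566,514760,676340,6
drug_therapy_only,0.30,1.00,-1212155,213980,746840,-2
drug_therapy_only,0.30,0.80,-1212155,583720,746840,-7
complications_only,0.20,1.00,154305043,184900,676340,314
complications_only,0.20,0.80,154305043,459460,676340,711
complications_only,0.30,1.00,155540742,203440,746840,286
complications_only,0.30,0.80,155540742,529880,746840,717
diagnostics_drug,0.20,1.00,142898661,222020,676340,315
diagnostics_drug,0.20,0.80,142898661,559200,676340,1220
diagnostics_drug,0.30,1.00,141710592,240300,746840,280
diagnostics_drug,0.30,0.80,141710592,628380,746840,1196
drug_complications,0.20,1.00,143197068,208700,676340,306
drug_complications,0.20,0.80,143197068,524560,676340,943
drug_complications,0.30,1.00,141319370,226200,746840,271
drug_complications,0.30,0.80,141319370,594520,746840,928
diagnostics_drug_complications,0.20,1.00,436637189,241880,676340,1005
diagnostics_drug_complications,0.20,0.80,436637189,579720,676340,4519
diagnostics_drug_complications,0.30,1.00,437370072,259640,746840,898
diagnostics_drug_complications,0.30,0.80,437370072,649720,746840,4503
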