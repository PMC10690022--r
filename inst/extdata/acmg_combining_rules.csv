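# ACMG/AMP evidence-combining rules, v1 (packaged as data for auditability).
# A rule fires when the evidence set contains at least the stated number of
# codes in each strength category (PVS = PVS1; PS = PS1-PS4; PM = PM1-PM6;
# PP = PP1-PP5; BA = BA1; BS = BS1-BS4; BP = BP1-BP7). Pathogenic-side and
# benign-side rules are evaluated independently; if both sides fire the
# combined class is VUS (conflicting evidence), as is an empty set.
class,rule_id,min_pvs,min_ps,min_pm,min_pp,min_ba,min_bs,min_bp
Pathogenic,P_1vs_1s,1,1,0,0,0,0,0
Pathogenic,P_1vs_2m,1,0,2,0,0,0,0
Pathogenic,P_1vs_1m_1p,1,0,1,1,0,0,0
Pathogenic,P_1vs_2p,1,0,0,2,0,0,0
Pathogenic,P_2s,0,2,0,0,0,0,0
Pathogenic,P_1s_3m,0,1,3,0,0,0,0
Pathogenic,P_1s_2m_2p,0,1,2,2,0,0,0
Pathogenic,P_1s_1m_4p,0,1,1,4,0,0,0
Likely pathogenic,LP_1vs_1m,1,0,1,0,0,0,0
Likely pathogenic,LP_1s_1m,0,1,1,0,0,0,0
Likely pathogenic,LP_1s_2p,0,1,0,2,0,0,0
Likely pathogenic,LP_3m,0,0,3,0,0,0,0
Likely pathogenic,LP_2m_2p,0,0,2,2,0,0,0
Likely pathogenic,LP_1m_4p,0,0,1,4,0,0,0
Benign,B_1ba,0,0,0,0,1,0,0
Benign,B_2bs,0,0,0,0,0,2,0
Likely benign,LB_1bs_1bp,0,0,0,0,0,1,1
Likely benign,LB_2bp,0,0,0,0,0,0,2
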