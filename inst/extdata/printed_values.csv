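quantity,printed,kind
judge_unconstrained_ob_count,10,count
jugde_judge_shared_obs,9,count
junpe_judge_shared_obs,3,count
span2_ob_count_7letter,15,count
casaca_casa_binary_match,1.0,score
exp1_2L_identity_priming_ms,97,priming
exp1_2L_TL_priming_ms,57,priming
exp1_3L_identity_priming_ms,82,priming
exp1_3L_TL_priming_ms,48,priming
exp2_7L_0L_priming_ms,24,priming
exp2_7L_1L_priming_ms,24,priming
exp2_7L_3L_priming_ms,28,priming
exp3_7L_0L_priming_ms,29,priming
exp3_7L_3L_priming_ms,25,priming
exp3_7L_rev0L_priming_ms,18,priming
exp3_7L_rev3L_priming_ms,13,priming
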