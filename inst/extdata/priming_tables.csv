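experiment,response,target_class,condition,prime_example,rt_ms,pct_error,sig_flag
exp1,Same,2L,identity,of,380,2.1,TRUE
exp1,Same,2L,TL,fo,420,7.5,TRUE
exp1,Same,2L,ALD,ym,477,9.2,NA
exp1,Same,3L,identity,the,389,4.2,TRUE
exp1,Same,3L,TL,hte,423,3.8,TRUE
exp1,Same,3L,ALD,nma,471,12.1,NA
exp1,Different,2L,identity,of,476,4.2,FALSE
exp1,Different,2L,TL,fo,471,5.0,FALSE
exp1,Different,2L,ALD,ym,473,5.4,NA
exp1,Different,3L,identity,the,472,5.8,FALSE
exp1,Different,3L,TL,hte,475,2.9,FALSE
exp1,Different,3L,ALD,mna,501,3.3,NA
exp2,Same,7L,0L,bo,463,4.2,TRUE
exp2,Same,7L,1L,bl,463,4.5,TRUE
exp2,Same,7L,3L,bs,459,5.5,TRUE
exp2,Same,7L,ALD,du,487,4.2,NA
exp2,Different,7L,0L,bo,513,3.0,FALSE
exp2,Different,7L,1L,bl,508,3.9,FALSE
exp2,Different,7L,3L,bs,515,3.6,FALSE
exp2,Different,7L,ALD,du,516,3.9,NA
exp3,Same,7L,0L,bo,455,3.7,TRUE
exp3,Same,7L,3L,bs,459,3.2,TRUE
exp3,Same,7L,rev0L,ob,466,4.3,TRUE
exp3,Same,7L,rev3L,sb,471,4.2,TRUE
exp3,Same,7L,ALD,du,484,6.3,NA
exp3,Different,7L,0L,bo,498,2.5,FALSE
exp3,Different,7L,3L,bs,509,2.2,FALSE
exp3,Different,7L,rev0L,ob,500,1.8,FALSE
exp3,Different,7L,rev3L,sb,501,1.8,FALSE
exp3,Different,7L,ALD,du,500,2.2,NA
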